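toy_results <- function(names, q) {
  res <- data.frame(set_name = names, size = 10L, es = 0.5, nes = 1.5,
                    p_value = q, q_value = q, stringsAsFactors = FALSE)
  res$leading_edge <- I(as.list(rep("G01", length(names))))
  res
}

test_that("the q filter keeps exactly the sets at or below the threshold", {
  res <- toy_results(c("A", "B", "C"), c(5e-5, 5e-4, 1e-4))
  kept <- filter_significant(res, 1e-4)
  expect_equal(kept$set_name, c("A", "C"))  # boundary q == q_max is kept
  expect_equal(filter_significant(res, 1)$set_name, res$set_name)
})

test_that("jaccard matches enumeration and its boundary identities", {
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard(c("A", "B", "C", "D"), c("A", "B", "C", "E")), 0.6)
  expect_error(jaccard(character(0), character(0)), "empty")

  set.seed(601)
  for (i in 1:30) {
    a <- sample(LETTERS, sample(1:10, 1))
    b <- sample(LETTERS, sample(1:10, 1))
    expect_equal(jaccard(a, b),
                 length(intersect(a, b)) / length(union(a, b)))
    expect_equal(jaccard(a, b), jaccard(b, a))
    expect_gte(jaccard(a, b), 0)
    expect_lte(jaccard(a, b), 1)
  }
})

test_that("edges appear exactly at the similarity threshold", {
  rl <- ranked_list(paste0("G", 1:10), 10:1)
  db <- gene_set_db(list(S1 = paste0("G", 1:4),
                         S2 = c(paste0("G", 1:3), "G5"),   # J = 0.6 with S1
                         S3 = c("G1", "G2", "G7", "G8")))  # J = 1/3 with S1
  net <- build_network(toy_results(c("S1", "S2", "S3"), 1e-5), db, rl,
                       network_params())
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$from, "S1")
  expect_equal(net$edges$to, "S2")
  expect_equal(net$edges$similarity, 0.6)
  expect_equal(net$edges$overlap_size, 3L)
})

test_that("identical surviving sets give a complete graph", {
  rl <- ranked_list(paste0("G", 1:10), 10:1)
  members <- paste0("G", 1:5)
  db <- gene_set_db(stats::setNames(replicate(4, members, simplify = FALSE),
                                    paste0("S", 1:4)))
  net <- build_network(toy_results(paste0("S", 1:4), 1e-5), db, rl,
                       network_params())
  expect_equal(nrow(net$edges), 6L)
  expect_true(all(net$edges$similarity == 1))
})

test_that("networks match brute-force all-pairs computation on random inputs", {
  set.seed(602)
  for (i in 1:5) {
    rl <- random_ranked_list(80)
    k <- sample(5:30, 1)
    db <- random_gene_set_db(k, rl$gene, size_range = c(4L, 12L))
    res <- toy_results(names(db), rep(1e-5, k))
    thr <- runif(1, 0.05, 0.6)
    net <- build_network(res, db, rl, network_params(similarity_min = thr))
    # brute force over all unordered pairs, restricted to the universe
    expected <- 0L
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      ma <- intersect(db$sets[[a]], rl$gene)
      mb <- intersect(db$sets[[b]], rl$gene)
      s <- length(intersect(ma, mb)) / length(union(ma, mb))
      nm <- sort(c(names(db)[a], names(db)[b]))
      hit <- net$edges$from == nm[1] & net$edges$to == nm[2]
      if (s >= thr) {
        expected <- expected + 1L
        expect_true(any(hit))
        expect_equal(net$edges$similarity[hit], s)
      } else {
        expect_false(any(hit))
      }
    }
    expect_equal(nrow(net$edges), expected)
  }
})

test_that("raising thresholds is monotone: fewer edges, never fewer nodes", {
  set.seed(603)
  rl <- random_ranked_list(60)
  db <- random_gene_set_db(12, rl$gene, size_range = c(4L, 10L))
  q <- runif(12, 0, 1)
  res <- toy_results(names(db), q)
  edge_key <- function(net) paste(net$edges$from, net$edges$to)
  thresholds <- c(0.1, 0.3, 0.5, 0.8)
  nets <- lapply(thresholds, function(s)
    build_network(filter_significant(res, 0.5), db, rl,
                  network_params(similarity_min = s)))
  for (i in seq_along(nets)[-1])
    expect_true(all(edge_key(nets[[i]]) %in% edge_key(nets[[i - 1]])))

  n_nodes <- vapply(c(0.05, 0.2, 0.5, 1), function(qm)
    nrow(build_network(filter_significant(res, qm), db, rl,
                       network_params())$nodes), 0L)
  expect_true(all(diff(n_nodes) >= 0))
})

test_that("a result set absent from the database is reported by name", {
  rl <- ranked_list(paste0("G", 1:10), 10:1)
  db <- gene_set_db(list(S1 = paste0("G", 1:4)))
  expect_error(build_network(toy_results(c("S1", "GHOST"), 1e-5), db, rl,
                             network_params()), "GHOST")
})
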