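test_that("restrict_sets intersects with the universe and applies size bounds", {
  rl <- ranked_list(sprintf("G%02d", 1:30), 30:1)
  db <- gene_set_db(list(
    ABSENT = paste0("X", 1:10),
    BIG = c(sprintf("G%02d", 1:16), paste0("X", 1:4)),  # 16 in universe
    SMALL = sprintf("G%02d", 1:5)))
  out <- restrict_sets(db, rl, gsea_params(min_set_size = 15))
  expect_equal(names(out), "BIG")
  expect_length(out$sets$BIG, 16L)
  expect_true(all(out$sets$BIG %in% rl$gene))
  expect_error(restrict_sets(db, rl, gsea_params(min_set_size = 400)),
               "size")
})

test_that("extreme singleton sets reach the ES bounds", {
  rl <- ranked_list(paste0("G", 1:5), c(3, 2, 1, -1, -2))
  expect_equal(enrichment_score(rl, "G1")$es, 1)
  expect_equal(enrichment_score(rl, "G5", weight_exponent = 0)$es, -1)
  expect_error(enrichment_score(rl, paste0("G", 1:5)), "entire universe")
  expect_error(enrichment_score(rl, "NOPE"), "no member")
})

test_that("ES and leading edge match the brute-force running sum", {
  rl <- ranked_list(paste0("G", 1:5), c(3, 2, 1, -1, -2))
  out <- enrichment_score(rl, c("G1", "G3"))
  expect_equal(out$es, oracle_es(rl$gene, rl$score, c("G1", "G3")),
               tolerance = 1e-14)

  set.seed(501)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    rl <- random_ranked_list(n)
    k <- sample(seq_len(n - 1), 1)
    set <- sample(rl$gene, k)
    w <- sample(c(0, 0.5, 1, 2), 1)
    out <- enrichment_score(rl, set, w)
    expect_equal(out$es, oracle_es(rl$gene, rl$score, set, w),
                 tolerance = 1e-12)
    expect_true(all(out$leading_edge %in% intersect(set, rl$gene)))
    # leading edge sits on the correct side of the extremum
    pos <- match(out$leading_edge, rl$gene)
    if (out$es > 0) expect_lte(max(pos), which.max(out$running_sum))
    if (out$es < 0) expect_gte(min(pos), which.min(out$running_sum))
  }
})

test_that("ES agrees with fgsea's statistic on random instances", {
  set.seed(502)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    rl <- random_ranked_list(n)
    set <- sample(rl$gene, sample(3:10, 1))
    ours <- enrichment_score(rl, set, weight_exponent = 1)$es
    stats <- stats::setNames(rl$score, rl$gene)
    theirs <- fgsea::calcGseaStat(stats, match(set, rl$gene), gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("negating scores mirrors ES, NES and the leading edge", {
  set.seed(503)
  for (i in 1:10) {
    rl <- random_ranked_list(30)
    neg <- ranked_list(rl$gene, -rl$score)
    set <- sample(rl$gene, 8)
    a <- enrichment_score(rl, set)
    b <- enrichment_score(neg, set)
    expect_equal(a$es, -b$es, tolerance = 1e-12)
    expect_setequal(a$leading_edge, b$leading_edge)
  }
})

test_that("the permutation null is deterministic, bounded, and cached per size", {
  rl <- random_ranked_list(50)
  p <- gsea_params(n_permutations = 500, seed = 7)
  n1 <- permutation_null(rl, 10, p)
  n2 <- permutation_null(rl, 10, p)
  expect_identical(n1, n2)
  expect_true(all(n1 >= -1 & n1 <= 1))
  expect_length(n1, 500L)
})

test_that("NES and p follow the same-sign conventions", {
  out <- normalize_and_test(0.4, c(0.2, 0.4, -0.5))
  expect_equal(out$nes, 0.4 / 0.3)
  expect_equal(out$p, 2 / 3)

  expect_equal(normalize_and_test(0, rnorm(10)),
               list(nes = 0, p = 1, degenerate = FALSE))

  null <- c(runif(999, 0.01, 0.5), -0.2)
  out <- normalize_and_test(0.99, null)
  expect_equal(out$p, 1 / 1000)

  expect_warning(out <- normalize_and_test(0.5, c(-0.1, -0.2)), "same-sign")
  expect_equal(out$p, 1)
  expect_true(out$degenerate)
})

test_that("BH adjustment matches the hand step-up and is permutation-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(504)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-15)
})

test_that("run_gsea is invariant to database order and null depth leaves ES alone", {
  set.seed(505)
  rl <- random_ranked_list(200)
  db <- random_gene_set_db(12, rl$gene, size_range = c(15L, 30L))
  p <- gsea_params(n_permutations = 200, seed = 11)
  res <- run_gsea(rl, db, p)
  expect_true(all(abs(res$es) <= 1))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))

  shuffled <- gene_set_db(db$sets[sample(length(db$sets))])
  res2 <- run_gsea(rl, shuffled, p)
  expect_equal(res2[order(res2$set_name), setdiff(names(res2), "leading_edge")],
               res[order(res$set_name), setdiff(names(res), "leading_edge")],
               ignore_attr = TRUE)

  deeper <- run_gsea(rl, db, gsea_params(n_permutations = 400, seed = 11))
  expect_equal(deeper$es[match(res$set_name, deeper$set_name)], res$es)
})
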