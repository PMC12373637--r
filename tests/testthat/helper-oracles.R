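# Independent oracles used to validate the package's core statistics.
# These are literal, unoptimized transcriptions of the definitions; they
# deliberately share no code with the implementations in R/.

# Brute-force GSEA running sum: walk the ranked list one gene at a time.
oracle_es <- function(genes, scores, set_members, weight = 1) {
  n <- length(genes)
  hit <- genes %in% set_members
  k <- sum(hit)
  w <- abs(scores)^weight
  nr <- sum(w[hit])
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + if (nr > 0) w[i] / nr else 1 / k
    } else {
      cur <- cur - 1 / (n - k)
    }
    running[i] <- cur
  }
  mx <- max(running)
  mn <- min(running)
  # positive extremum wins magnitude ties, compared with a relative
  # tolerance so rounding noise cannot flip an exact tie
  if (mx >= -mn - 1e-12 * max(mx, -mn)) mx else mn
}

# Union-find connected components, path halving; returns a canonical
# partition (list of sorted member vectors, sorted by first member).
oracle_components <- function(nodes, from, to) {
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    ra <- find(match(from[e], nodes))
    rb <- find(match(to[e], nodes))
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  parts <- lapply(split(nodes, roots), function(m) sort(m))
  unname(parts[order(vapply(parts, `[`, "", 1L))])
}

canonical_partition <- function(groups) {
  parts <- lapply(groups, function(m) sort(m))
  unname(parts[order(vapply(parts, `[`, "", 1L))])
}

# Line-by-line transcription of the published low-count filter rule.
oracle_filter_keep <- function(counts, group, min_count = 10,
                               min_total_count = 15, large_n = 10,
                               min_prop = 0.7) {
  lib <- colSums(counts)
  cutoff <- min_count / median(lib) * 1e6
  n_small <- min(table(group))
  if (n_small > large_n) n_small <- large_n + (n_small - large_n) * min_prop
  cpm_mat <- sweep(counts, 2, lib, "/") * 1e6
  tol <- 1e-14
  rowSums(cpm_mat >= cutoff) >= n_small - tol &
    rowSums(counts) >= min_total_count - tol
}

# Step-by-step transcription of the TMM factor for one sample against a
# given reference column (trimming by sorted order rather than ranks).
oracle_tmm_one <- function(obs, ref, lib_obs, lib_ref) {
  pr_obs <- obs / lib_obs
  pr_ref <- ref / lib_ref
  use <- obs > 0 & ref > 0
  m <- log2(pr_obs[use] / pr_ref[use])
  a <- (log2(pr_obs[use]) + log2(pr_ref[use])) / 2
  w <- (lib_obs - obs[use]) / (lib_obs * obs[use]) +
       (lib_ref - ref[use]) / (lib_ref * ref[use])
  n <- length(m)
  lo_m <- floor(n * 0.3) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
  keep_m <- rank(m) >= lo_m & rank(m) <= hi_m
  keep_a <- rank(a) >= lo_a & rank(a) <= hi_a
  keep <- keep_m & keep_a
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

# Conditional NB double tail by direct summation of the product of two NB
# probability masses (groups of n1 and n2 samples, equal means).
oracle_exact_p <- function(z1, z2, n1, n2, phi) {
  z <- z1 + z2
  r <- 1 / phi
  mu <- z / (n1 + n2)
  k <- 0:z
  pr <- dnbinom(k, size = n1 * r, mu = n1 * mu) *
        dnbinom(z - k, size = n2 * r, mu = n2 * mu)
  pr <- pr / sum(pr)
  min(1, 2 * min(sum(pr[k <= z1]), sum(pr[k >= z1])))
}

# Small random fixtures shared across tests.
random_gene_set_db <- function(n_sets, universe, size_range = c(3L, 8L)) {
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(universe, sample(size_range[1L]:size_range[2L], 1L))
  })
  names(sets) <- sprintf("RSET_%03d", seq_len(n_sets))
  gene_set_db(sets)
}

random_ranked_list <- function(n) {
  ranked_list(sprintf("RG%04d", seq_len(n)), rnorm(n))
}
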