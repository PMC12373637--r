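#' Low-count filter configuration
#'
#' Constants of the filterByExpr-style rule with its published defaults:
#' a gene is kept when enough samples reach a CPM cutoff derived from
#' `min_count` at the median library size, and its total count reaches
#' `min_total_count`. When the smallest class has more than `large_n`
#' samples, the required number of passing samples is damped toward
#' `large_n + (n_small - large_n) * min_prop`.
#'
#' @param min_count Minimum count in a "worthwhile" sample (default 10).
#' @param min_total_count Minimum total count across samples (default 15).
#' @param large_n Class size beyond which the damping applies (default 10).
#' @param min_prop Damping proportion (default 0.7).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_count = 10, min_total_count = 15,
                          large_n = 10, min_prop = 0.7) {
  stopifnot(min_count >= 0, min_total_count >= 0, large_n >= 0,
            min_prop > 0, min_prop <= 1)
  structure(list(min_count = min_count, min_total_count = min_total_count,
                 large_n = large_n, min_prop = min_prop),
            class = "filter_config")
}

#' Remove genes with too few reads to support inference
#'
#' @param x An [expr_matrix()] with classes set.
#' @param cfg A [filter_config()].
#' @return The `expr_matrix` restricted to surviving genes, row order
#'   preserved.
#' @export
filter_low_counts <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(cfg, "filter_config"))
  if (is.null(x$classes)) stop("sample classes must be set before filtering")
  grp_n <- tabulate(x$classes)
  if (any(grp_n == 0L)) stop("each class needs at least one sample")
  lib <- lib_sizes(x)
  if (any(lib <= 0)) stop("sample with zero library size: ",
                          colnames(x$counts)[which(lib <= 0)[1L]])
  cpm_cutoff <- cfg$min_count / stats::median(lib) * 1e6
  n_small <- min(grp_n)
  if (n_small > cfg$large_n)
    n_small <- cfg$large_n + (n_small - cfg$large_n) * cfg$min_prop
  cpm_raw <- t(t(x$counts) / lib) * 1e6
  tol <- 1e-14
  keep <- rowSums(cpm_raw >= cpm_cutoff) >= n_small - tol &
    rowSums(x$counts) >= cfg$min_total_count - tol
  expr_matrix(x$counts[keep, , drop = FALSE], x$classes)
}

# Upper-quartile of count/library-size per sample: reference selection
# statistic of the TMM procedure.
.uq_stat <- function(counts, lib) {
  apply(counts, 2L, stats::quantile, probs = 0.75) / lib
}

# Pairwise TMM factor of column `obs` against column `ref`: doubly trimmed
# (30% of M, 5% of A), precision-weighted mean of the log2 ratios, weights
# the inverse asymptotic binomial variances.
.tmm_pair <- function(obs, ref, n_obs, n_ref,
                      logratio_trim = 0.3, sum_trim = 0.05,
                      a_cutoff = -1e10) {
  log_r <- log2((obs / n_obs) / (ref / n_ref))
  abs_e <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(log_r) & is.finite(abs_e) & (abs_e > a_cutoff)
  log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
  if (length(log_r) == 0L || max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_l <- floor(n * logratio_trim) + 1; hi_l <- n + 1 - lo_l
  lo_s <- floor(n * sum_trim) + 1;      hi_s <- n + 1 - lo_s
  keep <- (rank(log_r) >= lo_l & rank(log_r) <= hi_l) &
          (rank(abs_e) >= lo_s & rank(abs_e) <= hi_s)
  f <- sum(log_r[keep] / v[keep], na.rm = TRUE) /
       sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Scaling factors correcting for RNA composition bias between samples. The
#' reference sample is the column whose upper-quartile count fraction is
#' closest to the mean across samples; each sample's factor is the
#' precision-weighted mean of its trimmed log2 count ratios against the
#' reference (30% trim on M-values, 5% on average abundance, both two-sided),
#' and factors are rescaled so their geometric mean is 1.
#'
#' @param x An [expr_matrix()] with at least two samples.
#' @return A `tmm_factors` object: `factors` (named, geometric mean 1) and
#'   `reference_sample`.
#' @export
tmm_factors <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  counts <- x$counts
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("sample with zero library size: ", colnames(counts)[which(lib <= 0)[1L]])
  uq <- .uq_stat(counts, lib)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref])
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  structure(list(factors = f, reference_sample = colnames(counts)[ref]),
            class = "tmm_factors")
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("TMM factors (reference:", x$reference_sample, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Counts per million over effective library sizes
#'
#' `count / (library size x factor) x 1e6`. The log variant returns
#' `log2` CPM with a prior count scaled proportionally to each sample's
#' effective library size, so that `2^logCPM` converges to linear CPM as
#' `prior_count -> 0`.
#'
#' @param x An [expr_matrix()].
#' @param factors Optional [tmm_factors()] (or bare numeric vector aligned
#'   with samples); defaults to unit factors.
#' @param log Return log2 values?
#' @param prior_count Average prior count added before taking logs.
#' @return A genes x samples numeric matrix.
#' @export
cpm <- function(x, factors = NULL, log = FALSE, prior_count = 0.5) {
  stopifnot(inherits(x, "expr_matrix"))
  f <- if (is.null(factors)) rep(1, ncol(x$counts))
       else if (inherits(factors, "tmm_factors")) factors$factors
       else as.numeric(factors)
  if (length(f) != ncol(x$counts))
    stop("factors do not align with samples")
  eff <- colSums(x$counts) * f
  if (!log)
    return(t(t(x$counts) / eff) * 1e6)
  pc <- prior_count * eff / mean(eff)
  log2(t((t(x$counts) + pc) / (eff + 2 * pc)) * 1e6)
}
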