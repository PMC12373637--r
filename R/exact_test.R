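# Two-sided conditional NB exact p-value for one gene: class sums z1, z2
# from n1 and n2 equalized samples at common dispersion phi. Conditional on
# the total, the class-1 sum follows a beta-binomial with shape n1/phi,
# n2/phi; p is twice the smaller tail (observed point included), capped at 1.
# Totals above `big_count` use the limiting beta approximation with a 0.5
# continuity correction; dispersion ~ 0 reduces to the binomial split.
exact_nb_pval_one <- function(z1, z2, n1, n2, phi, big_count = 900) {
  z <- z1 + z2
  if (z == 0) return(1)
  if (phi < 1e-8) {
    p_lo <- stats::pbinom(z1, z, n1 / (n1 + n2))
    p_hi <- stats::pbinom(z2, z, n2 / (n1 + n2))
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  r <- 1 / phi
  a1 <- n1 * r
  a2 <- n2 * r
  if (z <= big_count) {
    k <- 0:z
    logp <- lchoose(z, k) + lbeta(k + a1, z - k + a2) - lbeta(a1, a2)
    pr <- exp(logp - max(logp))
    # Tails summed as exact mirror images (low tail in ascending k, high
    # tail in descending k) so that swapping the class labels permutes the
    # two tails bitwise and the doubled-smaller-tail p-value is exactly
    # label-symmetric.
    lo_raw <- sum(pr[seq_len(z1 + 1L)])
    hi_raw <- sum(pr[z + 1L - seq_len(z2 + 1L) + 1L])
    denom <- lo_raw + hi_raw - pr[z1 + 1L]
    p_lo <- lo_raw / denom
    p_hi <- hi_raw / denom
  } else {
    p_lo <- stats::pbeta((z1 + 0.5) / (z + 1), a1, a2)
    p_hi <- stats::pbeta((z2 + 0.5) / (z + 1), a2, a1)
  }
  min(1, 2 * min(p_lo, p_hi))
}

#' Exact negative-binomial test for two-class differential expression
#'
#' The classic conditional exact test with a common dispersion: library
#' sizes are equalized via TMM-scaled quantile-adjusted pseudo-counts,
#' class sums are conditioned on the gene total, and the two-sided p-value
#' is the doubled smaller tail of the conditional (beta-binomial)
#' distribution, capped at 1. Log2 fold changes (class B vs class A, i.e.
#' second factor level vs first) come from class-mean CPMs with a small
#' prior count; q-values are Benjamini-Hochberg over all tested genes.
#'
#' @param x A filtered [expr_matrix()] with classes set, >= 2 samples per
#'   class.
#' @param dispersion Common NB dispersion (e.g. from
#'   [estimate_common_dispersion()]); must be >= 0.
#' @param factors Optional [tmm_factors()]; computed from `x` when omitted.
#' @param prior_count Per-sample prior count for the fold-change CPMs
#'   (default 0.5).
#' @return Data frame with one row per gene: `gene`, `log2_fold_change`,
#'   `p_value`, `adjusted_p`, `mean_cpm`.
#' @export
differential_test <- function(x, dispersion, factors = NULL,
                              prior_count = 0.5) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion < 0)
    stop("dispersion must be a single non-negative number")
  idx <- class_index(x)
  if (any(lengths(idx) < 2L))
    stop("fewer than 2 samples in a class: the exact test cannot run; ",
         "supply a pre-ranked RNK file instead")
  if (is.null(factors)) factors <- tmm_factors(x)
  f <- if (inherits(factors, "tmm_factors")) factors$factors
       else as.numeric(factors)
  eq <- equalize_pseudo(x, max(dispersion, 1e-10), f)
  jA <- idx[[1L]]; jB <- idx[[2L]]
  z1 <- round(rowSums(eq$pseudo[, jA, drop = FALSE]))
  z2 <- round(rowSums(eq$pseudo[, jB, drop = FALSE]))
  n1 <- length(jA); n2 <- length(jB)
  p <- vapply(seq_along(z1), function(i) {
    exact_nb_pval_one(z1[i], z2[i], n1, n2, dispersion)
  }, 0)
  eff <- colSums(x$counts) * f
  pc <- prior_count * eff / mean(eff)
  cpm_prior <- t((t(x$counts) + pc) / (eff + 2 * pc)) * 1e6
  lfc <- log2(rowMeans(cpm_prior[, jB, drop = FALSE]) /
                rowMeans(cpm_prior[, jA, drop = FALSE]))
  data.frame(gene = rownames(x$counts),
             log2_fold_change = unname(lfc),
             p_value = p,
             adjusted_p = bh_adjust(p),
             mean_cpm = unname(rowMeans(cpm(x, factors = f))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Signed rank scores from differential-expression results
#'
#' Each gene scores `sign(log2 fold change) * -log10(p)`, with the p-value
#' floored at 1e-300 and a zero fold change mapping to score 0. The result
#' is ordered descending with lexicographic tie-breaking.
#'
#' @param de A [differential_test()] result.
#' @return A [ranked_list()].
#' @export
compute_ranks <- function(de) {
  if (nrow(de) == 0L) stop("no genes to rank")
  p <- pmax(de$p_value, 1e-300)
  score <- sign(de$log2_fold_change) * (-log10(p))
  ranked_list(de$gene, score)
}
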