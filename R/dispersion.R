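# Quantile-to-quantile mapping of negative-binomial counts from one mean to
# another at fixed dispersion, averaging a normal and a gamma approximation.
# Used to construct pseudo-counts at a common library size.
q2q_nbinom <- function(x, input_mean, output_mean, dispersion) {
  eps <- 1e-14
  input_mean <- pmax(input_mean, eps)
  output_mean <- pmax(output_mean, eps)
  ri <- 1 + dispersion * input_mean
  ro <- 1 + dispersion * output_mean
  # normal approximation: match z-scores
  q1 <- output_mean + sqrt(output_mean * ro / (input_mean * ri)) *
    (x - input_mean)
  # gamma approximation: match cumulative probabilities
  p <- stats::pgamma(x, shape = input_mean / ri, scale = ri)
  q2 <- stats::qgamma(p, shape = output_mean / ro, scale = ro)
  pmax((q1 + q2) / 2, 0)
}

# One-group negative-binomial means with a log link and library-size
# offsets: Fisher scoring for log-abundance per gene, vectorized over genes.
# Returns per-gene abundance beta (counts per unit library size, on the
# natural scale).
nb_group_abundance <- function(counts, eff_lib, dispersion, iter = 10L) {
  tot <- rowSums(counts)
  beta <- log(pmax(tot, 1e-8) / sum(eff_lib))
  for (i in seq_len(iter)) {
    mu <- exp(beta) %o% eff_lib
    w <- 1 + dispersion * mu
    num <- rowSums((counts - mu) / w)
    den <- rowSums(mu / w)
    step <- num / pmax(den, 1e-10)
    step <- pmin(pmax(step, -5), 5)
    beta <- beta + step
  }
  beta[tot == 0] <- -Inf
  exp(beta)
}

# Pseudo-counts at the common (geometric-mean) effective library size, per
# class, at a given dispersion. Returns the pseudo matrix and per-gene,
# per-class fitted abundances.
equalize_pseudo <- function(x, dispersion, factors = NULL) {
  f <- if (is.null(factors)) rep(1, ncol(x$counts))
       else if (inherits(factors, "tmm_factors")) factors$factors
       else as.numeric(factors)
  eff <- colSums(x$counts) * f
  common <- geo_mean(eff)
  idx <- class_index(x)
  pseudo <- x$counts
  for (g in names(idx)) {
    j <- idx[[g]]
    lam <- nb_group_abundance(x$counts[, j, drop = FALSE], eff[j], dispersion)
    input_mean <- lam %o% eff[j]
    output_mean <- matrix(lam * common, nrow = nrow(pseudo), ncol = length(j))
    pseudo[, j] <- q2q_nbinom(x$counts[, j, drop = FALSE],
                              input_mean, output_mean, dispersion)
  }
  list(pseudo = pseudo, common_lib = common)
}

# Pooled conditional (quantile-adjusted) NB log-likelihood of a common
# dispersion, computed on equalized pseudo-counts: within each class, the
# likelihood of the counts conditional on their sum, summed over genes.
common_cond_loglik <- function(pseudo, classes, dispersion) {
  r <- 1 / dispersion
  ll <- 0
  for (j in split(seq_len(ncol(pseudo)), classes)) {
    y <- pseudo[, j, drop = FALSE]
    n <- length(j)
    z <- rowSums(y)
    use <- z > 0
    ll <- ll + sum(rowSums(lgamma(y[use, , drop = FALSE] + r)) -
                     n * lgamma(r) + lgamma(n * r) - lgamma(z[use] + n * r))
  }
  ll
}

#' Estimate a single common negative-binomial dispersion
#'
#' Maximizes the conditional likelihood of a shared dispersion pooled across
#' genes, after equalizing library sizes by quantile-adjusted pseudo-counts.
#' The search is a bounded one-dimensional optimization on
#' `[1e-6, 4]` (tolerance 1e-6), alternated twice with pseudo-count
#' recomputation; the procedure is deterministic.
#'
#' @param x A filtered [expr_matrix()] with classes set and at least two
#'   samples per class.
#' @param factors Optional [tmm_factors()] used for effective library sizes.
#' @return The dispersion estimate (scalar, `>= 1e-6`).
#' @export
estimate_common_dispersion <- function(x, factors = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  idx <- class_index(x)
  if (any(lengths(idx) < 2L))
    stop("fewer than 2 samples in a class: the exact test cannot run; ",
         "supply a pre-ranked RNK file instead")
  disp <- 0.1
  for (round in 1:2) {
    eq <- equalize_pseudo(x, disp, factors)
    opt <- stats::optimize(
      function(d) common_cond_loglik(eq$pseudo, x$classes, d),
      interval = c(1e-6, 4), maximum = TRUE, tol = 1e-6)
    disp <- opt$maximum
  }
  disp
}
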