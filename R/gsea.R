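#' Preranked GSEA parameters
#'
#' @param min_set_size,max_set_size Bounds on the size of a set after
#'   intersection with the ranked universe (defaults 15 and 500).
#' @param weight_exponent Exponent on |score| for hit increments (default 1;
#'   0 gives the unweighted Kolmogorov-Smirnov-like statistic).
#' @param n_permutations Gene-sampling permutations per set size (default
#'   1000, minimum 100). Note the nominal p-value cannot drop below
#'   `1/(n_permutations + 1)`; tight downstream q-value filters need
#'   correspondingly deep sampling.
#' @param seed Integer seed driving the permutation null.
#' @return A `gsea_params` list.
#' @export
gsea_params <- function(min_set_size = 15L, max_set_size = 500L,
                        weight_exponent = 1, n_permutations = 1000L,
                        seed = 42L) {
  stopifnot(min_set_size >= 1, min_set_size <= max_set_size,
            weight_exponent >= 0, n_permutations >= 100)
  structure(list(min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size),
                 weight_exponent = weight_exponent,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "gsea_params")
}

#' Restrict a gene-set database to the ranked universe
#'
#' Each set is intersected with the genes of the ranked list (member order
#' preserved); sets whose intersected size falls outside
#' `[min_set_size, max_set_size]` are dropped. Database order is retained.
#'
#' @param db A [gene_set_db()].
#' @param ranks A [ranked_list()].
#' @param params A [gsea_params()].
#' @return The restricted `gene_set_db`.
#' @export
restrict_sets <- function(db, ranks, params = gsea_params()) {
  stopifnot(inherits(db, "gene_set_db"), inherits(ranks, "ranked_list"))
  universe <- ranks$gene
  sets <- lapply(db$sets, function(m) m[m %in% universe])
  sz <- lengths(sets)
  keep <- sz >= params$min_set_size & sz <= params$max_set_size
  if (!any(keep))
    stop("no gene set overlaps the ranked universe within the size bounds ",
         sprintf("[%d, %d]; consider relaxing min/max set size",
                 params$min_set_size, params$max_set_size))
  gene_set_db(sets[keep], db$descriptions[keep], db$source)
}

#' Running-sum enrichment score of one gene set
#'
#' Walking the list from the top, in-set genes ("hits") increment the
#' running sum by `|score|^weight_exponent` normalized by the sum of those
#' weights over in-set genes (uniform increments if that sum is zero), and
#' out-of-set genes decrement it by `1/(N - n_set)`. The enrichment score is
#' the running-sum value of maximal absolute deviation from zero (the
#' positive branch wins exact-magnitude ties). The leading edge contains the
#' in-set genes at or before the positive extremum (at or after the negative
#' extremum when ES < 0), in rank order.
#'
#' @param ranks A [ranked_list()].
#' @param set_members Character vector of member genes; the intersection
#'   with the universe must be non-empty and proper.
#' @param weight_exponent Weighting exponent (see [gsea_params()]).
#' @return List with `es`, `running_sum` (length N) and `leading_edge`.
#' @export
enrichment_score <- function(ranks, set_members, weight_exponent = 1) {
  stopifnot(inherits(ranks, "ranked_list"))
  n <- nrow(ranks)
  hit <- ranks$gene %in% set_members
  k <- sum(hit)
  if (k == 0L) stop("gene set has no member in the ranked universe")
  if (k == n) stop("gene set covers the entire universe; the miss decrement is undefined")
  w <- abs(ranks$score)^weight_exponent
  hw <- w * hit
  sw <- sum(hw)
  inc <- if (sw > 0) hw / sw else hit / k
  rs <- cumsum(inc - (!hit) / (n - k))
  i_max <- which.max(rs)
  i_min <- which.min(rs)
  # positive branch wins magnitude ties; the comparison carries a relative
  # tolerance so that exact rational ties are not flipped by summation-order
  # rounding
  mx <- rs[i_max]
  mn <- rs[i_min]
  es <- if (mx >= -mn - 1e-12 * max(mx, -mn)) mx else mn
  le <- if (es >= 0) ranks$gene[hit & seq_len(n) <= i_max]
        else ranks$gene[hit & seq_len(n) >= i_min]
  list(es = es, running_sum = rs, leading_edge = le)
}

#' Sample the gene-permutation null ES distribution for one set size
#'
#' Draws `n_permutations` gene sets of the given size uniformly without
#' replacement from the ranked universe and returns their enrichment
#' scores. Reproducible given `params$seed`; within [run_gsea()] the null is
#' computed once per distinct set size and shared.
#'
#' @param ranks A [ranked_list()].
#' @param set_size Number of genes per null set.
#' @param params A [gsea_params()].
#' @return Numeric vector of `n_permutations` null enrichment scores.
#' @export
permutation_null <- function(ranks, set_size, params = gsea_params()) {
  stopifnot(inherits(ranks, "ranked_list"))
  absw <- abs(ranks$score)^params$weight_exponent
  with_seed(params$seed,
            .null_es_batch(absw, as.integer(set_size),
                           params$n_permutations))
}

#' Normalize an enrichment score and compute its permutation p-value
#'
#' `nes = es / mean(|null values of the same sign as es|)`;
#' `p = (1 + #same-sign nulls at least as extreme) / (1 + #same-sign
#' nulls)`. `es = 0` maps to `nes = 0`, `p = 1`. If no null value shares the
#' sign of `es`, `p` is set to 1 and the result is flagged degenerate.
#'
#' @param es Observed enrichment score.
#' @param null Numeric vector of null enrichment scores.
#' @return List with `nes`, `p` and logical `degenerate`.
#' @export
normalize_and_test <- function(es, null) {
  if (length(null) == 0L) stop("empty null sample")
  if (es == 0) return(list(nes = 0, p = 1, degenerate = FALSE))
  same <- null[sign(null) == sign(es)]
  if (length(same) == 0L) {
    warning("no same-sign null values; p-value set to 1")
    return(list(nes = NA_real_, p = 1, degenerate = TRUE))
  }
  nes <- es / mean(abs(same))
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(nes = nes, p = p, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Run preranked gene-set enrichment analysis
#'
#' Restricts the database to the ranked universe, computes each set's
#' enrichment score and leading edge, samples a gene-permutation null shared
#' across sets of equal size, derives NES and nominal p-values, and adjusts
#' with Benjamini-Hochberg across all tested sets. Fully reproducible given
#' `params$seed`, and invariant to the order of sets in the database.
#'
#' @param ranks A [ranked_list()].
#' @param db A [gene_set_db()].
#' @param params A [gsea_params()].
#' @return Data frame sorted by q-value, then |NES| descending, then set
#'   name: columns `set_name`, `size`, `es`, `nes`, `p_value`, `q_value`,
#'   `leading_edge` (list column), `degenerate`.
#' @export
run_gsea <- function(ranks, db, params = gsea_params()) {
  restricted <- restrict_sets(db, ranks, params)
  set_names <- names(restricted$sets)
  per_set <- lapply(restricted$sets, enrichment_score, ranks = ranks,
                    weight_exponent = params$weight_exponent)
  es <- vapply(per_set, `[[`, 0, "es")
  sizes <- lengths(restricted$sets)
  absw <- abs(ranks$score)^params$weight_exponent
  nulls <- with_seed(params$seed, {
    out <- list()
    for (s in sort(unique(sizes)))
      out[[as.character(s)]] <-
        .null_es_batch(absw, as.integer(s), params$n_permutations)
    out
  })
  nt <- Map(function(e, s) normalize_and_test(e, nulls[[as.character(s)]]),
            es, sizes)
  res <- data.frame(set_name = set_names,
                    size = as.integer(unname(sizes)),
                    es = unname(es),
                    nes = vapply(nt, `[[`, 0, "nes"),
                    p_value = vapply(nt, `[[`, 0, "p"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$q_value <- bh_adjust(res$p_value)
  res$leading_edge <- I(unname(lapply(per_set, `[[`, "leading_edge")))
  res$degenerate <- vapply(nt, `[[`, TRUE, "degenerate")
  o <- order(res$q_value, -abs(ifelse(is.na(res$nes), 0, res$nes)),
             res$set_name, method = "radix")
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "universe") <- ranks$gene
  attr(res, "params") <- params
  res
}
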