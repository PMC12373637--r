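#' Enrichment-network parameters
#'
#' Defaults follow standard enrichment-map practice: gene sets with
#' q-value above 1e-4 are removed, and surviving sets are connected when
#' their Jaccard similarity is at least 0.5. Both boundaries are inclusive
#' for keeping/connecting.
#'
#' @param q_max Maximum q-value for a set to become a node (default 1e-4).
#' @param similarity_min Minimum Jaccard similarity for an edge (default
#'   0.5).
#' @param similarity_metric Metric token; only `"jaccard"` is implemented.
#' @param restrict_to_universe Compute similarity on set members intersected
#'   with the ranked universe (default `TRUE`), so edge overlaps refer to
#'   the same universe as node sizes.
#' @return A `network_params` list.
#' @export
network_params <- function(q_max = 1e-4, similarity_min = 0.5,
                           similarity_metric = "jaccard",
                           restrict_to_universe = TRUE) {
  stopifnot(q_max > 0, q_max <= 1, similarity_min > 0, similarity_min <= 1)
  if (!identical(similarity_metric, "jaccard"))
    stop("unknown similarity metric: ", similarity_metric)
  structure(list(q_max = q_max, similarity_min = similarity_min,
                 similarity_metric = similarity_metric,
                 restrict_to_universe = isTRUE(restrict_to_universe)),
            class = "network_params")
}

#' Keep only significantly enriched sets
#'
#' Retains exactly the results with `q_value <= q_max` (inclusive
#' boundary), preserving order.
#'
#' @param results Enrichment-result data frame from [run_gsea()].
#' @param q_max Significance threshold on the BH-adjusted p-value.
#' @return The filtered data frame.
#' @export
filter_significant <- function(results, q_max = 1e-4) {
  out <- results[results$q_value <= q_max, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$universe <- attr(results, "universe")
  out
}

#' Jaccard similarity of two gene sets
#'
#' `|a intersect b| / |a union b|`.
#'
#' @param a,b Character vectors of gene identifiers; not both empty.
#' @return Similarity in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L)
    stop("Jaccard similarity of two empty sets is undefined")
  length(intersect(a, b)) / length(union(a, b))
}

#' Build the enrichment-map network
#'
#' One node per (filtered) result, carrying NES, q-value and set size; an
#' edge connects every unordered pair of sets whose Jaccard similarity
#' reaches `similarity_min`. Similarities are computed on set members
#' intersected with the ranked universe (configurable). Node and edge
#' ordering is lexicographic, so the construction is deterministic.
#'
#' @param results Filtered enrichment results (see [filter_significant()]).
#' @param db The [gene_set_db()] the results refer to.
#' @param ranks The [ranked_list()] defining the universe.
#' @param params A [network_params()].
#' @return An `enrichment_network`: list with `nodes`, `edges` data frames,
#'   `clusters` (`NULL` until [cluster_network()] runs) and `params`.
#' @export
build_network <- function(results, db, ranks, params = network_params()) {
  stopifnot(inherits(db, "gene_set_db"), inherits(ranks, "ranked_list"))
  missing <- setdiff(results$set_name, names(db$sets))
  if (length(missing))
    stop("result set missing from the database: ", missing[1L])
  nm <- sort(results$set_name, method = "radix")
  idx <- match(nm, results$set_name)
  members <- lapply(db$sets[nm], function(m) {
    if (params$restrict_to_universe) m[m %in% ranks$gene] else m
  })
  nodes <- data.frame(name = nm,
                      nes = results$nes[idx],
                      q_value = results$q_value[idx],
                      size = results$size[idx],
                      stringsAsFactors = FALSE, row.names = NULL)
  edges <- data.frame(from = character(0), to = character(0),
                      similarity = numeric(0), overlap_size = integer(0),
                      stringsAsFactors = FALSE)
  if (length(nm) >= 2L) {
    pairs <- utils::combn(length(nm), 2L)
    sim <- numeric(ncol(pairs))
    ov <- integer(ncol(pairs))
    for (c in seq_len(ncol(pairs))) {
      a <- members[[pairs[1L, c]]]
      b <- members[[pairs[2L, c]]]
      ov[c] <- length(intersect(a, b))
      sim[c] <- if (length(a) == 0L && length(b) == 0L) 0
                else ov[c] / length(union(a, b))
    }
    keep <- sim >= params$similarity_min
    edges <- data.frame(from = nm[pairs[1L, keep]],
                        to = nm[pairs[2L, keep]],
                        similarity = sim[keep],
                        overlap_size = ov[keep],
                        stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(nodes = nodes, edges = edges, clusters = NULL,
                 cluster_labels = NULL, params = params),
            class = "enrichment_network")
}

#' @export
print.enrichment_network <- function(x, ...) {
  cat(sprintf("enrichment_network: %d nodes, %d edges", nrow(x$nodes),
              nrow(x$edges)))
  if (!is.null(x$clusters))
    cat(sprintf(", %d clusters", length(unique(x$clusters))))
  cat("\n")
  invisible(x)
}
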