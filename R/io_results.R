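#' Write enrichment results as TSV
#'
#' One row per gene set with columns `name`, `size`, `ES`, `NES`, `pval`,
#' `padj`, `leading_edge` (comma-joined gene symbols). Numbers are written at
#' full precision so the numeric columns survive a round trip to at least 12
#' significant digits.
#'
#' @param results An enrichment-result data frame as returned by
#'   [run_gsea()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  header <- paste(c("name", "size", "ES", "NES", "pval", "padj",
                    "leading_edge"), collapse = "\t")
  if (nrow(results) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  le <- vapply(results$leading_edge, paste, "", collapse = ",")
  rows <- paste(results$set_name,
                results$size,
                format_num(results$es),
                format_num(results$nes),
                format_num(results$p_value),
                format_num(results$q_value),
                le,
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an enrichment-result TSV written by [write_results_tsv()]
#'
#' @param path Path to the TSV.
#' @return Enrichment-result data frame (leading edge as a list column).
#' @export
read_results_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "numeric",
                                         "numeric", "numeric", "numeric",
                                         "character"))
  data.frame(set_name = df$name, size = df$size, es = df$ES, nes = df$NES,
             p_value = df$pval, q_value = df$padj,
             leading_edge = I(strsplit(df$leading_edge, ",", fixed = TRUE)),
             stringsAsFactors = FALSE)
}

# igraph view of an enrichment network, with node and edge attributes;
# isolated nodes are kept.
as_igraph <- function(net) {
  stopifnot(inherits(net, "enrichment_network"))
  v <- net$nodes
  v <- data.frame(name = v$name, nes = v$nes, padj = v$q_value,
                  size = v$size, stringsAsFactors = FALSE)
  if (!is.null(net$clusters))
    v$cluster <- unname(net$clusters[v$name])
  e <- net$edges[, c("from", "to", "similarity", "overlap_size")]
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

#' Write an enrichment network to JSON or GraphML
#'
#' JSON uses a versioned schema (`format_version` 1.0): `nodes` records carry
#' `name`, `nes`, `padj`, `size` and (when clustering has run) `cluster` and
#' `cluster_label`; `edges` records carry `source`, `target`, `similarity`
#' and `overlap_size`. GraphML encodes the same attributes and is readable by
#' standard graph tools.
#'
#' @param net An `enrichment_network` from [build_network()].
#' @param path Output file path.
#' @param format `"json"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "enrichment_network"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
    return(invisible(path))
  }
  nodes <- data.frame(name = net$nodes$name, nes = net$nodes$nes,
                      padj = net$nodes$q_value, size = net$nodes$size,
                      stringsAsFactors = FALSE)
  if (!is.null(net$clusters)) {
    nodes$cluster <- unname(net$clusters[nodes$name])
    if (!is.null(net$cluster_labels))
      nodes$cluster_label <- unname(net$cluster_labels[as.character(nodes$cluster)])
  }
  edges <- data.frame(source = net$edges$from, target = net$edges$to,
                      similarity = net$edges$similarity,
                      overlap_size = net$edges$overlap_size,
                      stringsAsFactors = FALSE)
  obj <- list(format_version = "1.0",
              similarity_metric = net$params$similarity_metric,
              similarity_min = net$params$similarity_min,
              q_max = net$params$q_max,
              nodes = nodes, edges = edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Export a three-file enrichment folder
#'
#' Writes `enrichment_results.tsv` (the result table),
#' `ranks.rnk` (the ranked list the analysis used) and `gene_sets.gmt`
#' (the database filtered to the sets appearing in the results) into `dir`.
#'
#' @param results Enrichment-result data frame.
#' @param ranks The [ranked_list()] the results were computed from.
#' @param db The [gene_set_db()] the results were computed from.
#' @param dir Target directory (created if absent).
#' @param overwrite Allow writing into a non-empty directory.
#' @return `dir`, invisibly.
#' @export
export_enrichment_folder <- function(results, ranks, db, dir,
                                     overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite)
    stop("target directory is not empty (use overwrite = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_results_tsv(results, file.path(dir, "enrichment_results.tsv"))
  write_rnk(ranks, file.path(dir, "ranks.rnk"))
  if (nrow(results) > 0L)
    write_gmt(subset_gene_sets(db, results$set_name),
              file.path(dir, "gene_sets.gmt"))
  else
    writeLines(character(0), file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}
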