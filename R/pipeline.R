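#' Assemble a full run configuration
#'
#' Bundles every stage's parameters with the input paths into one
#' serializable object. Either `counts` (+ `classes`) or `rnk` must be
#' given, together with `gmt`.
#'
#' @param counts Path to an expression table (TSV/CSV), or `NULL`.
#' @param rnk Path to a pre-ranked RNK file, or `NULL`.
#' @param gmt Path to the GMT gene-set database.
#' @param classes Character vector of class labels in sample column order
#'   (expression mode only).
#' @param filter A [filter_config()].
#' @param gsea A [gsea_params()].
#' @param network A [network_params()].
#' @param cluster_method `"components"` or `"modularity"`.
#' @param output_dir Directory for result files, or `NULL` to skip writing.
#' @param network_format `"json"` or `"graphml"`.
#' @param seed Integer seed (overrides `gsea$seed`).
#' @param overwrite Allow writing into a non-empty output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(counts = NULL, rnk = NULL, gmt = NULL,
                       classes = NULL, filter = filter_config(),
                       gsea = gsea_params(), network = network_params(),
                       cluster_method = "components", output_dir = NULL,
                       network_format = "json", seed = NULL,
                       overwrite = FALSE) {
  if (is.null(gmt)) stop("a GMT gene-set database is required")
  if (is.null(counts) == is.null(rnk))
    stop("exactly one of 'counts' or 'rnk' must be given")
  if (!is.null(counts) && is.null(classes))
    stop("expression input requires a class assignment")
  if (!is.null(seed)) gsea$seed <- as.integer(seed)
  structure(list(input_mode = if (is.null(rnk)) "expression" else "rnk",
                 counts = counts, rnk = rnk, gmt = gmt, classes = classes,
                 filter = filter, gsea = gsea, network = network,
                 cluster_method = cluster_method, output_dir = output_dir,
                 network_format = network_format,
                 overwrite = isTRUE(overwrite)),
            class = "run_config")
}

# Effective parameters of a run, as a plain serializable list.
config_as_list <- function(config) {
  list(schema_version = "1.0",
       package_version = as.character(utils::packageVersion("enrichmapr")),
       input_mode = config$input_mode,
       counts = config$counts, rnk = config$rnk, gmt = config$gmt,
       classes = config$classes,
       filter = unclass(config$filter),
       gsea = unclass(config$gsea),
       network = unclass(config$network),
       cluster_method = config$cluster_method,
       network_format = config$network_format,
       seed = config$gsea$seed)
}

#' Run the full enrichment-map pipeline
#'
#' Expression mode: low-count filter, TMM factors, common-dispersion
#' estimate, exact NB test, signed -log10(p) ranks. RNK mode: ranks are
#' read directly. Then preranked GSEA, significance filtering, Jaccard
#' network construction, clustering and cluster labeling. When
#' `config$output_dir` is set, writes `ranks.rnk`,
#' `enrichment_results.tsv`, `gene_sets.gmt` (sets appearing in the
#' results), the network file and `run_log.json` (all effective
#' parameters); outputs are byte-identical across runs with the same
#' configuration and seed.
#'
#' @param config A [run_config()].
#' @return List with `ranks`, `results`, `network`, `clusters` and, in
#'   expression mode, `de` and `dispersion`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  db <- read_gmt(config$gmt)
  de <- NULL; dispersion <- NULL
  if (config$input_mode == "expression") {
    x <- read_expression(config$counts)
    x <- set_classes(x, config$classes)
    x <- filter_low_counts(x, config$filter)
    f <- tmm_factors(x)
    dispersion <- estimate_common_dispersion(x, f)
    de <- differential_test(x, dispersion, f)
    ranks <- compute_ranks(de)
  } else {
    ranks <- read_rnk(config$rnk)
  }
  if (config$network$q_max < 1 / (config$gsea$n_permutations + 1))
    warning(sprintf(
      "q-value filter %.3g is below the permutation p-value resolution %.3g; increase n_permutations",
      config$network$q_max, 1 / (config$gsea$n_permutations + 1)))
  results <- run_gsea(ranks, db, config$gsea)
  significant <- filter_significant(results, config$network$q_max)
  net <- build_network(significant, db, ranks, config$network)
  net <- cluster_network(net, config$cluster_method)
  net <- annotate_clusters(net)
  clusters <- network_clusters(net)
  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    if (dir.exists(dir) && length(list.files(dir)) > 0L &&
        !config$overwrite)
      stop("output directory is not empty (use overwrite): ", dir)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_rnk(ranks, file.path(dir, "ranks.rnk"))
    write_results_tsv(results, file.path(dir, "enrichment_results.tsv"))
    if (nrow(results) > 0L)
      write_gmt(subset_gene_sets(db, results$set_name),
                file.path(dir, "gene_sets.gmt"))
    net_file <- file.path(dir, paste0("network.", config$network_format))
    write_network(net, net_file, config$network_format)
    jsonlite::write_json(config_as_list(config),
                         file.path(dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  out <- list(ranks = ranks, results = results, network = net,
              clusters = clusters)
  if (!is.null(de)) {
    out$de <- de
    out$dispersion <- dispersion
  }
  invisible(out)
}
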