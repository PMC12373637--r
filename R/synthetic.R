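#' Simulate a two-class negative-binomial count matrix with planted DE
#'
#' Gene relative abundances are log-normal; library sizes are uniform in
#' `lib_size_range`; counts are NB with variance `mu + dispersion * mu^2`
#' (`dispersion = 0` gives Poisson counts). A `de_fraction` of genes gets a
#' `+/-lfc` log2 fold change applied in class B, with balanced signs and no
#' renormalization, so the matrix carries realistic composition bias.
#' Reproducible bit-for-bit given `seed`.
#'
#' @param n_genes Number of genes (>= 100; default 10000).
#' @param n_per_class Samples per class (>= 2; default 3).
#' @param dispersion NB dispersion (default 0.1).
#' @param lib_size_range Range of expected library sizes (default
#'   `c(8e5, 1.2e6)`).
#' @param de_fraction Fraction of differentially expressed genes in [0, 1)
#'   (default 0.1).
#' @param lfc Absolute log2 fold change of DE genes (default 2).
#' @param seed Integer seed.
#' @return List with `matrix` (an [expr_matrix()], classes `A`/`B` set) and
#'   `truth` (a `sim_truth`: `genes`, `de_genes` data frame with signed
#'   `lfc`, empty `enriched_sets`/`planted_clusters`, `seed`).
#' @export
simulate_counts <- function(n_genes = 10000L, n_per_class = 3L,
                            dispersion = 0.1,
                            lib_size_range = c(8e5, 1.2e6),
                            de_fraction = 0.1, lfc = 2, seed = 1L) {
  if (n_genes < 100L) stop("n_genes must be >= 100")
  if (n_per_class < 2L) stop("n_per_class must be >= 2")
  if (de_fraction < 0 || de_fraction >= 1) stop("de_fraction must be in [0, 1)")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (length(lib_size_range) != 2L || any(lib_size_range <= 0) ||
      lib_size_range[1L] > lib_size_range[2L])
    stop("lib_size_range must be an increasing positive pair")
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    rel <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.2)
    rel <- rel / sum(rel)
    n_samp <- 2L * n_per_class
    lib <- stats::runif(n_samp, lib_size_range[1L], lib_size_range[2L])
    samples <- sprintf("S%02d", seq_len(n_samp))
    classes <- rep(c("A", "B"), each = n_per_class)
    n_de <- round(de_fraction * n_genes)
    de_idx <- sort(sample.int(n_genes, n_de))
    sign_de <- rep_len(c(1, -1), n_de)
    fc <- rep(1, n_genes)
    fc[de_idx] <- 2^(sign_de * lfc)
    mu <- rel %o% lib
    b <- classes == "B"
    mu[, b] <- mu[, b] * fc
    counts <- if (dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), nrow = n_genes)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nrow = n_genes)
    }
    dimnames(counts) <- list(genes, samples)
    truth <- structure(list(
      genes = genes,
      de_genes = data.frame(gene = genes[de_idx],
                            lfc = sign_de * lfc,
                            stringsAsFactors = FALSE, row.names = NULL),
      enriched_sets = data.frame(name = character(0), sign = numeric(0),
                                 stringsAsFactors = FALSE),
      planted_clusters = list(),
      seed = as.integer(seed)), class = "sim_truth")
    list(matrix = expr_matrix(counts, classes), truth = truth)
  })
}

# Draw one enriched-style set: at least `de_frac` of `size` members from
# same-sign DE genes, remainder from non-DE genes.
.draw_enriched <- function(size, sgn, de_pool_up, de_pool_dn, bg_pool,
                           de_frac) {
  pool <- if (sgn > 0) de_pool_up else de_pool_dn
  n_de <- ceiling(de_frac * size)
  if (n_de > length(pool))
    stop("not enough DE genes of sign ", sgn, " to plant an enriched set")
  c(sample(pool, n_de), sample(bg_pool, size - n_de))
}

#' Plant a gene-set database over simulated counts
#'
#' Builds a GMT-style database containing: `n_enriched` enriched sets
#' drawing at least 60% of members from same-sign differentially expressed
#' genes (signs alternate across sets); `n_decoy` decoy sets sampled
#' uniformly from non-DE genes; and `n_cluster_groups` groups of
#' `group_size` highly overlapping enriched-style sets, built by perturbing
#' a seed set so that every within-group pair has Jaccard similarity at
#' least `intra_overlap` while between-group similarity stays below 0.5
#' (constraint-checked after generation with bounded retries).
#'
#' @param truth A `sim_truth` from [simulate_counts()].
#' @param n_enriched Number of standalone enriched sets (default 5).
#' @param n_decoy Number of decoy sets (default 200).
#' @param size_range Set-size range, drawn uniformly (default `c(30, 30)`).
#' @param n_cluster_groups Number of overlapping groups (default 2).
#' @param group_size Sets per overlapping group (default 3).
#' @param intra_overlap Minimum within-group pairwise Jaccard (default 0.6).
#' @param de_member_fraction Minimum fraction of same-sign DE members in an
#'   enriched set (default 0.6).
#' @param seed Integer seed.
#' @return List with `db` (a [gene_set_db()]) and the updated `truth`
#'   (`enriched_sets` includes group members; `planted_clusters` lists the
#'   groups; `decoy_sets` names the decoys).
#' @export
simulate_genesets <- function(truth, n_enriched = 5L, n_decoy = 200L,
                              size_range = c(30L, 30L),
                              n_cluster_groups = 2L, group_size = 3L,
                              intra_overlap = 0.6,
                              de_member_fraction = 0.6, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (intra_overlap <= 0 || intra_overlap > 1)
    stop("intra_overlap must be in (0, 1]")
  de_up <- truth$de_genes$gene[truth$de_genes$lfc > 0]
  de_dn <- truth$de_genes$gene[truth$de_genes$lfc < 0]
  bg <- setdiff(truth$genes, truth$de_genes$gene)
  sizes <- size_range[1L]:size_range[2L]
  draw_size <- function() sizes[sample.int(length(sizes), 1L)]
  with_seed(seed, {
    sets <- list(); descs <- character(0)
    enr <- data.frame(name = character(0), sign = numeric(0),
                      stringsAsFactors = FALSE)
    for (i in seq_len(n_enriched)) {
      sgn <- if (i %% 2L == 1L) 1 else -1
      nm <- sprintf("PLANTED_%s_%02d", if (sgn > 0) "UP" else "DOWN", i)
      sets[[nm]] <- .draw_enriched(draw_size(), sgn, de_up, de_dn, bg,
                                   de_member_fraction)
      descs[nm] <- "planted enriched set"
      enr <- rbind(enr, data.frame(name = nm, sign = sgn,
                                   stringsAsFactors = FALSE))
    }
    planted_clusters <- list()
    for (g in seq_len(n_cluster_groups)) {
      sgn <- if (g %% 2L == 1L) 1 else -1
      size <- draw_size()
      # members replaced per variant; m chosen so that two variants with
      # disjoint replacements still satisfy J >= (size-2m)/(size+2m)
      m <- max(1L, floor(size * (1 - intra_overlap) /
                           (2 * (1 + intra_overlap))))
      group_names <- character(0)
      for (attempt in 1:50) {
        seed_set <- .draw_enriched(size, sgn, de_up, de_dn, bg,
                                   de_member_fraction)
        # only background positions are swapped out, so every variant keeps
        # the seed set's full complement of same-sign DE members
        bg_pos <- which(!seed_set %in% c(de_up, de_dn))
        if (length(bg_pos) < m) stop("overlap constraints infeasible: ",
                                     "too few background members to perturb")
        variants <- list(seed_set)
        for (v in 2:group_size) {
          repl <- bg_pos[sample.int(length(bg_pos), m)]
          fresh <- sample(setdiff(bg, unlist(variants)), m)
          var <- seed_set
          var[repl] <- fresh
          variants[[v]] <- var
        }
        ok <- all(utils::combn(group_size, 2L, FUN = function(p)
          jaccard(variants[[p[1L]]], variants[[p[2L]]])) >= intra_overlap)
        if (ok) {
          ok <- all(vapply(sets, function(s)
            jaccard(s, unlist(variants)) < 0.5, TRUE))
        }
        if (ok) {
          group_names <- sprintf("PLANTED_GROUP%d_SET%d", g,
                                 seq_len(group_size))
          for (v in seq_len(group_size)) {
            sets[[group_names[v]]] <- variants[[v]]
            descs[group_names[v]] <- sprintf("planted overlap group %d", g)
            enr <- rbind(enr, data.frame(name = group_names[v], sign = sgn,
                                         stringsAsFactors = FALSE))
          }
          break
        }
      }
      if (length(group_names) == 0L)
        stop("could not satisfy overlap constraints for group ", g,
             " after 50 attempts")
      planted_clusters[[sprintf("GROUP%d", g)]] <- group_names
    }
    decoy_names <- sprintf("DECOY_%03d", seq_len(n_decoy))
    for (nm in decoy_names) {
      sets[[nm]] <- sample(bg, draw_size())
      descs[nm] <- "decoy set"
    }
    truth$enriched_sets <- enr
    truth$planted_clusters <- planted_clusters
    truth$decoy_sets <- decoy_names
    list(db = gene_set_db(sets, descs, source = "simulated"),
         truth = truth)
  })
}

#' Write simulated fixtures to disk
#'
#' Standard formats only: counts TSV, gene sets GMT, and a JSON truth file.
#'
#' @param x The simulated [expr_matrix()].
#' @param db A planted [gene_set_db()].
#' @param truth The matching `sim_truth`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(x, db, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(x, file.path(dir, "counts.tsv"))
  write_gmt(db, file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(
    list(seed = truth$seed,
         de_genes = truth$de_genes,
         enriched_sets = truth$enriched_sets,
         planted_clusters = truth$planted_clusters,
         decoy_sets = truth$decoy_sets %||% character(0)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
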