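#' Gene-set database
#'
#' An ordered collection of named gene sets, as parsed from a GMT file. Set
#' names must be unique and every set must have at least one member; members
#' are stored as uppercased, de-duplicated identifier vectors.
#'
#' @param sets Named list of character vectors (members per set).
#' @param descriptions Optional named character vector of free-text
#'   descriptions, one per set; missing entries default to `""`.
#' @param source Provenance text (e.g. the file the database came from).
#' @return An object of class `gene_set_db`.
#' @export
gene_set_db <- function(sets, descriptions = NULL, source = "") {
  if (!is.list(sets) || length(sets) == 0L)
    stop("'sets' must be a non-empty named list of character vectors")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every gene set must have a non-empty name")
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1L])
  sets <- lapply(sets, function(m) {
    m <- as.character(m)
    m <- m[nzchar(m)]
    unique(m)
  })
  if (any(lengths(sets) == 0L))
    stop("gene set with no members: ", nm[lengths(sets) == 0L][1L])
  desc <- rep("", length(sets))
  names(desc) <- nm
  if (!is.null(descriptions)) desc[names(descriptions)] <- descriptions
  structure(list(sets = sets, descriptions = desc, source = source),
            class = "gene_set_db")
}

#' @export
length.gene_set_db <- function(x) length(x$sets)

#' @export
names.gene_set_db <- function(x) names(x$sets)

#' @export
print.gene_set_db <- function(x, ...) {
  cat(sprintf("gene_set_db: %d sets, member counts %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Subset a gene-set database by set name
#'
#' @param db A `gene_set_db`.
#' @param keep Character vector of set names to retain (order preserved as
#'   given in `keep`).
#' @return A `gene_set_db` with only the requested sets.
#' @export
subset_gene_sets <- function(db, keep) {
  stopifnot(inherits(db, "gene_set_db"))
  missing <- setdiff(keep, names(db$sets))
  if (length(missing))
    stop("gene set not in database: ", missing[1L])
  gene_set_db(db$sets[keep], db$descriptions[keep], db$source)
}

#' Ranked gene list
#'
#' Genes with unique, finite, signed scores ordered descending by score;
#' exact score ties are ordered lexicographically by gene identifier so the
#' ordering is deterministic.
#'
#' @param gene Character vector of unique gene identifiers.
#' @param score Numeric vector of finite scores, one per gene.
#' @return A data frame of class `ranked_list` with columns `gene`, `score`,
#'   sorted descending by score.
#' @export
ranked_list <- function(gene, score) {
  gene <- as.character(gene)
  score <- as.numeric(score)
  if (length(gene) != length(score) || length(gene) == 0L)
    stop("'gene' and 'score' must be non-empty and of equal length")
  if (any(!is.finite(score)))
    stop("ranked-list scores must be finite")
  if (anyDuplicated(gene))
    stop("duplicate gene in ranked list: ", gene[duplicated(gene)][1L])
  o <- order(-score, gene, method = "radix")
  structure(data.frame(gene = gene[o], score = score[o],
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ranked_list", "data.frame"))
}

#' Expression count matrix with a two-class sample assignment
#'
#' @param counts Numeric matrix, genes x samples, non-negative, with unique
#'   row (gene) and column (sample) names.
#' @param classes Optional named vector/factor mapping every sample to one of
#'   exactly two class labels. May be left `NULL` and attached later with
#'   [set_classes()].
#' @return An object of class `expr_matrix` with elements `counts` and
#'   `classes`.
#' @export
expr_matrix <- function(counts, classes = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("expression matrix is empty")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifier: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample name: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  if (any(!is.finite(counts)))
    stop("counts must be finite (no NA/NaN/Inf)")
  if (any(counts < 0))
    stop("counts must be non-negative")
  x <- structure(list(counts = counts, classes = NULL), class = "expr_matrix")
  if (!is.null(classes)) x <- set_classes(x, classes)
  x
}

#' Attach the two-class sample assignment
#'
#' @param x An `expr_matrix`.
#' @param classes Vector or factor of class labels. If named, names must
#'   cover all samples; if unnamed, labels are taken in column order.
#' @return `x` with `classes` set as a two-level factor named by sample.
#' @export
set_classes <- function(x, classes) {
  stopifnot(inherits(x, "expr_matrix"))
  samples <- colnames(x$counts)
  cls <- as.character(classes)
  if (!is.null(names(classes))) {
    if (!all(samples %in% names(classes)))
      stop("classes must name every sample")
    cls <- cls[match(samples, names(classes))]
  } else if (length(cls) != length(samples)) {
    stop("unnamed classes must have one label per sample (in column order)")
  }
  if (anyNA(cls) || any(!nzchar(cls)))
    stop("every sample needs a class label")
  lev <- sort(unique(cls))
  if (length(lev) != 2L)
    stop("exactly two classes are required, got: ",
         paste(lev, collapse = ", "))
  x$classes <- factor(cls, levels = lev)
  names(x$classes) <- samples
  x
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples", nrow(x$counts),
              ncol(x$counts)))
  if (!is.null(x$classes))
    cat(sprintf(" (classes: %s)",
                paste(sprintf("%s=%d", levels(x$classes),
                              tabulate(x$classes)), collapse = ", ")))
  cat("\n")
  invisible(x)
}

# Library sizes (column sums) of an expression matrix.
lib_sizes <- function(x) colSums(x$counts)

# Column indices of the two classes, as a list keyed by level.
class_index <- function(x) {
  if (is.null(x$classes)) stop("sample classes are not set")
  split(seq_len(ncol(x$counts)), x$classes)
}
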