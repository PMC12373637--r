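#' Read a GMT gene-set database
#'
#' One set per line: name, description, then one or more member genes, all
#' tab-separated. Member symbols are uppercased and de-duplicated within a
#' line; Ensembl version suffixes are stripped. Line order is preserved.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_db()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d (fewer than 3 tab-separated fields) in %s",
                 line_no[bad[1L]], path))
  nm <- vapply(fields, `[[`, "", 1L)
  if (any(!nzchar(nm)))
    stop(sprintf("empty gene-set name on GMT line %d",
                 line_no[which(!nzchar(nm))[1L]]))
  if (anyDuplicated(nm))
    stop("duplicate gene-set name in GMT: ", nm[duplicated(nm)][1L])
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(norm_gene_ids(f[-(1:2)])))
  names(sets) <- nm
  names(desc) <- nm
  gene_set_db(sets, desc, source = path)
}

#' Write a gene-set database as GMT
#'
#' Emits the exact dialect [read_gmt()] expects, so the round trip
#' `read_gmt(write_gmt(db, f))` reproduces `db`.
#'
#' @param db A [gene_set_db()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "gene_set_db"))
  if (length(db$sets) == 0L) stop("refusing to write an empty database")
  lines <- vapply(names(db$sets), function(nm) {
    paste(c(nm, db$descriptions[[nm]], db$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a pre-ranked gene list (RNK)
#'
#' Two tab-separated columns, gene and score. Lines starting with `#` and
#' blank lines are skipped. Scores must parse as finite reals and genes must
#' be unique; the list is re-sorted descending by score (ties broken
#' lexicographically) regardless of file order.
#'
#' @param path Path to an RNK file.
#' @return A [ranked_list()].
#' @export
read_rnk <- function(path) {
  if (!file.exists(path)) stop("RNK file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("RNK file has no data lines: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop(sprintf("malformed RNK line %d (expected gene<TAB>score) in %s",
                 line_no[bad[1L]], path))
  gene <- norm_gene_ids(vapply(fields, `[[`, "", 1L))
  score_txt <- vapply(fields, `[[`, "", 2L)
  score <- suppressWarnings(as.numeric(score_txt))
  bad <- which(!is.finite(score))
  if (length(bad))
    stop(sprintf("non-numeric or non-finite score '%s' on RNK line %d",
                 score_txt[bad[1L]], line_no[bad[1L]]))
  if (anyDuplicated(gene))
    stop("duplicate gene in RNK file: ", gene[duplicated(gene)][1L])
  ranked_list(gene, score)
}

#' Write a ranked list as RNK
#'
#' @param ranks A [ranked_list()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranks, path) {
  stopifnot(inherits(ranks, "ranked_list"))
  writeLines(paste(ranks$gene, format_num(ranks$score), sep = "\t"), path)
  invisible(path)
}
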