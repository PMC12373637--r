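#' Read an expression count table (TSV or CSV)
#'
#' The first row is a header of sample names (with or without a leading
#' label for the gene column) and the first column holds gene identifiers.
#' The delimiter is chosen from the file extension (`.csv` vs anything else)
#' or, for `auto` with an unknown extension, sniffed from the header line.
#'
#' @param path Path to the table.
#' @param delimiter `"auto"`, `"tab"` or `"comma"`.
#' @return An [expr_matrix()] with classes unset.
#' @export
read_expression <- function(path, delimiter = c("auto", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- switch(delimiter, tab = "\t", comma = ",", auto = {
    ext <- tolower(tools::file_ext(path))
    if (ext == "csv") "," else if (ext %in% c("tsv", "txt", "tab")) "\t" else {
      first <- readLines(path, n = 1L)
      n_tab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
      n_com <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
      if (n_com > n_tab) "," else "\t"
    }
  })
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  hdr <- gsub('^"|"$', "", trimws(hdr))
  body <- utils::read.table(path, sep = sep, skip = 1L, header = FALSE,
                            colClasses = "character", quote = "\"",
                            comment.char = "", fill = FALSE,
                            stringsAsFactors = FALSE)
  if (nrow(body) == 0L) stop("expression table has no data rows: ", path)
  if (ncol(body) < 2L) stop("expression table needs a gene column plus >= 1 sample")
  samples <- if (length(hdr) == ncol(body)) hdr[-1L]
             else if (length(hdr) == ncol(body) - 1L) hdr
             else stop("header/body column mismatch in ", path)
  if (any(!nzchar(samples))) stop("empty sample name in header of ", path)
  if (anyDuplicated(samples))
    stop("duplicate sample name: ", samples[duplicated(samples)][1L])
  genes <- norm_gene_ids(body[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene row: ", genes[duplicated(genes)][1L])
  counts <- suppressWarnings(
    vapply(body[-1L], as.numeric, numeric(nrow(body))))
  counts <- matrix(counts, nrow = nrow(body),
                   dimnames = list(genes, samples))
  if (any(!is.finite(counts)))
    stop("non-numeric entry in expression table ", path)
  if (any(counts < 0))
    stop("negative count in expression table ", path)
  expr_matrix(counts)
}

#' Write an expression matrix as TSV
#'
#' @param x An [expr_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  header <- paste(c("gene", colnames(x$counts)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x$counts)), function(i) {
    paste(c(rownames(x$counts)[i], format_num(x$counts[i, ])),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}
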