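#' @useDynLib enrichmapr, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Normalize gene identifiers so symbols join reliably across expression, RNK
# and GMT inputs: uppercase HGNC symbols; Ensembl IDs keep their case class
# (already upper) but lose a trailing version suffix (".N").
norm_gene_ids <- function(x) {
  x <- toupper(trimws(as.character(x)))
  ens <- grepl("^ENS[A-Z]*[0-9]{6,}", x)
  x[ens] <- sub("\\.[0-9]+$", "", x[ens])
  x
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# global random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

geo_mean <- function(x) exp(mean(log(x)))

# Full-precision decimal formatting for text exports: shortest of 15/17
# significant digits that round-trips through as.numeric() exactly, "."
# decimal separator, no grouping. Exact round-trip keeps re-imported ranks
# and results bit-identical to the in-memory values.
format_num <- function(x) {
  out <- trimws(formatC(x, digits = 15, format = "g", flag = "-"))
  bad <- suppressWarnings(as.numeric(out)) != x
  bad[is.na(bad)] <- FALSE
  if (any(bad))
    out[bad] <- trimws(formatC(x[bad], digits = 17, format = "g", flag = "-"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
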