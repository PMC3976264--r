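#' Construct an aggregated Ct table
#'
#' A `ct_table` holds one aggregated Ct value (cycles) per sample and miR,
#' plus the expression ceiling used during pre-processing.  Values on the
#' raw Ct scale are bounded above by the ceiling; normalized tables
#' (see [geom_mean_normalize()]) carry real-valued delta-Ct entries and
#' drop the bound.
#'
#' @param values numeric matrix, samples in rows, miRs in columns; both
#'   dimensions must be named.
#' @param ceiling Ct value representing "not expressed" (default 34);
#'   `NA` for normalized tables.
#' @param normalized logical; `TRUE` once per-sample geometric-mean
#'   normalization has been applied.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(values, ceiling = 34, normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have sample row names and miR column names")
  }
  if (anyNA(values)) stop("ct_table values must be complete (no NA)")
  if (!normalized && !is.na(ceiling) && any(values > ceiling + 1e-9)) {
    stop("raw Ct values must not exceed the ceiling (", ceiling, ")")
  }
  structure(
    list(values = values,
         sample_ids = rownames(values),
         mir_ids = colnames(values),
         ceiling = ceiling,
         normalized = isTRUE(normalized)),
    class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d samples x %d miRs (%s, ceiling %s)\n",
              length(x$sample_ids), length(x$mir_ids),
              if (x$normalized) "normalized delta-Ct" else "raw Ct",
              format(x$ceiling)))
  print(head(x$values, 5L))
  if (length(x$sample_ids) > 5L) cat("...\n")
  invisible(x)
}

#' @export
dim.ct_table <- function(x) dim(x$values)

#' Write / read an aggregated Ct table
#'
#' The on-disk form is a delimited sample-by-miR matrix with a leading
#' `sample` column; values are printed with full precision so a
#' write-then-read round trip is exact to the printed digits.
#'
#' @param x a [ct_table()].
#' @param path file path.
#' @param ceiling,normalized metadata restored on read (not stored in the
#'   file itself).
#' @return `read_ct_table` returns a [ct_table()]; `write_ct_table`
#'   returns `path` invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  df <- data.frame(sample = x$sample_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path, ceiling = 34, normalized = FALSE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample") stop("first column must be 'sample'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  ct_table(m, ceiling = ceiling, normalized = normalized)
}
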