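#' Read replicate-level qPCR Ct exports
#'
#' Reads long-format delimited text with columns `sample`, `mir`,
#' `replicate`, `ct`.  Undetermined observations (tokens such as
#' `"Undetermined"`, `"NA"` or an empty field) are preserved as `NA` in
#' the `ct` column; they are only mapped to the expression ceiling later
#' by [apply_ceiling()].
#'
#' @param path path to the delimited file.
#' @param sep field separator (`","` default; `"\t"` accepted).
#' @param undetermined character tokens to treat as undetermined.
#' @param quiet suppress the row-count message.
#' @return A data frame with columns `sample`, `mir`, `replicate` and
#'   numeric `ct` (`NA` = undetermined).
#' @export
read_replicates <- function(path, sep = ",",
                            undetermined = c("Undetermined", "NA", ""),
                            quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, colClasses = "character",
                 check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("sample", "mir", "replicate", "ct")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  ct_raw <- trimws(df$ct)
  is_und <- ct_raw %in% undetermined
  ct <- suppressWarnings(as.numeric(ct_raw))
  bad <- which(!is_und & is.na(ct))
  if (length(bad) > 0L) {
    stop("unparseable ct value '", ct_raw[bad[1]], "' at line ",
         bad[1] + 1L)  # +1 for header
  }
  ct[is_und] <- NA_real_
  if (any(!is.na(ct) & ct <= 0)) {
    stop("finite Ct values must be positive (line ",
         which(!is.na(ct) & ct <= 0)[1] + 1L, ")")
  }
  out <- data.frame(sample = df$sample, mir = df$mir,
                    replicate = as.integer(df$replicate), ct = ct,
                    stringsAsFactors = FALSE)
  key <- paste(out$sample, out$mir, out$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (sample, mir, replicate) key: ",
         gsub("\r", ", ", d, fixed = TRUE))
  }
  if (!quiet) message("read ", nrow(out), " replicate records from ", path)
  out
}

#' Write a replicate table in the long-format dialect read by
#' [read_replicates()]
#'
#' @param replicates data frame with columns `sample`, `mir`,
#'   `replicate`, `ct` (`NA` = undetermined).
#' @param path output file path.
#' @param undetermined_token token written for `NA` Ct values.
#' @export
write_replicates <- function(replicates, path,
                             undetermined_token = "Undetermined") {
  df <- replicates[, c("sample", "mir", "replicate", "ct")]
  ct <- ifelse(is.na(df$ct), undetermined_token,
               format(df$ct, digits = 15, trim = TRUE, scientific = FALSE))
  df$ct <- ct
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects columns `sample`, `cohort`, `fluid`, `platform`, `risk`
#' (`low`/`high`).  Returns the table with an added numeric `label`
#' column (+1 = high risk, -1 = low risk).
#'
#' @param path path to delimited metadata file.
#' @param sep field separator.
#' @export
read_sample_meta <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  needed <- c("sample", "cohort", "fluid", "platform", "risk")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(df$risk %in% c("low", "high"))) {
    stop("risk must be 'low' or 'high' for every sample")
  }
  df$label <- ifelse(df$risk == "high", 1, -1)
  df
}

#' Apply the expression ceiling to replicate Ct values
#'
#' Ct values above the ceiling are considered not expressed and set to
#' the ceiling; undetermined observations are likewise set to the
#' ceiling.  Values exactly equal to the ceiling are kept.  The
#' operation is idempotent.
#'
#' @param replicates replicate data frame (see [read_replicates()]).
#' @param ceiling Ct value treated as "not expressed" (default 34).
#' @return The replicate table with no remaining `NA` values and
#'   attributes `ceiled = TRUE`, `ceiling` recording provenance.
#' @export
apply_ceiling <- function(replicates, ceiling = 34) {
  if (!is.numeric(ceiling) || length(ceiling) != 1L || ceiling <= 0) {
    stop("ceiling must be a single positive Ct value")
  }
  ct <- replicates$ct
  ct[is.na(ct) | ct > ceiling] <- ceiling
  replicates$ct <- ct
  attr(replicates, "ceiled") <- TRUE
  attr(replicates, "ceiling") <- ceiling
  replicates
}

#' Remove triplicate outliers by the 20% rule
#'
#' Within each (sample, miR) group of three or more replicates, a
#' replicate is an outlier when its relative deviation from the mean of
#' the remaining replicates exceeds `rel_threshold`
#' (|x - m| / m > threshold, m = mean of the others).  At most one
#' replicate — the worst offender — is removed per group, so a triplet
#' can never lose two values.  Groups of fewer than three replicates
#' pass through untouched.
#'
#' @param replicates replicate table, ceiling already applied.
#' @param rel_threshold relative deviation threshold (default 0.20).
#' @return A list with `replicates` (outliers dropped) and `report`
#'   (data frame of removals: sample, mir, replicate, ct, deviation).
#' @export
remove_replicate_outliers <- function(replicates, rel_threshold = 0.20) {
  if (!isTRUE(attr(replicates, "ceiled"))) {
    warning("replicate table has no ceiling provenance; ",
            "apply_ceiling() should run first")
  }
  if (anyNA(replicates$ct)) stop("undetermined values present; apply_ceiling() first")
  key <- paste(replicates$sample, replicates$mir, sep = "\r")
  drop <- logical(nrow(replicates))
  rep_rows <- split(seq_len(nrow(replicates)), key)
  removals <- list()
  for (rows in rep_rows) {
    if (length(rows) < 3L) next
    x <- replicates$ct[rows]
    dev <- vapply(seq_along(x), function(i) {
      m <- mean(x[-i])
      abs(x[i] - m) / m
    }, numeric(1))
    if (any(dev > rel_threshold)) {
      worst <- which.max(dev)
      drop[rows[worst]] <- TRUE
      removals[[length(removals) + 1L]] <- data.frame(
        sample = replicates$sample[rows[worst]],
        mir = replicates$mir[rows[worst]],
        replicate = replicates$replicate[rows[worst]],
        ct = x[worst], deviation = dev[worst],
        stringsAsFactors = FALSE)
    }
  }
  report <- if (length(removals) > 0L) {
    do.call(rbind, removals)
  } else {
    data.frame(sample = character(), mir = character(),
               replicate = integer(), ct = numeric(),
               deviation = numeric(), stringsAsFactors = FALSE)
  }
  out <- replicates[!drop, , drop = FALSE]
  attr(out, "ceiled") <- attr(replicates, "ceiled")
  attr(out, "ceiling") <- attr(replicates, "ceiling")
  attr(out, "outliers_removed") <- TRUE
  list(replicates = out, report = report)
}

#' Aggregate surviving replicates to a sample-by-miR Ct matrix
#'
#' @param replicates replicate table after ceiling and outlier removal.
#' @param method `"mean"` (default) or `"median"`.
#' @param ceiling expression ceiling recorded in the output; defaults to
#'   the provenance attribute set by [apply_ceiling()].
#' @return A [ct_table()] with one value per (sample, miR); any
#'   combination with no surviving replicate is set to the ceiling with
#'   a warning.
#' @export
aggregate_replicates <- function(replicates, method = c("mean", "median"),
                                 ceiling = attr(replicates, "ceiling")) {
  method <- match.arg(method)
  if (!isTRUE(attr(replicates, "outliers_removed"))) {
    warning("replicate table has no outlier-removal provenance; ",
            "remove_replicate_outliers() should run first")
  }
  if (is.null(ceiling)) ceiling <- 34
  samples <- unique(replicates$sample)
  mirs <- unique(replicates$mir)
  fun <- if (method == "mean") mean else median
  agg <- tapply(replicates$ct,
                list(factor(replicates$sample, levels = samples),
                     factor(replicates$mir, levels = mirs)),
                fun)
  if (anyNA(agg)) {
    warning(sum(is.na(agg)), " (sample, miR) combination(s) had no ",
            "surviving replicate; set to ceiling ", ceiling)
    agg[is.na(agg)] <- ceiling
  }
  m <- matrix(agg, nrow = length(samples), ncol = length(mirs),
              dimnames = list(samples, mirs))
  ct_table(m, ceiling = ceiling)
}

#' Flag and remove samples with low overall detection
#'
#' A sample is removed when the fraction of panel miRs sitting at the
#' expression ceiling (i.e. undetected) exceeds `max_ceiling_fraction`.
#'
#' @param ct a raw-scale [ct_table()].
#' @param max_ceiling_fraction maximum tolerated fraction of undetected
#'   panel miRs per sample (default 0.5).
#' @return A list with `ct` (filtered table) and `report` (data frame of
#'   every sample with its undetected fraction and removal flag).
#' @export
flag_low_detection_samples <- function(ct, max_ceiling_fraction = 0.5) {
  stopifnot(inherits(ct, "ct_table"))
  if (ct$normalized || is.na(ct$ceiling)) {
    stop("detection QC applies to raw Ct tables with a ceiling")
  }
  frac <- rowMeans(ct$values >= ct$ceiling - 1e-9)
  removed <- frac > max_ceiling_fraction
  if (all(removed)) stop("all samples fail the detection threshold")
  report <- data.frame(sample = ct$sample_ids,
                       ceiling_fraction = unname(frac),
                       removed = unname(removed),
                       stringsAsFactors = FALSE)
  out <- ct_table(ct$values[!removed, , drop = FALSE],
                  ceiling = ct$ceiling)
  list(ct = out, report = report)
}

#' PSA doubling time by the log-slope method
#'
#' Fits least squares of natural-log PSA against time and converts the
#' slope to a doubling time: ln(2) / slope, in months.  (Equivalently,
#' the reciprocal of the base-2 log slope.)  A non-positive slope means
#' PSA is not rising; `Inf` is returned.
#'
#' @param time_years observation times in years (strictly increasing).
#' @param psa PSA values in ng/ml (> 0).
#' @return Doubling time in months, or `Inf` when PSA is not rising.
#' @export
psa_doubling_time <- function(time_years, psa) {
  if (length(time_years) != length(psa) || length(psa) < 2L) {
    stop("need at least 2 matched (time, PSA) points")
  }
  if (any(psa <= 0)) stop("PSA values must be positive")
  if (any(diff(time_years) <= 0)) stop("times must be strictly increasing")
  slope <- unname(coef(lm(log(psa) ~ time_years))[2])  # per year
  if (!is.finite(slope) || slope <= 0) return(Inf)
  (log(2) / slope) * 12
}
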