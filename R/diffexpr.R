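#' Per-miR group means
#'
#' @param ct a [ct_table()].
#' @param labels +1/-1 risk labels (named or in sample order).
#' @return Data frame with `mir`, `mean_low`, `mean_high`.
#' @export
group_means <- function(ct, labels) {
  stopifnot(inherits(ct, "ct_table"))
  labels <- align_labels(labels, ct$sample_ids)
  if (!any(labels == -1) || !any(labels == 1)) {
    stop("both risk groups must be non-empty")
  }
  data.frame(
    mir = ct$mir_ids,
    mean_low = colMeans(ct$values[labels == -1, , drop = FALSE]),
    mean_high = colMeans(ct$values[labels == 1, , drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Delta-delta-Ct and fold change from group means
#'
#' ddCt = mean_high - mean_low; fold change = 2^ddCt.  This is the sign
#' convention that reproduces published qPCR summary tables in which a
#' positive ddCt row carries a fold change above 1; note that on the Ct
#' scale a *higher* Ct means *less* template, so no abundance direction
#' is asserted here.
#'
#' @param mean_low,mean_high group-mean Ct values (vectorized).
#' @return Data frame with `ddct` and `fold_change`.
#' @export
ddct_fold_change <- function(mean_low, mean_high) {
  stopifnot(is.finite(mean_low), is.finite(mean_high))
  ddct <- mean_high - mean_low
  data.frame(ddct = ddct, fold_change = 2^ddct)
}

#' Two-group t-test p-value
#'
#' @param values_low,values_high Ct (or delta-Ct) values for the two
#'   groups; at least 2 per group.
#' @param variant `"welch"` (unequal variances, default) or `"pooled"`.
#' @return Two-sided p-value; degenerate inputs (zero variance in both
#'   groups) return 1 with a warning.
#' @export
two_group_ttest <- function(values_low, values_high,
                            variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(values_low) < 2L || length(values_high) < 2L) {
    stop("need >= 2 samples per group")
  }
  if (var(values_low) + var(values_high) == 0) {
    warning("zero variance in both groups; p set to 1")
    return(1)
  }
  t.test(values_low, values_high, var.equal = variant == "pooled")$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' q(i) = min over j >= i of p(j) * m / j, capped at 1 and returned in
#' the input order.  `m` defaults to the number of p-values but can be
#' raised when the tested family was larger than the reported list
#' (e.g. an assay whose p-value was never printed).
#'
#' @param p p-values in (0, 1].
#' @param m size of the hypothesis family (>= `length(p)`).
#' @return Adjusted q-values in input order.
#' @export
benjamini_hochberg <- function(p, m = length(p)) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (m < length(p)) stop("m must be >= length(p)")
  p.adjust(p, method = "BH", n = m)
}

#' Differential-expression table
#'
#' One row per panel miR with group means, delta-delta-Ct, fold change,
#' t-test p-value and Benjamini-Hochberg q-value, sorted by descending
#' ddCt — the layout of a standard qPCR biomarker summary table.
#'
#' @param ct a [ct_table()] (conventionally raw aggregated Ct).
#' @param labels +1/-1 risk labels.
#' @param variant t-test variant, see [two_group_ttest()].
#' @param m size of the BH family; default = panel size.
#' @return Data frame with columns `mir`, `mean_low`, `mean_high`,
#'   `ddct`, `fold_change`, `p_value`, `q_value`.
#' @export
de_table <- function(ct, labels, variant = c("welch", "pooled"), m = NULL) {
  variant <- match.arg(variant)
  labels <- align_labels(labels, ct$sample_ids)
  gm <- group_means(ct, labels)
  dd <- ddct_fold_change(gm$mean_low, gm$mean_high)
  p <- vapply(ct$mir_ids, function(mir) {
    two_group_ttest(ct$values[labels == -1, mir],
                    ct$values[labels == 1, mir], variant = variant)
  }, numeric(1))
  if (is.null(m)) m <- length(p)
  out <- cbind(gm, dd,
               data.frame(p_value = unname(p),
                          q_value = benjamini_hochberg(unname(p), m = m)))
  out[order(-out$ddct), , drop = FALSE]
}

#' Write a differential-expression table as delimited text
#'
#' @param de data frame from [de_table()].
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  write.csv(de, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
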