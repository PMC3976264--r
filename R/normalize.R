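#' Assess a candidate endogenous control
#'
#' Scores a panel miR on the three failure modes that disqualify an
#' endogenous control in biofluid qPCR: poor detection, high variance
#' relative to the rest of the panel, and risk-group dependence.
#'
#' @param ct a raw-scale [ct_table()].
#' @param labels +1/-1 risk labels (named or in sample order).
#' @param control miR id of the candidate control.
#' @param min_detection minimum fraction of samples with Ct below the
#'   ceiling (default 0.5).
#' @param max_sd_rank controls whose Ct standard deviation ranks in the
#'   top `max_sd_rank` of the panel are unsuitable (default 3;
#'   rank 1 = highest sd).
#' @param max_group_p two-sided p-value threshold below which the
#'   control is considered group-dependent (default 0.05).
#' @return A one-row data frame: `mir`, `detection_fraction`, `sd_ct`,
#'   `sd_rank`, `group_diff_p`, `suitable`.
#' @export
assess_control <- function(ct, labels, control, min_detection = 0.5,
                           max_sd_rank = 3, max_group_p = 0.05) {
  stopifnot(inherits(ct, "ct_table"))
  if (!control %in% ct$mir_ids) stop("unknown miR id: ", control)
  labels <- align_labels(labels, ct$sample_ids)
  v <- ct$values[, control]
  detection <- if (is.na(ct$ceiling)) 1 else mean(v < ct$ceiling - 1e-9)
  sds <- apply(ct$values, 2, sd)
  sd_rank <- unname(rank(-sds, ties.method = "min")[control])
  p <- two_group_ttest(v[labels == -1], v[labels == 1])
  suitable <- detection >= min_detection && sd_rank > max_sd_rank &&
    p >= max_group_p
  data.frame(mir = control, detection_fraction = detection,
             sd_ct = unname(sds[control]), sd_rank = sd_rank,
             group_diff_p = p, suitable = suitable,
             stringsAsFactors = FALSE)
}

#' Geometric-mean normalization of a Ct table
#'
#' Subtracts from each sample's Ct values the arithmetic mean Ct across
#' the (non-excluded) panel, which equals normalizing each sample by the
#' geometric mean of its expression values on the linear scale.  This
#' removes per-sample loading/input offsets exactly.  Excluded miRs
#' (e.g. a rejected endogenous control) contribute nothing to the mean
#' and are dropped from the output.
#'
#' @param ct a [ct_table()].
#' @param exclude miR ids to leave out of the reference mean and output.
#' @return A normalized [ct_table()] of per-sample delta-Ct values; each
#'   sample's values average to zero.
#' @export
geom_mean_normalize <- function(ct, exclude = character()) {
  stopifnot(inherits(ct, "ct_table"))
  keep <- setdiff(ct$mir_ids, exclude)
  if (length(keep) < 2L) stop("need at least 2 non-excluded miRs")
  v <- ct$values[, keep, drop = FALSE]
  v <- v - rowMeans(v)
  ct_table(v, ceiling = NA_real_, normalized = TRUE)
}
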