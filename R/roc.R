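#' ROC curve and AUC
#'
#' Builds the ROC curve by sweeping a threshold down the sorted decision
#' scores (tied scores move as a block) and computes the AUC as the
#' trapezoidal area, which equals the Mann-Whitney pair-counting
#' statistic: (concordant positive-negative pairs + ties/2) /
#' (n_pos * n_neg).
#'
#' @param scores numeric decision values; higher = more positive.
#' @param y +1/-1 labels.
#' @return A list of class `roc_result`: `auc`, `curve` (data frame of
#'   `fpr`, `tpr`, starting at (0,0) and ending at (1,1)), `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, y) {
  y <- align_labels(y, names(scores) %||% as.character(seq_along(scores)))
  n_pos <- sum(y == 1); n_neg <- sum(y == -1)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys == 1); fp <- cumsum(ys == -1)
  # collapse tied scores: keep the last index of each tie block
  last <- c(ss[-length(ss)] != ss[-1], TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(auc = auc,
                 curve = data.frame(fpr = fpr, tpr = tpr),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d pos / %d neg)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}
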