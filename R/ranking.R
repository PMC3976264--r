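#' Feature rankings for two-group panels
#'
#' `tscore_rank()` scores feature i by the two-sample t statistic
#' (mu_high - mu_low) / sqrt(s2_high/M_high + s2_low/M_low) and ranks by
#' descending absolute score.  `centroid_rank()` scores by the magnitude
#' of the between-class mean difference |mu_high - mu_low| and ranks by
#' descending score, ignoring variances.  Ties are broken by
#' lexicographic feature name, deterministically.
#'
#' @param X numeric matrix, samples in rows, named feature columns.
#' @param y +1/-1 labels (named or in row order).
#' @return A list of class `feature_ranking` with `method`, `scores`
#'   (named, signed for tscore) and `order` (feature names, best first).
#' @export
tscore_rank <- function(X, y) {
  r <- rank_features(X, y, "tscore")
  r
}

#' @rdname tscore_rank
#' @export
centroid_rank <- function(X, y) {
  rank_features(X, y, "centroid")
}

rank_features <- function(X, y, method) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have named feature columns")
  y <- align_labels(y, rownames(X) %||% as.character(seq_len(nrow(X))))
  hi <- X[y == 1, , drop = FALSE]
  lo <- X[y == -1, , drop = FALSE]
  if (nrow(hi) < 2L || nrow(lo) < 2L) {
    if (method == "tscore") stop("tscore ranking needs >= 2 samples per class")
  }
  dmean <- colMeans(hi) - colMeans(lo)
  if (method == "tscore") {
    se2 <- apply(hi, 2, var) / nrow(hi) + apply(lo, 2, var) / nrow(lo)
    scores <- ifelse(se2 == 0, 0, dmean / sqrt(se2))
    if (any(se2 == 0)) {
      warning("zero variance in both classes for feature(s): ",
              paste(colnames(X)[se2 == 0], collapse = ", "),
              "; score set to 0")
    }
  } else {
    scores <- abs(dmean)
  }
  ord <- colnames(X)[order(-abs(scores), colnames(X))]
  structure(list(method = method, scores = scores, order = ord),
            class = "feature_ranking")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_ranking <- function(x, ...) {
  cat("feature_ranking (", x$method, "): ",
      paste(x$order, collapse = " > "), "\n", sep = "")
  invisible(x)
}
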