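# Stratified Monte-Carlo train/test splits.  Returns a list of logical
# train-row masks; each split holds out ~test_fraction of every class.
stratified_splits <- function(y, n_splits, test_fraction, seed,
                              min_train_per_class = 2L, retry_cap = 100L) {
  idx_pos <- which(y == 1); idx_neg <- which(y == -1)
  n_test_pos <- max(1L, round(length(idx_pos) * test_fraction))
  n_test_neg <- max(1L, round(length(idx_neg) * test_fraction))
  if (length(idx_pos) - n_test_pos < min_train_per_class ||
      length(idx_neg) - n_test_neg < min_train_per_class) {
    stop("not enough samples per class for stratified splitting")
  }
  with_seed(seed, {
    lapply(seq_len(n_splits), function(i) {
      for (attempt in seq_len(retry_cap)) {
        test <- c(sample(idx_pos, n_test_pos), sample(idx_neg, n_test_neg))
        train <- setdiff(seq_along(y), test)
        if (length(unique(y[train])) == 2L) {
          return(!seq_along(y) %in% test)
        }
      }
      stop("could not draw a two-class training split")
    })
  })
}

#' Feature-selection stability under Monte-Carlo cross-validation
#'
#' For each of `n_splits` stratified random training subsets, ranks the
#' panel features on the training rows only; for every n up to
#' `top_max`, records whether each feature falls in that split's top-n.
#' The reported percentages quantify how stable a ranking is under
#' resampling — an unstable panel shows percentages drifting across
#' many features.
#'
#' @param X sample-by-feature matrix with named columns.
#' @param y +1/-1 labels.
#' @param method `"tscore"` or `"centroid"`.
#' @param n_splits number of Monte-Carlo resamples (default 30).
#' @param top_max largest top-n reported (default 8).
#' @param test_fraction held-out fraction per split (default 1/3).
#' @param seed RNG seed for the split sequence.
#' @return A list of class `stability_table`: `percent` (feature x
#'   top-n matrix, rounded to integers for display), `fraction` (raw
#'   fractions), `method`, `n_splits`, `seed`.  Rows are sorted by
#'   descending top-1, then top-2, ... percentage.
#' @export
stability_table <- function(X, y, method = c("tscore", "centroid"),
                            n_splits = 30, top_max = 8,
                            test_fraction = 1 / 3, seed = 1) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- align_labels(y, rownames(X) %||% as.character(seq_len(nrow(X))))
  top_max <- min(top_max, ncol(X))
  splits <- stratified_splits(y, n_splits, test_fraction, seed)
  counts <- matrix(0L, ncol(X), top_max,
                   dimnames = list(colnames(X), paste0("top", seq_len(top_max))))
  for (train in splits) {
    ord <- rank_features(X[train, , drop = FALSE], y[train], method)$order
    for (n in seq_len(top_max)) {
      counts[ord[seq_len(n)], n] <- counts[ord[seq_len(n)], n] + 1L
    }
  }
  fraction <- counts / n_splits
  ord <- do.call(order, c(as.data.frame(-fraction), list(rownames(fraction))))
  structure(list(percent = round(100 * fraction[ord, , drop = FALSE]),
                 fraction = fraction[ord, , drop = FALSE],
                 method = method, n_splits = n_splits, seed = seed),
            class = "stability_table")
}

#' @export
print.stability_table <- function(x, ...) {
  cat(sprintf("stability_table (%s, %d splits, seed %d):\n",
              x$method, x$n_splits, x$seed))
  print(x$percent)
  invisible(x)
}

#' Cross-validated AUC of a feature subset
#'
#' Trains a linear SVM on each stratified Monte-Carlo training subset
#' (restricted to `features`), scores the held-out samples, pools all
#' out-of-split decision values, and computes one ROC/AUC on the pooled
#' scores — the protocol that yields a single ROC curve.
#'
#' @inheritParams stability_table
#' @param features feature names to use.
#' @param C SVM regularization constant.
#' @return A `roc_result` (see [roc_auc()]).
#' @export
cv_auc <- function(X, y, features, n_splits = 30, test_fraction = 1 / 3,
                   seed = 1, C = 1) {
  X <- as.matrix(X)
  if (length(features) == 0L) stop("feature subset must be non-empty")
  missing <- setdiff(features, colnames(X))
  if (length(missing) > 0L) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  }
  y <- align_labels(y, rownames(X) %||% as.character(seq_len(nrow(X))))
  splits <- stratified_splits(y, n_splits, test_fraction, seed)
  pooled_scores <- numeric(0)
  pooled_y <- numeric(0)
  for (train in splits) {
    model <- train_linear_svm(X[train, features, drop = FALSE], y[train], C = C)
    s <- decision_values(model, X[!train, features, drop = FALSE])
    pooled_scores <- c(pooled_scores, unname(s))
    pooled_y <- c(pooled_y, y[!train])
  }
  roc_auc(pooled_scores, pooled_y)
}

#' Rank candidate feature subsets by cross-validated AUC
#'
#' @inheritParams cv_auc
#' @param candidates list of character vectors of feature names.
#' @return Data frame with `subset` (features joined by `+`), `size` and
#'   `auc`, sorted by descending AUC; ties broken by smaller subset,
#'   then subset name.
#' @export
evaluate_subsets <- function(X, y, candidates, n_splits = 30,
                             test_fraction = 1 / 3, seed = 1, C = 1) {
  if (length(candidates) == 0L) stop("candidates must be non-empty")
  rows <- lapply(candidates, function(feats) {
    r <- cv_auc(X, y, feats, n_splits = n_splits,
                test_fraction = test_fraction, seed = seed, C = C)
    data.frame(subset = paste(feats, collapse = "+"),
               size = length(feats), auc = r$auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$auc, out$size, out$subset), , drop = FALSE]
}

#' All non-empty subsets of a feature set
#'
#' Convenience for exhaustive small-panel subset searches.
#'
#' @param features character vector of feature names.
#' @return List of character vectors (2^k - 1 subsets).
#' @export
all_subsets <- function(features) {
  k <- length(features)
  if (k == 0L) stop("features must be non-empty")
  unlist(lapply(seq_len(k), function(n) {
    m <- utils::combn(features, n, simplify = FALSE)
    m
  }), recursive = FALSE)
}
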