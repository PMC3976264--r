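#' Default pipeline configuration
#'
#' @param ceiling expression ceiling (cycles).
#' @param outlier_threshold replicate outlier rule threshold.
#' @param aggregate replicate aggregation method.
#' @param max_ceiling_fraction sample detection-QC threshold.
#' @param normalize normalization before classification: `"geomean"` or
#'   `"none"`.  Differential expression is always computed on the raw
#'   aggregated Ct scale (the scale on which group means are reported).
#' @param exclude miR ids excluded from the geometric mean (e.g. a
#'   rejected endogenous control).
#' @param ttest t-test variant for differential expression.
#' @param n_splits,test_fraction,top_max Monte-Carlo CV parameters.
#' @param C SVM regularization constant.
#' @param candidate_subsets list of feature subsets to compare by CV
#'   AUC; `NULL` = all non-empty subsets of the top 3 t-score features.
#' @param model_features features of the final frozen model; `NULL` =
#'   the best candidate subset.
#' @param seed RNG seed recorded in every output.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(ceiling = 34, outlier_threshold = 0.20,
                       aggregate = "mean", max_ceiling_fraction = 0.5,
                       normalize = c("geomean", "none"),
                       exclude = character(), ttest = "welch",
                       n_splits = 30, test_fraction = 1 / 3, top_max = 8,
                       C = 1, candidate_subsets = NULL,
                       model_features = NULL, seed = 1) {
  normalize <- match.arg(normalize)
  structure(as.list(environment()), class = "run_config")
}

#' Pre-process replicate-level Ct data
#'
#' Runs the fixed pre-processing order: expression ceiling, replicate
#' outlier removal, aggregation, low-detection sample QC.
#'
#' @param replicates long-format replicate data frame.
#' @param config a [run_config()].
#' @return List with `ct` (a [ct_table()]), `outlier_report`,
#'   `qc_report`.
#' @export
preprocess_replicates <- function(replicates, config = run_config()) {
  r <- apply_ceiling(replicates, ceiling = config$ceiling)
  o <- remove_replicate_outliers(r, rel_threshold = config$outlier_threshold)
  ct <- aggregate_replicates(o$replicates, method = config$aggregate)
  qc <- flag_low_detection_samples(ct, config$max_ceiling_fraction)
  list(ct = qc$ct, outlier_report = o$report, qc_report = qc$report)
}

#' Run the discovery-cohort analysis
#'
#' Executes the full discovery workflow on replicate-level data:
#' pre-processing, differential expression on raw aggregated Ct,
#' normalization for classification, t-score and centroid
#' ranking-stability tables, candidate-subset CV AUC comparison, and a
#' final frozen linear SVM (trained on the full cohort with the chosen
#' features).  Deterministic given the config seed.
#'
#' @param replicates long-format replicate data frame.
#' @param labels +1/-1 risk labels (named by sample id).
#' @param config a [run_config()].
#' @return A list of class `discovery_report`: `config`, `ct`,
#'   `ct_class` (normalized or raw matrix used for classification),
#'   `de`, `stability` (tscore + centroid), `subset_aucs`, `model`
#'   (with frozen scaling and normalization provenance), `cv_roc`,
#'   `resubstitution_roc`, `outlier_report`, `qc_report`.
#' @export
run_discovery <- function(replicates, labels, config = run_config()) {
  pre <- preprocess_replicates(replicates, config)
  ct <- pre$ct
  labels <- align_labels(labels, ct$sample_ids)
  names(labels) <- ct$sample_ids
  de <- de_table(ct, labels, variant = config$ttest)

  ct_class <- if (config$normalize == "geomean") {
    geom_mean_normalize(ct, exclude = config$exclude)
  } else {
    ct
  }
  X <- ct_class$values

  stab <- list(
    tscore = stability_table(X, labels, "tscore",
                             n_splits = config$n_splits,
                             top_max = config$top_max,
                             test_fraction = config$test_fraction,
                             seed = config$seed),
    centroid = stability_table(X, labels, "centroid",
                               n_splits = config$n_splits,
                               top_max = config$top_max,
                               test_fraction = config$test_fraction,
                               seed = config$seed))

  candidates <- config$candidate_subsets
  if (is.null(candidates)) {
    top3 <- tscore_rank(X, labels)$order[1:min(3L, ncol(X))]
    candidates <- all_subsets(top3)
  }
  subset_aucs <- evaluate_subsets(X, labels, candidates,
                                  n_splits = config$n_splits,
                                  test_fraction = config$test_fraction,
                                  seed = config$seed, C = config$C)

  feats <- config$model_features %||%
    strsplit(subset_aucs$subset[1], "+", fixed = TRUE)[[1]]
  model <- train_linear_svm(X[, feats, drop = FALSE], labels, C = config$C)
  model$normalize <- config$normalize
  model$exclude <- config$exclude
  model$seed <- config$seed

  cv_roc <- cv_auc(X, labels, feats, n_splits = config$n_splits,
                   test_fraction = config$test_fraction,
                   seed = config$seed, C = config$C)
  resub_roc <- roc_auc(decision_values(model, X), labels)

  structure(list(config = config, ct = ct, ct_class = ct_class, de = de,
                 stability = stab, subset_aucs = subset_aucs,
                 model = model, model_features = feats,
                 cv_roc = cv_roc, resubstitution_roc = resub_roc,
                 outlier_report = pre$outlier_report,
                 qc_report = pre$qc_report),
            class = "discovery_report")
}

#' Apply a frozen discovery model to a validation cohort
#'
#' Pre-processes the validation replicates with the same rules, applies
#' the model's normalization choice and frozen feature scaling, and
#' reports the transfer ROC/AUC plus the validation differential
#' expression table.
#'
#' @param model a `linear_model` from [run_discovery()] /
#'   [train_linear_svm()] (must carry `normalize` and `exclude`
#'   provenance fields; plain models are treated as `normalize =
#'   "none"`).
#' @param replicates validation replicate data frame.
#' @param labels +1/-1 validation labels.
#' @param config a [run_config()] for pre-processing (defaults match
#'   discovery).
#' @return A list of class `validation_report`: `roc` (transfer
#'   ROC/AUC), `de`, `scores`, `ct`.
#' @export
run_validation <- function(model, replicates, labels,
                           config = run_config()) {
  if (nrow(replicates) == 0L) stop("empty validation set")
  pre <- preprocess_replicates(replicates, config)
  ct <- pre$ct
  if (length(ct$sample_ids) == 0L) stop("empty validation set")
  labels <- align_labels(labels, ct$sample_ids)
  names(labels) <- ct$sample_ids
  de <- de_table(ct, labels, variant = config$ttest)
  ct_class <- if (identical(model$normalize, "geomean")) {
    geom_mean_normalize(ct, exclude = model$exclude %||% character())
  } else {
    ct
  }
  scores <- decision_values(model, ct_class$values)
  structure(list(roc = roc_auc(scores, labels), de = de,
                 scores = scores, ct = ct),
            class = "validation_report")
}

#' Cross-platform Ct concordance
#'
#' Pearson correlation (and r^2) of aggregated Ct values between two
#' platforms over samples present in both tables, per miR.
#'
#' @param ct_a,ct_b [ct_table()]s from the two platforms.
#' @param mirs miR ids to compare; default = miRs common to both.
#' @return Data frame with `mir`, `n_matched_samples`, `pearson_r`,
#'   `r_squared`.
#' @export
platform_concordance <- function(ct_a, ct_b, mirs = NULL) {
  stopifnot(inherits(ct_a, "ct_table"), inherits(ct_b, "ct_table"))
  common <- intersect(ct_a$sample_ids, ct_b$sample_ids)
  dropped <- length(union(ct_a$sample_ids, ct_b$sample_ids)) - length(common)
  if (dropped > 0L) message(dropped, " unmatched sample(s) dropped")
  if (length(common) < 3L) stop("need >= 3 matched samples")
  if (is.null(mirs)) mirs <- intersect(ct_a$mir_ids, ct_b$mir_ids)
  missing <- setdiff(mirs, intersect(ct_a$mir_ids, ct_b$mir_ids))
  if (length(missing) > 0L) {
    stop("miR(s) absent from a platform: ", paste(missing, collapse = ", "))
  }
  r <- vapply(mirs, function(m) {
    cor(ct_a$values[common, m], ct_b$values[common, m])
  }, numeric(1))
  data.frame(mir = mirs, n_matched_samples = length(common),
             pearson_r = unname(r), r_squared = unname(r^2),
             stringsAsFactors = FALSE)
}

#' Write a discovery report to a directory
#'
#' Emits machine-readable tables (CSV), the frozen model (JSON) and a
#' human-readable summary (`report.txt`), plus a structured
#' `report.json` carrying config and seed for provenance.
#'
#' @param report a `discovery_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "discovery_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_de_table(report$de, file.path(dir, "de_table.csv"))
  write.csv(report$subset_aucs, file.path(dir, "subset_aucs.csv"),
            row.names = FALSE)
  for (m in names(report$stability)) {
    write.csv(data.frame(mir = rownames(report$stability[[m]]$percent),
                         report$stability[[m]]$percent),
              file.path(dir, paste0("stability_", m, ".csv")),
              row.names = FALSE)
  }
  write_model(report$model, file.path(dir, "model.json"))
  jsonlite::write_json(
    list(config = unclass(report$config),
         model_features = report$model_features,
         cv_auc = report$cv_roc$auc,
         resubstitution_auc = report$resubstitution_roc$auc,
         n_samples = length(report$ct$sample_ids),
         n_mirs = length(report$ct$mir_ids)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  txt <- c(
    sprintf("discovery report (seed %d)", report$config$seed),
    sprintf("samples: %d, miRs: %d", length(report$ct$sample_ids),
            length(report$ct$mir_ids)),
    sprintf("model features: %s", paste(report$model_features,
                                        collapse = ", ")),
    sprintf("pooled CV AUC: %.4f", report$cv_roc$auc),
    sprintf("resubstitution AUC: %.4f", report$resubstitution_roc$auc))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
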