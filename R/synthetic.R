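#' Specify a synthetic qPCR cohort
#'
#' Defines the ground truth for a two-group replicate-level qPCR cohort:
#' per-miR baseline Ct in the low-risk group, an additive Ct shift in the
#' high-risk group, Gaussian between-sample (biological) and
#' within-triplicate (technical) noise on the Ct scale, and deterministic
#' dropout — any noisy replicate value above `dropout_ceiling` is emitted
#' as undetermined, exactly as a real instrument reports reactions that
#' never cross threshold.
#'
#' @param n_low,n_high numbers of low-risk / high-risk samples (>= 2).
#' @param mir_names ordered panel miR identifiers.
#' @param baseline_ct per-miR mean Ct in the low-risk group (cycles).
#' @param group_shift per-miR additive Ct shift in the high-risk group
#'   (cycles, signed).
#' @param biological_sd per-miR between-sample Ct standard deviation
#'   (cycles, > 0); recycled if scalar.
#' @param replicate_sd within-triplicate technical Ct standard deviation
#'   (cycles, >= 0).
#' @param n_replicates replicates per (sample, miR), default 3.
#' @param dropout_ceiling Ct above which an observation is emitted as
#'   undetermined (default 34).
#' @param seed integer random seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_low, n_high, mir_names, baseline_ct, group_shift,
                        biological_sd = 1.5, replicate_sd = 0.3,
                        n_replicates = 3, dropout_ceiling = 34, seed = 1) {
  k <- length(mir_names)
  if (length(biological_sd) == 1L) biological_sd <- rep(biological_sd, k)
  if (n_low < 2) stop("n_low must be >= 2")
  if (n_high < 2) stop("n_high must be >= 2")
  if (length(baseline_ct) != k) stop("baseline_ct must match mir_names in length")
  if (length(group_shift) != k) stop("group_shift must match mir_names in length")
  if (length(biological_sd) != k) stop("biological_sd must match mir_names in length")
  if (any(biological_sd <= 0)) stop("biological_sd must be > 0")
  if (replicate_sd < 0) stop("replicate_sd must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (dropout_ceiling <= 0) stop("dropout_ceiling must be > 0")
  structure(
    list(n_low = as.integer(n_low), n_high = as.integer(n_high),
         mir_names = as.character(mir_names),
         baseline_ct = as.numeric(baseline_ct),
         group_shift = as.numeric(group_shift),
         biological_sd = as.numeric(biological_sd),
         replicate_sd = as.numeric(replicate_sd),
         n_replicates = as.integer(n_replicates),
         dropout_ceiling = as.numeric(dropout_ceiling),
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Specify an affine platform transformation
#'
#' A second qPCR platform measuring the same reactions is modelled as an
#' affine map of the true Ct with extra technical noise:
#' Ct' = slope * Ct + intercept + N(0, extra_noise_sd^2), applied before
#' dropout.
#'
#' @param slope unitless multiplier (> 0).
#' @param intercept additive Ct offset (cycles).
#' @param extra_noise_sd additional Ct noise on the second platform.
#' @return An object of class `platform_spec`.
#' @export
platform_spec <- function(slope = 1, intercept = 0, extra_noise_sd = 0) {
  if (slope <= 0) stop("slope must be > 0")
  if (extra_noise_sd < 0) stop("extra_noise_sd must be >= 0")
  structure(list(slope = slope, intercept = intercept,
                 extra_noise_sd = extra_noise_sd),
            class = "platform_spec")
}

# Draw sample-level true Ct and pre-dropout replicate values.
simulate_replicate_values <- function(spec) {
  n <- spec$n_low + spec$n_high
  labels <- c(rep(-1, spec$n_low), rep(1, spec$n_high))
  ids <- c(sprintf("LR%03d", seq_len(spec$n_low)),
           sprintf("HR%03d", seq_len(spec$n_high)))
  k <- length(spec$mir_names)
  mu <- outer(labels == 1, spec$group_shift) +
    matrix(spec$baseline_ct, n, k, byrow = TRUE)
  true_ct <- mu + matrix(rnorm(n * k, sd = rep(spec$biological_sd, each = n)),
                         n, k)
  dimnames(true_ct) <- list(ids, spec$mir_names)
  long <- expand.grid(replicate = seq_len(spec$n_replicates),
                      mir = spec$mir_names, sample = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long <- long[, c("sample", "mir", "replicate")]
  base <- true_ct[cbind(long$sample, long$mir)]
  long$ct <- base + rnorm(nrow(long), sd = spec$replicate_sd)
  names(labels) <- ids
  list(long = long, labels = labels, true_ct = true_ct)
}

apply_dropout <- function(long, ceiling) {
  long$ct[long$ct > ceiling] <- NA_real_
  long
}

#' Generate a replicate-level synthetic cohort
#'
#' Sample-level true Ct values are baseline (+ shift for high-risk) plus
#' biological noise; replicates add technical noise; values above the
#' dropout ceiling are emitted as undetermined (`NA` in the `ct`
#' column).  The same spec and seed always give identical output.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `replicates` (long data frame: sample, mir,
#'   replicate, ct), `labels` (named +1/-1 vector) and `true_ct` (the
#'   noise-free-replicate sample-by-miR ground-truth matrix).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sim <- with_seed(spec$seed, simulate_replicate_values(spec))
  sim$replicates <- apply_dropout(sim$long, spec$dropout_ceiling)
  sim$long <- NULL
  sim[c("replicates", "labels", "true_ct")]
}

#' Generate the same cohort measured on two platforms
#'
#' Platform A reports the simulated replicate values directly; platform
#' B applies the affine platform map plus extra noise to the same
#' pre-dropout replicate values, so the two tables describe the same
#' underlying reactions.  Dropout is applied per platform.
#'
#' @param spec a [cohort_spec()].
#' @param platform a [platform_spec()].
#' @return A list with `replicates_a`, `replicates_b`, `labels`,
#'   `true_ct`.
#' @export
generate_two_platform <- function(spec, platform) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(platform, "platform_spec"))
  sim <- with_seed(spec$seed, {
    s <- simulate_replicate_values(spec)
    s$ct_b <- platform$slope * s$long$ct + platform$intercept +
      rnorm(nrow(s$long), sd = platform$extra_noise_sd)
    s
  })
  long_b <- sim$long
  long_b$ct <- sim$ct_b
  list(replicates_a = apply_dropout(sim$long, spec$dropout_ceiling),
       replicates_b = apply_dropout(long_b, spec$dropout_ceiling),
       labels = sim$labels, true_ct = sim$true_ct)
}

#' Built-in study scenarios
#'
#' Three ready-made cohort specifications emulating the conditions of a
#' published urinary/plasma miRNA prostate-cancer risk study:
#'
#' * `discovery_urine` — 17 low-risk / 16 high-risk samples over the
#'   13-miR urine panel; low-risk baselines and high-risk shifts equal
#'   the published discovery group means and delta-delta-Ct values
#'   (12 positive shifts, miR218 negative).
#' * `validation_flipped` — 14 low-risk / 22 high-risk samples over the
#'   miR16/miR21/miR222 validation panel with the published *negative*
#'   shifts, reproducing the effect-sign reversal that sank the
#'   signature; comes with a `platform_spec` describing the second PCR
#'   platform (unit slope, +2 cycle offset, 0.5 cycle extra noise).
#' * `plasma_weak` — 33 low-risk / 37 high-risk samples over the 12-miR
#'   plasma panel with shifts of at most 0.5 Ct and high baselines
#'   (near-ceiling dropout), so the best single miR reaches only
#'   AUC ~ 0.6.
#'
#' @param name one of `"discovery_urine"`, `"validation_flipped"`,
#'   `"plasma_weak"`.
#' @param seed seed stored in the returned spec (default 1).
#' @return A list with `cohort` (a [cohort_spec()]) and `platform`
#'   (a [platform_spec()] or `NULL`).
#' @export
qpcr_scenario <- function(name, seed = 1) {
  valid <- c("discovery_urine", "validation_flipped", "plasma_weak")
  if (!name %in% valid) {
    stop("unknown scenario '", name, "'; valid scenarios: ",
         paste(valid, collapse = ", "))
  }
  if (name == "discovery_urine") {
    tab <- discovery_summary()
    spec <- cohort_spec(n_low = 17, n_high = 16, mir_names = tab$mir,
                        baseline_ct = tab$mean_low, group_shift = tab$ddct,
                        biological_sd = 1.5, replicate_sd = 0.3, seed = seed)
    platform <- NULL
  } else if (name == "validation_flipped") {
    tab <- validation_summary()
    spec <- cohort_spec(n_low = 14, n_high = 22, mir_names = tab$mir,
                        baseline_ct = tab$mean_low, group_shift = tab$ddct,
                        biological_sd = 1.5, replicate_sd = 0.3, seed = seed)
    platform <- platform_spec(slope = 1, intercept = 2, extra_noise_sd = 0.5)
  } else {
    mirs <- c("miR16", "miR145", "miR106b", "miR34a", "miR182", "miR20a",
              "miR21", "miR222", "miR331", "miR375", "miR205", "miR221")
    baseline <- c(24.0, 27.0, 29.0, 31.0, 31.5, 28.0,
                  27.5, 30.0, 32.0, 31.0, 33.0, 30.5)
    shift <- c(0.5, 0.3, 0.35, 0.3, 0.1, 0.2,
               0.15, 0.1, 0.1, 0.1, 0.0, 0.2)
    spec <- cohort_spec(n_low = 33, n_high = 37, mir_names = mirs,
                        baseline_ct = baseline, group_shift = shift,
                        biological_sd = 1.5, replicate_sd = 0.3, seed = seed)
    platform <- NULL
  }
  list(cohort = spec, platform = platform)
}

#' Published cohort summary tables
#'
#' Per-miR group-mean Ct, delta-delta-Ct, fold-change, p- and q-values
#' as printed for the urine discovery cohort (13 miRs) and the urine
#' validation cohort (3 miRs) of the study the scenarios emulate.
#' Shipped as plain-text package data; used both as scenario ground
#' truth and as fixtures for exact-arithmetic checks.
#'
#' @return A data frame with columns `mir`, `mean_low`, `mean_high`,
#'   `ddct`, `fold_change`, `p_value`, `q_value`.
#' @export
discovery_summary <- function() {
  read.csv(system.file("extdata", "urine_discovery_summary.csv",
                       package = "mirisk"), stringsAsFactors = FALSE)
}

#' @rdname discovery_summary
#' @export
validation_summary <- function() {
  read.csv(system.file("extdata", "urine_validation_summary.csv",
                       package = "mirisk"), stringsAsFactors = FALSE)
}
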