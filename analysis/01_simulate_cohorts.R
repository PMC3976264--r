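#!/usr/bin/env Rscript
# Materialize the three built-in study scenarios as replicate-level qPCR
# exports plus metadata, so the downstream steps exercise the same
# long-format text interface a real instrument export would use.

library(mirisk)

out <- "results/cohorts"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1

for (name in c("discovery_urine", "validation_flipped", "plasma_weak")) {
  sc <- qpcr_scenario(name, seed = seed)
  g <- generate_cohort(sc$cohort)
  write_replicates(g$replicates, file.path(out, paste0(name, "_replicates.csv")))
  meta <- data.frame(sample = names(g$labels),
                     cohort = if (grepl("validation", name)) "validation" else "discovery",
                     fluid = if (grepl("plasma", name)) "plasma" else "urine",
                     platform = if (is.null(sc$platform)) "TLDA" else "preamp-qPCR",
                     risk = ifelse(g$labels > 0, "high", "low"))
  write.csv(meta, file.path(out, paste0(name, "_meta.csv")), row.names = FALSE)
  und <- sum(is.na(g$replicates$ct))
  message(sprintf("%s: %d samples (%d low / %d high), %d replicate records, %d undetermined",
                  name, length(g$labels), sc$cohort$n_low, sc$cohort$n_high,
                  nrow(g$replicates), und))
}

# the discovery cohort measured on two platforms, for step 06
sc <- qpcr_scenario("discovery_urine", seed = seed)
tp <- generate_two_platform(sc$cohort, platform_spec(slope = 1, intercept = 2,
                                                     extra_noise_sd = 0.5))
write_replicates(tp$replicates_a, file.path(out, "discovery_platformA_replicates.csv"))
write_replicates(tp$replicates_b, file.path(out, "discovery_platformB_replicates.csv"))
message("two-platform discovery profiles written (affine offset +2 cycles, extra noise 0.5)")
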