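#!/usr/bin/env Rscript
# Pre-process the simulated discovery cohort: expression ceiling at 34
# cycles, 20% triplicate outlier rule, aggregation to a sample-by-miR Ct
# matrix, and low-detection sample QC.

library(mirisk)

dir.create("results", showWarnings = FALSE)
reps <- read_replicates("results/cohorts/discovery_urine_replicates.csv")
meta <- read_sample_meta("results/cohorts/discovery_urine_meta.csv")

cfg <- run_config(seed = 1)
pre <- preprocess_replicates(reps, cfg)

write_ct_table(pre$ct, "results/discovery_ct_table.csv")
write.csv(pre$outlier_report, "results/discovery_outlier_report.csv", row.names = FALSE)
write.csv(pre$qc_report, "results/discovery_qc_report.csv", row.names = FALSE)

message(sprintf("aggregated %d samples x %d miRs", nrow(pre$ct$values), ncol(pre$ct$values)))
message(sprintf("replicate outliers removed: %d", nrow(pre$outlier_report)))
message(sprintf("samples failing detection QC: %d", sum(pre$qc_report$removed)))
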