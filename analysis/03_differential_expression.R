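#!/usr/bin/env Rscript
# Differential expression on the aggregated discovery Ct table: per-miR
# group means, delta-delta-Ct, fold change, Welch t-test and
# Benjamini-Hochberg q-values, compared against the shifts the simulator
# injected.

library(mirisk)

ct <- read_ct_table("results/discovery_ct_table.csv")
meta <- read_sample_meta("results/cohorts/discovery_urine_meta.csv")
labels <- setNames(meta$label, meta$sample)

de <- de_table(ct, labels)
write_de_table(de, "results/discovery_de_table.csv")

truth <- qpcr_scenario("discovery_urine", seed = 1)$cohort
cmp <- merge(de, data.frame(mir = truth$mir_names, injected = truth$group_shift))
message(sprintf("%d/%d miRs with q < 0.1", sum(de$q_value < 0.1), nrow(de)))
message(sprintf("%d/%d ddct estimates within 0.8 cycles of the injected shift",
                sum(abs(cmp$ddct - cmp$injected) <= 0.8), nrow(cmp)))
message("top of the table:")
print(head(de[, c("mir", "ddct", "fold_change", "p_value", "q_value")], 4),
      digits = 4, row.names = FALSE)
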