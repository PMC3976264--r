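#!/usr/bin/env Rscript
# Feature-ranking stability under Monte-Carlo cross-validation (t-score
# and centroid rankings, 30 stratified splits) and the CV AUC of every
# subset of the three panel members chosen for validation.

library(mirisk)

ct <- read_ct_table("results/discovery_ct_table.csv")
meta <- read_sample_meta("results/cohorts/discovery_urine_meta.csv")
labels <- setNames(meta$label, meta$sample)

for (method in c("tscore", "centroid")) {
  st <- stability_table(ct$values, labels, method, n_splits = 30, seed = 1)
  write.csv(data.frame(mir = rownames(st$percent), st$percent),
            sprintf("results/stability_%s.csv", method), row.names = FALSE)
  message(sprintf("%s stability leaders (top-2 %%): %s", method,
                  paste(utils::head(rownames(st$percent), 3), collapse = ", ")))
}

panel <- c("miR16", "miR21", "miR222")
res <- evaluate_subsets(ct$values, labels, all_subsets(panel),
                        n_splits = 30, seed = 1)
write.csv(res, "results/subset_aucs.csv", row.names = FALSE)
message("subset CV AUCs (pooled out-of-split scores):")
print(res, digits = 3, row.names = FALSE)
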