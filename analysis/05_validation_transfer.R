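#!/usr/bin/env Rscript
# Train the frozen 3-miR linear SVM on the discovery cohort and apply it
# unchanged to the sign-flipped validation cohort: the signature that
# cross-validates well at discovery collapses below chance when the
# group effects reverse direction.

library(mirisk)

cfg <- run_config(seed = 1, normalize = "none",
                  model_features = c("miR16", "miR21", "miR222"))

reps <- read_replicates("results/cohorts/discovery_urine_replicates.csv")
meta <- read_sample_meta("results/cohorts/discovery_urine_meta.csv")
disc <- run_discovery(reps, setNames(meta$label, meta$sample), cfg)
write_report(disc, "results/discovery_report")

vreps <- read_replicates("results/cohorts/validation_flipped_replicates.csv")
vmeta <- read_sample_meta("results/cohorts/validation_flipped_meta.csv")
val <- run_validation(disc$model, vreps, setNames(vmeta$label, vmeta$sample), cfg)
write_de_table(val$de, "results/validation_de_table.csv")
write.csv(data.frame(auc = c(discovery_cv = disc$cv_roc$auc,
                             discovery_resubstitution = disc$resubstitution_roc$auc,
                             validation_transfer = val$roc$auc)),
          "results/transfer_aucs.csv")

message(sprintf("discovery pooled CV AUC: %.3f", disc$cv_roc$auc))
message(sprintf("validation transfer AUC: %.3f (sign-flipped shifts)", val$roc$auc))
message("validation DE table (note the negative ddct):")
print(val$de[, c("mir", "ddct", "fold_change", "q_value")], digits = 3,
      row.names = FALSE)
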