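#!/usr/bin/env Rscript
# Blood-count statistics on the simulated donor cohorts: the
# neutrophil/eosinophil ratio by group, and paired pre/post-dialysis
# t-tests per immune cell type.

suppressMessages(library(netmorph))

dir.create("results", showWarnings = FALSE)

bc <- read.csv("results/data/blood_counts.csv")
ratio <- neut_eos_ratio(bc)
message(sprintf("Neut/Eos median ratio: HC %.2f, HD %.2f (quotient %.2f)",
                ratio$group_medians[["HC"]], ratio$group_medians[["HD"]],
                ratio$group_medians[["HC"]] / ratio$group_medians[["HD"]]))
write.csv(ratio$per_donor, "results/neut_eos_ratio.csv", row.names = FALSE)

dc <- read.csv("results/data/dialysis_counts.csv")
rows <- lapply(c("neutrophils", "eosinophils", "lymphocytes", "monocytes"),
               function(ct) {
  res <- paired_pre_post(dc, ct)
  message(sprintf(
    "%s pre vs post: t = %.2f, p = %.3f, mean change %.1f%% (n = %d pairs)",
    ct, res$statistic, res$p_value, res$mean_pct_change, res$n_pairs))
  data.frame(cell_type = ct, t = res$statistic, p = res$p_value,
             mean_pct_change = res$mean_pct_change, n_pairs = res$n_pairs)
})
write.csv(do.call(rbind, rows), "results/dialysis_paired_tests.csv",
          row.names = FALSE)
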