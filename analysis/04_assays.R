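#!/usr/bin/env Rscript
# Quantify the companion assays from the simulated plate and CFU data
# written by 01_simulate_data.R: cfDNA via the Sytox-green standard curve,
# and bacterial-killing percentages per organism and donor group.

suppressMessages(library(netmorph))

dir.create("results", showWarnings = FALSE)

std <- read.csv("results/data/standard_curves.csv")
curve <- fit_standard_curve(std$concentration_ng_ml, std$rfu)
print(curve)

# example unknowns: supernatant readings converted through the curve
unknown_rfu <- c(350, 1200, 2600, 4800)
cfdna <- rfu_to_cfdna(curve, unknown_rfu)
quant <- data.frame(rfu = unknown_rfu, cfdna_ng_ml = as.numeric(cfdna),
                    below_blank = attr(cfdna, "below_blank"))
write.csv(quant, "results/cfdna_quantification.csv", row.names = FALSE)
message("cfDNA (ng/ml): ", paste(round(quant$cfdna_ng_ml, 3), collapse = ", "))

cfu <- read.csv("results/data/cfu_records.csv")
cfu$mode <- "total"
cfu$condition <- paste(cfu$organism, cfu$condition, sep = ":")
ks <- killing_summary(cfu)
write.csv(ks, "results/killing_summary.csv", row.names = FALSE)
for (i in seq_len(nrow(ks))) {
  message(sprintf("%s total killing: %.2f%% +/- %.2f (n=%d)",
                  ks$condition[i], ks$mean_killing[i], ks$sd_killing[i],
                  ks$n[i]))
}

# noiseless worked example of the killing arithmetic at the printed values
worked <- data.frame(
  condition = c("S_aureus:HC", "S_aureus:HD", "E_coli:HC", "E_coli:HD"),
  control_cfu = 1e4,
  sample_cfu = simulate_cfu(1e4, c(72.93, 39.48, 69.55, 51.43))$sample_cfu)
worked$killing_pct <- as.numeric(
  killing_percent(worked$sample_cfu, worked$control_cfu))
write.csv(worked, "results/killing_worked_example.csv", row.names = FALSE)
message("worked killing percentages: ",
        paste(worked$killing_pct, collapse = ", "))
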