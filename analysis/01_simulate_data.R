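#!/usr/bin/env Rscript
# Generate the synthetic study data: an example imaged population for each
# condition, plate-reader standards, CFU records for the killing assays,
# and donor blood counts. Everything downstream runs from these seeded
# simulations; no external data are required.

suppressMessages(library(netmorph))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# One example image per condition (full-scale populations are regenerated
# on the fly by 03; these are for inspection).
for (preset in c("unstimulated", "HC_A23187", "HD_A23187")) {
  cfg <- population_config(preset, cells_per_image = 20L, n_images = 1L,
                           seed = 1L)
  pop <- make_population(cfg)
  write_population(pop, file.path(out, paste0("population_", preset)))
  message(preset, ": ", nrow(pop$truth), " nuclei rendered (",
          paste(capture.output(print(table(pop$truth$class))), collapse = " "),
          ")")
}

# Sytox-green DNA standards, 0.1-5 ng/ml, triplicate plates.
std <- do.call(rbind, lapply(1:3, function(r) {
  cbind(plate = r, simulate_standard_curve(noise_sd = 25, seed = 100 + r))
}))
write.csv(std, file.path(out, "standard_curves.csv"), row.names = FALSE)
message("standard curves: ", nrow(std), " wells")

# CFU records for the two organisms: survivors constructed from the
# study's printed killing percentages plus Poisson plating noise.
cfu <- rbind(
  cbind(organism = "S_aureus",
        simulate_cfu(1e4, 72.93, noise = TRUE, condition = "HC",
                     replicate = 1:3, seed = 11)),
  cbind(organism = "S_aureus",
        simulate_cfu(1e4, 39.48, noise = TRUE, condition = "HD",
                     replicate = 1:3, seed = 12)),
  cbind(organism = "E_coli",
        simulate_cfu(1e4, 69.55, noise = TRUE, condition = "HC",
                     replicate = 1:3, seed = 13)),
  cbind(organism = "E_coli",
        simulate_cfu(1e4, 51.43, noise = TRUE, condition = "HD",
                     replicate = 1:3, seed = 14)))
write.csv(cfu, file.path(out, "cfu_records.csv"), row.names = FALSE)
message("CFU records: ", nrow(cfu), " platings")

# Blood counts: two cross-sectional groups (HD eosinophils elevated x1.88)
# and paired pre/post-dialysis counts.
bc <- simulate_blood_counts(seed = 21)
write.csv(bc, file.path(out, "blood_counts.csv"), row.names = FALSE)
dc <- simulate_dialysis_counts(seed = 22)
write.csv(dc, file.path(out, "dialysis_counts.csv"), row.names = FALSE)
message("blood counts: ", nrow(bc), " donors; paired rows: ", nrow(dc))
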