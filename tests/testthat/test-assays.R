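# cfDNA standard-curve quantification and CFU killing arithmetic.

test_that("standard curve fit recovers an exact line", {
  sc <- fit_standard_curve(c(1, 2, 3), c(1050, 2050, 3050))
  expect_equal(sc$slope, 1000)
  expect_equal(sc$intercept, 50)
  expect_equal(sc$r_squared, 1)
  expect_equal(sc$n_points, 3L)
})

test_that("standard curve fit rejects degenerate standards", {
  expect_error(fit_standard_curve(1, 1000), "at least 2")
  expect_error(fit_standard_curve(c(2, 2, 2), c(10, 11, 12)), "distinct")
  expect_error(fit_standard_curve(c(1, 2), 5), "equal length")
})

test_that("noiseless simulation and refit are exact inverses", {
  sim <- simulate_standard_curve(slope = 1000, intercept = 50, noise_sd = 0)
  expect_equal(sim$rfu, 50 + 1000 * sim$concentration_ng_ml)
  sc <- fit_standard_curve(sim$concentration_ng_ml, sim$rfu)
  expect_equal(sc$slope, 1000, tolerance = 1e-9)
  expect_equal(sc$intercept, 50, tolerance = 1e-9)
  # round trip conc -> RFU -> conc
  back <- rfu_to_cfdna(sc, sim$rfu)
  expect_lt(max(abs(back - sim$concentration_ng_ml)), 1e-9)
})

test_that("slope is recovered within 5% at plate-reader noise", {
  sim <- simulate_standard_curve(slope = 1000, intercept = 50,
                                 noise_sd = 25, seed = 7)
  expect_equal(nrow(sim), 8L)
  sc <- fit_standard_curve(sim$concentration_ng_ml, sim$rfu)
  expect_lt(abs(sc$slope - 1000) / 1000, 0.05)
})

test_that("simulated standards reject negative concentrations", {
  expect_error(simulate_standard_curve(concentrations = c(-0.1, 1)),
               "non-negative")
})

test_that("rfu_to_cfdna flags readings below the blank", {
  sc <- fit_standard_curve(c(0, 1, 2), c(100, 1100, 2100))
  conc <- rfu_to_cfdna(sc, c(2600, 100, 50))
  expect_equal(as.numeric(conc), c(2.5, 0, 0))
  expect_equal(attr(conc, "below_blank"), c(FALSE, FALSE, TRUE))
  bad <- sc; bad$slope <- -1
  expect_error(rfu_to_cfdna(bad, 100), "slope")
})

test_that("killing percentages reproduce the study's printed values", {
  # surviving counts constructed from the printed killing percentages
  expect_equal(as.numeric(killing_percent(2707, 10000)), 72.93)
  expect_equal(as.numeric(killing_percent(6052, 10000)), 39.48)
  expect_equal(as.numeric(killing_percent(3045, 10000)), 69.55)
  expect_equal(as.numeric(killing_percent(10000, 10000)), 0)
  expect_equal(as.numeric(killing_percent(0, 10000)), 100)
})

test_that("killing percent is scale-invariant and decreasing in survivors", {
  s <- c(100, 500, 900)
  expect_equal(as.numeric(killing_percent(s, 1000)),
               as.numeric(killing_percent(7 * s, 7000)))
  expect_true(all(diff(as.numeric(killing_percent(s, 1000))) < 0))
  expect_error(killing_percent(10, 0), "control_cfu")
  over <- killing_percent(1500, 1000)
  expect_equal(as.numeric(over), -50)
  expect_true(attr(over, "net_growth"))
})

test_that("CFU from serial dilution follows the plating arithmetic", {
  expect_equal(cfu_from_dilution(50, 1e4, 0.1), 5e6)
  expect_equal(cfu_from_dilution(0, 1e4, 0.1), 0)
  expect_equal(cfu_from_dilution(37, 1, 1), 37)
  expect_error(cfu_from_dilution(10, 10, 0), "plated_volume")
})

test_that("simulated CFU records follow the survival model", {
  expect_equal(simulate_cfu(10000, 0)$sample_cfu, 10000)
  expect_equal(simulate_cfu(10000, 100)$sample_cfu, 0)
  expect_equal(simulate_cfu(10000, 72.93)$sample_cfu, 2707)
  expect_error(simulate_cfu(10000, 120), "killing_pct")
  expect_error(simulate_cfu(0, 10), "control_cfu")
  # Poisson mode is seeded and near the survival mean
  r1 <- simulate_cfu(10000, 50, noise = TRUE, seed = 11)
  r2 <- simulate_cfu(10000, 50, noise = TRUE, seed = 11)
  expect_identical(r1, r2)
  expect_lt(abs(r1$sample_cfu - 5000), 4 * sqrt(5000))
})

test_that("replicate summaries and the NET-attributable component", {
  recs <- rbind(
    simulate_cfu(10000, c(70, 72, 74), condition = "HC", replicate = 1:3),
    simulate_cfu(10000, c(25, 26, 27), condition = "HC", replicate = 1:3))
  recs$mode <- rep(c("extracellular", "extracellular+DNase"), each = 3)
  ks <- killing_summary(recs)
  expect_equal(nrow(ks), 2L)
  expect_equal(ks$mean_killing[ks$mode == "extracellular"], 72)
  expect_equal(ks$n, c(3L, 3L))
  na <- net_attributable_killing(ks, "HC")
  expect_equal(na$net_attributable, 72 - 26)
  expect_false(na$flagged_negative)
  # negative differences are flagged, not truncated
  ks2 <- ks
  ks2$mean_killing[ks2$mode == "extracellular"] <- 20
  na2 <- net_attributable_killing(ks2, "HC")
  expect_true(na2$flagged_negative)
  expect_lt(na2$net_attributable, 0)
})
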