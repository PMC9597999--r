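# Stage-distribution aggregation, condition comparison and blood-count
# statistics.

pred_frame <- function(classes, donor = "d1", condition = "A") {
  data.frame(donor_id = donor, condition = condition,
             class = classes)
}

test_that("distributions count directly and cover all four stages", {
  d <- class_distribution(pred_frame(c("LOBULATED", "LOBULATED",
                                       "DELOBULATED", "SPREAD")))
  expect_equal(d$pooled$fraction[match(morphology_levels(),
                                       d$pooled$class)],
               c(0.5, 0.25, 0, 0.25))
  expect_equal(sum(d$pooled$count), 4)
  expect_equal(unique(d$pooled$n_cells), 4)
})

test_that("fractions sum to one per donor and per condition", {
  set.seed(31)
  df <- data.frame(
    donor_id = sample(paste0("d", 1:5), 400, TRUE),
    condition = sample(c("A", "B"), 400, TRUE),
    class = sample(morphology_levels(), 400, TRUE,
                   prob = c(0.5, 0.3, 0.15, 0.05)))
  d <- class_distribution(df)
  per <- aggregate(fraction ~ donor_id + condition, d$per_donor, sum)
  expect_true(all(abs(per$fraction - 1) < 1e-9))
  pooled <- aggregate(fraction ~ condition, d$pooled, sum)
  expect_true(all(abs(pooled$fraction - 1) < 1e-9))
  # conservation: pooled counts equal total cells
  expect_equal(sum(d$pooled$count), nrow(df))
})

test_that("with equal cells per donor the donor-mean equals the pooled fraction", {
  set.seed(7)
  df <- do.call(rbind, lapply(1:4, function(i) {
    pred_frame(sample(morphology_levels(), 50, TRUE), donor = paste0("d", i))
  }))
  d <- class_distribution(df)
  expect_equal(d$pooled$donor_mean, d$pooled$fraction, tolerance = 1e-12)
})

test_that("empty predictions give an empty distribution", {
  d <- class_distribution(data.frame(donor_id = character(0),
                                     condition = character(0),
                                     class = character(0)))
  expect_equal(nrow(d$pooled), 0L)
})

test_that("chi-square comparison: identity, extreme separation, scaling", {
  da <- class_distribution(pred_frame(rep(c("LOBULATED", "SPREAD"), c(30, 10))))
  same <- compare_conditions(da, da)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  d1 <- class_distribution(pred_frame(rep("LOBULATED", 100)))
  d2 <- class_distribution(pred_frame(rep("SPREAD", 100), condition = "B"))
  extreme <- compare_conditions(d1, d2)
  expect_lt(extreme$p_value, 1e-6)
  expect_equal(extreme$statistic, 200)  # 2x2 Pearson chi-square, all-or-none

  # doubling every count doubles the statistic
  ca <- pred_frame(rep(morphology_levels(), c(40, 25, 20, 15)))
  cb <- pred_frame(rep(morphology_levels(), c(20, 30, 25, 25)), condition = "B")
  x1 <- compare_conditions(class_distribution(ca), class_distribution(cb))
  x2 <- compare_conditions(class_distribution(rbind(ca, ca)),
                           class_distribution(rbind(cb, cb)))
  expect_equal(x2$statistic, 2 * x1$statistic, tolerance = 1e-12)

  empty <- class_distribution(data.frame(donor_id = character(0),
                                         condition = character(0),
                                         class = character(0)))
  expect_error(compare_conditions(da, empty), "positive total")
})

test_that("paired t-test matches the textbook formula", {
  counts <- data.frame(
    donor_id = rep(paste0("d", 1:4), 2),
    timepoint = rep(c("pre", "post"), each = 4),
    neutrophils = c(5, 7, 4, 8, 6, 9, 4, 10))
  res <- paired_pre_post(counts, "neutrophils")
  d <- c(6, 9, 4, 10) - c(5, 7, 4, 8)
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 3)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_equal(res$mean_pct_change, mean(d / c(5, 7, 4, 8)) * 100)
  expect_equal(res$n_pairs, 4L)
})

test_that("paired t-test handles no-change and degenerate designs", {
  counts <- data.frame(donor_id = rep(paste0("d", 1:3), 2),
                       timepoint = rep(c("pre", "post"), each = 3),
                       neutrophils = rep(c(5, 7, 4), 2))
  res <- paired_pre_post(counts, "neutrophils")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_pct_change, 0)

  one <- counts[counts$donor_id == "d1", ]
  expect_error(paired_pre_post(one, "neutrophils"), "at least 2")

  unpaired <- rbind(counts,
                    data.frame(donor_id = "d9", timepoint = "pre",
                               neutrophils = 5))
  expect_warning(res2 <- paired_pre_post(unpaired, "neutrophils"),
                 "unpaired")
  expect_equal(res2$n_excluded, 1L)
  expect_error(paired_pre_post(counts, "basophils"), "unknown cell type")
})

test_that("neut/eos ratios exclude zero-eosinophil donors", {
  counts <- data.frame(donor_id = c("a", "b", "c"), group = "HC",
                       neutrophils = c(4000, 3000, 2000),
                       eosinophils = c(200, 0, 100))
  res <- neut_eos_ratio(counts)
  expect_equal(res$per_donor$ratio, c(20, 20))
  expect_equal(res$n_excluded, 1L)
  expect_equal(unname(res$group_medians["HC"]), 20)
  zero <- counts; zero$eosinophils <- 0
  expect_error(neut_eos_ratio(zero), "all donors excluded")
})

test_that("the simulated HD eosinophil elevation is recovered from medians", {
  bc <- simulate_blood_counts(n_hc = 500, n_hd = 500, eos_scale_hd = 1.88,
                              seed = 2)
  res <- neut_eos_ratio(bc)
  quotient <- res$group_medians[["HC"]] / res$group_medians[["HD"]]
  expect_lt(abs(quotient - 1.88) / 1.88, 0.10)
})

test_that("a dialysis session leaves simulated counts unchanged on average", {
  dc <- simulate_dialysis_counts(n = 42, seed = 4)
  res <- paired_pre_post(dc, "neutrophils")
  expect_gt(res$p_value, 0.05)
  expect_lt(abs(res$mean_pct_change), 15)
})
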