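# The synthetic nucleus generator: determinism, mixture behaviour, stage
# geometry, and the simulated plate/CFU/blood-count data.

test_that("configuration validation catches bad mixtures and shapes", {
  expect_error(population_config(c(LOBULATED = 0.5, DELOBULATED = 0.5,
                                   DIFFUSED = 0.2, SPREAD = 0.2)),
               "sum to 1")
  expect_error(population_config(image_shape = c(32, 128)), ">= 64")
  expect_error(population_config(n_images = 0), "positive")
  expect_error(preset_proportions("bogus"), "unknown preset")
  p <- preset_proportions("HC_A23187")
  expect_equal(unname(p["SPREAD"]), 0.82)
  expect_equal(sum(p), 1)
})

test_that("a degenerate mixture yields only that stage", {
  cfg <- population_config(c(LOBULATED = 1, DELOBULATED = 0,
                             DIFFUSED = 0, SPREAD = 0),
                           cells_per_image = 25L, n_images = 2L,
                           image_shape = c(512L, 512L), seed = 2)
  pop <- make_population(cfg)
  expect_equal(nrow(pop$truth), 50L)
  expect_true(all(pop$truth$class == "LOBULATED"))
})

test_that("zero cells per image yields empty images and truth", {
  cfg <- population_config(cells_per_image = 0L, n_images = 2L,
                           image_shape = c(64L, 64L), seed = 1)
  pop <- make_population(cfg)
  expect_equal(nrow(pop$truth), 0L)
  expect_true(all(vapply(pop$masks, max, numeric(1)) == 0))
  expect_equal(dim(pop$images[[1]]), c(64L, 64L))
})

test_that("identical seeds give bit-identical populations", {
  cfg <- population_config("HD_A23187", cells_per_image = 5L, n_images = 1L,
                           image_shape = c(512L, 512L), seed = 17)
  p1 <- make_population(cfg)
  p2 <- make_population(cfg)
  expect_identical(p1$images, p2$images)
  expect_identical(p1$masks, p2$masks)
  expect_identical(p1$truth, p2$truth)
})

test_that("render_cell is deterministic under a fixed RNG state", {
  for (cl in morphology_levels()) {
    set.seed(33); a <- render_cell(cl)
    set.seed(33); b <- render_cell(cl)
    expect_identical(a, b)
  }
})

test_that("empirical class fractions follow the multinomial mixture", {
  # large-n mixture law on the label draw itself
  set.seed(12)
  p <- preset_proportions("HD_A23187")
  cls <- draw_classes(20000, p)
  emp <- table(factor(cls, levels = morphology_levels())) / 20000
  for (lv in morphology_levels()) {
    se <- sqrt(p[[lv]] * (1 - p[[lv]]) / 20000)
    expect_lt(abs(emp[[lv]] - p[[lv]]), 3 * se)
  }
  # and on a rendered population at the study's per-condition scale
  cfg <- population_config("unstimulated", cells_per_image = 20L,
                           n_images = 30L, seed = 1)
  pop <- make_population(cfg)
  expect_equal(nrow(pop$truth), 600L)
  frac_lob <- mean(pop$truth$class == "LOBULATED")
  expect_lt(abs(frac_lob - 0.85), 3 * sqrt(0.85 * 0.15 / 600))
})

test_that("ground truth and label masks agree object by object", {
  pop <- small_population("HD_A23187", seed = 9, cells = 8L,
                          shape = c(768L, 768L))
  mask <- pop$masks[[1]]
  areas <- tabulate(mask[mask > 0], nbins = max(mask))
  expect_equal(sort(unique(mask[mask > 0])), pop$truth$object_id)
  expect_true(all(abs(areas[pop$truth$object_id] - pop$truth$area_px2) <= 1))
  # every object is a single 8-connected component
  for (id in pop$truth$object_id) {
    expect_equal(max(EBImage::bwlabel((mask == id) + 0L)), 1)
  }
})

test_that("stage geometry: spread NETs dwarf lobulated nuclei", {
  set.seed(44)
  eqr <- function(cl, n) {
    vapply(seq_len(n), function(i) sqrt(sum(render_cell(cl)$mask) / pi),
           numeric(1))
  }
  r_spread <- eqr("SPREAD", 200)
  r_lob <- eqr("LOBULATED", 200)
  expect_gt(mean(r_spread) / mean(r_lob), 3)
  expect_true(all(r_spread >= 26 & r_spread <= 67))
})

test_that("smooth delobulated ellipses satisfy the analytic circularity bound", {
  set.seed(55)
  pars <- netmorph:::render_defaults()
  pars$delob_wobble_p <- 0  # the smooth-ellipse form
  for (i in 1:25) {
    m <- render_cell("DELOBULATED", pars)$mask
    expect_lte(heywood_circularity(mask_perimeter(m), sum(m)), 1.15)
  }
  # with residual waviness circularity stays moderate, below the spread range
  set.seed(56)
  hcfs <- replicate(40, {
    m <- render_cell("DELOBULATED")$mask
    heywood_circularity(mask_perimeter(m), sum(m))
  })
  expect_true(all(hcfs < 1.4))
})

test_that("diffused NETs are dimmer than condensed stages", {
  set.seed(66)
  lev <- function(cl, n) mean(replicate(n, render_cell(cl)$level))
  expect_lt(lev("DIFFUSED", 30) / lev("DELOBULATED", 30), 0.72)
  expect_gt(lev("DIFFUSED", 30) / lev("DELOBULATED", 30), 0.48)
})

test_that("impossible placements raise a placement error", {
  cfg <- population_config("HC_A23187", cells_per_image = 30L,
                           n_images = 1L, image_shape = c(256L, 256L),
                           seed = 3)
  expect_error(make_population(cfg), "placement error")
})

test_that("pixel values stay in the 16-bit range", {
  pop <- small_population(seed = 10)
  rng <- range(pop$images[[1]])
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 65535)
})
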