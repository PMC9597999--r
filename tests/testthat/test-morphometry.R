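# Morphometric features: the Heywood circularity anchor values, the
# sub-pixel perimeter estimator, and the feature-table contract.

test_that("Heywood circularity hits the analytic anchors", {
  r <- 7.3
  expect_equal(heywood_circularity(2 * pi * r, pi * r^2), 1.0)
  s <- 11
  expect_equal(heywood_circularity(4 * s, s^2), 2 / sqrt(pi))
  # vectorized
  expect_equal(heywood_circularity(c(2 * pi, 8), c(pi, 4)),
               c(1, 2 / sqrt(pi)))
})

test_that("Heywood circularity rejects degenerate inputs", {
  expect_error(heywood_circularity(10, 0), "area")
  expect_error(heywood_circularity(10, -3), "area")
  expect_error(heywood_circularity(0, 10), "perimeter")
})

test_that("rasterized disks and squares stay near the analytic values", {
  for (r in c(5, 10, 20, 40)) {
    d <- raster_disk(r)
    hcf <- heywood_circularity(mask_perimeter(d), sum(d))
    expect_gt(hcf, 0.98)
    expect_lt(hcf, 1.05)
    # against the circle of the rasterized area (discretization aside)
    expect_lt(abs(mask_perimeter(d) - 2 * sqrt(pi * sum(d))) /
                (2 * sqrt(pi * sum(d))), 0.05)
  }
  for (r in c(10, 20, 40)) {
    d <- raster_disk(r)
    expect_lt(abs(mask_perimeter(d) - 2 * pi * r) / (2 * pi * r), 0.015)
  }
  sq <- raster_square(30)
  hcf_sq <- heywood_circularity(mask_perimeter(sq), sum(sq))
  expect_lt(abs(hcf_sq - 2 / sqrt(pi)) / (2 / sqrt(pi)), 0.03)
})

test_that("perimeter matches the Ramanujan ellipse approximation", {
  a <- 20; b <- 12
  n <- 2 * (a + 6) + 1
  xy <- expand.grid(seq_len(n), seq_len(n))
  ctr <- a + 7
  el <- matrix(((xy[, 1] - ctr) / a)^2 + ((xy[, 2] - ctr) / b)^2 <= 1,
               n, n) + 0L
  h <- ((a - b) / (a + b))^2
  p_ramanujan <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_lt(abs(mask_perimeter(el) - p_ramanujan) / p_ramanujan, 0.015)
})

test_that("scale law: area ~ k^2, perimeter ~ k, HCF invariant", {
  hcfs <- numeric(0); areas <- numeric(0); perims <- numeric(0)
  for (r in c(10, 20, 40)) {
    d <- raster_disk(r)
    areas <- c(areas, sum(d))
    perims <- c(perims, mask_perimeter(d))
    hcfs <- c(hcfs, heywood_circularity(mask_perimeter(d), sum(d)))
  }
  expect_lt(abs(areas[2] / areas[1] - 4) / 4, 0.03)
  expect_lt(abs(areas[3] / areas[2] - 4) / 4, 0.03)
  expect_lt(abs(perims[2] / perims[1] - 2) / 2, 0.03)
  expect_lt(abs(perims[3] / perims[2] - 2) / 2, 0.03)
  expect_lt(max(hcfs) - min(hcfs), 0.03)
})

test_that("feature extraction on a uniform disk matches analytic values", {
  d <- raster_disk(20)
  img <- d * 100
  f <- extract_features(img, d, image_id = 9L)
  expect_equal(nrow(f), 1L)
  expect_equal(f$image_id, 9L)
  expect_lt(abs(f$area - pi * 400) / (pi * 400), 0.02)
  expect_lt(abs(f$integrated_density - 100 * f$area) / (100 * f$area), 1e-12)
  expect_gt(f$heywood_circularity, 0.98)
  expect_lt(f$heywood_circularity, 1.05)
  expect_lt(abs(f$equivalent_diameter - 40) / 40, 0.02)
  expect_lt(f$eccentricity, 0.1)
  expect_gt(f$solidity, 0.94)
})

test_that("feature table contract: empty mask, multiple labels, shape check", {
  img <- matrix(5, 30, 30)
  expect_equal(nrow(extract_features(img, matrix(0L, 30, 30))), 0L)
  expect_error(extract_features(img, matrix(0L, 10, 10)), "shape")
  m <- matrix(0L, 30, 30)
  m[3:8, 3:8] <- 1L
  m[20:26, 20:26] <- 2L
  f <- extract_features(img, m)
  expect_equal(f$object_id, c(1L, 2L))
  expect_equal(names(f), c("image_id", "object_id", extended_feature_names()))
})

test_that("integrated density is additive: mean intensity times area", {
  pop <- small_population(seed = 21)
  f <- extract_features(pop$images[[1]], pop$masks[[1]])
  expect_true(all(abs(f$integrated_density - f$mean_intensity * f$area) /
                    f$integrated_density < 1e-6))
})

test_that("solidity of an L-tromino equals the hand-computed 6/7", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 1L; m[2, 3] <- 1L; m[3, 2] <- 1L
  f <- extract_features(m * 10, m)
  expect_equal(f$solidity, 3 / 3.5, tolerance = 1e-9)
})

test_that("eccentricity matches analytic ellipse values", {
  a <- 18; b <- 9
  n <- 2 * (a + 5) + 1; ctr <- a + 6
  xy <- expand.grid(seq_len(n), seq_len(n))
  el <- matrix(((xy[, 1] - ctr) / a)^2 + ((xy[, 2] - ctr) / b)^2 <= 1,
               n, n) + 0L
  f <- extract_features(el * 1, el)
  expect_equal(f$eccentricity, sqrt(1 - (b / a)^2), tolerance = 0.02)
  # near-circular object: eccentricity near 0, strictly below 1
  d <- raster_disk(12)
  fd <- extract_features(d * 1, d)
  expect_lt(fd$eccentricity, 0.15)
})

test_that("near-circular stages attain the minimum Heywood circularity", {
  pop <- small_population("HD_A23187", seed = 8, cells = 10L,
                          shape = c(768L, 768L))
  f <- extract_features_all(pop$images, pop$masks)
  truth <- pop$truth
  spread_hcf <- f$heywood_circularity[truth$class == "SPREAD"]
  other_hcf <- f$heywood_circularity[truth$class != "SPREAD"]
  if (length(spread_hcf) > 0 && length(other_hcf) > 0) {
    expect_true(min(other_hcf) <= min(spread_hcf))
    expect_true(all(spread_hcf >= 1.35))
  }
  expect_true(all(f$solidity > 0 & f$solidity <= 1))
  expect_true(all(f$eccentricity >= 0 & f$eccentricity < 1))
  expect_true(all(f$heywood_circularity >= 0.95))
})
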