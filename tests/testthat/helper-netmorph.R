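# Shared fixtures and a session-level cache for the expensive default
# classifier (built once, reused across test files).

nm_cache <- new.env(parent = emptyenv())

# Default classifier at acceptance scale (500 nuclei/stage, seed 0).
cached_default_fit <- function() {
  if (is.null(nm_cache$fit)) {
    nm_cache$fit <- default_classifier(n_per_class = 500L, seed = 0L)
  }
  nm_cache$fit
}

# Smaller labelled feature pool for classifier property tests.
cached_small_training <- function() {
  if (is.null(nm_cache$small_ts)) {
    nm_cache$small_ts <- default_training_set(n_per_class = 100L, seed = 3L)
  }
  nm_cache$small_ts
}

# Rasterized disk (pixel-centre inclusion), odd-sized square patch.
raster_disk <- function(r, pad = 6) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  xy <- expand.grid(seq_len(n), seq_len(n))
  matrix((xy[, 1] - ctr)^2 + (xy[, 2] - ctr)^2 <= r^2, n, n) + 0L
}

raster_square <- function(side, pad = 6) {
  n <- side + 2 * pad
  m <- matrix(0L, n, n)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- 1L
  m
}

# Clearly separable synthetic feature table: stage feature ranges disjoint.
separable_features <- function(n_per_class = 30, seed = 42) {
  set.seed(seed)
  lv <- morphology_levels()
  area_mid <- c(LOBULATED = 100, DELOBULATED = 400, DIFFUSED = 1200,
                SPREAD = 6000)
  rows <- lapply(lv, function(cl) {
    area <- stats::runif(n_per_class, 0.9, 1.1) * area_mid[[cl]]
    per <- 2 * sqrt(pi * area) * stats::runif(n_per_class, 1.0, 1.1)
    mi <- stats::runif(n_per_class, 0.9, 1.1) *
      c(LOBULATED = 3000, DELOBULATED = 2000, DIFFUSED = 1200,
        SPREAD = 600)[[cl]]
    data.frame(image_id = 1L, object_id = seq_len(n_per_class),
               area = area, perimeter = per,
               heywood_circularity = per / (2 * sqrt(pi * area)),
               integrated_density = area * mi, mean_intensity = mi,
               equivalent_diameter = 2 * sqrt(area / pi),
               eccentricity = stats::runif(n_per_class, 0.1, 0.7),
               solidity = stats::runif(n_per_class, 0.8, 1.0),
               class = cl)
  })
  out <- do.call(rbind, rows)
  out$object_id <- seq_len(nrow(out))
  out
}

# Tiny population for structural tests (fast to render and segment).
small_population <- function(preset = "unstimulated", seed = 5,
                             cells = 6L, n_images = 1L,
                             shape = c(512L, 512L)) {
  make_population(population_config(preset, cells_per_image = cells,
                                    n_images = n_images,
                                    image_shape = shape, seed = seed))
}
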