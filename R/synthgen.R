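# Synthetic generator for populations of Sytox-stained neutrophil nuclei in
# the four NETosis stages, plus simulated plate (standard-curve) and CFU data.
# All randomness flows through the caller-visible seed; identical seeds give
# bit-identical output.

#' Preset stage mixtures
#'
#' Class proportions for three study-like conditions: resting neutrophils
#' (`"unstimulated"`, dominated by lobulated nuclei), healthy-control
#' neutrophils after 3 h of calcium-ionophore A23187 stimulation
#' (`"HC_A23187"`, dominated by spread NETs) and hemodialysis-patient
#' neutrophils under the same stimulus (`"HD_A23187"`, where chromatin
#' decondensation stalls and delobulated/diffused stages accumulate).
#'
#' @param name One of `"unstimulated"`, `"HC_A23187"`, `"HD_A23187"`.
#' @return Named numeric vector of proportions over [morphology_levels()].
#' @export
#' @examples
#' preset_proportions("unstimulated")
preset_proportions <- function(name) {
  presets <- list(
    unstimulated = c(LOBULATED = 0.85, DELOBULATED = 0.09,
                     DIFFUSED = 0.04, SPREAD = 0.02),
    HC_A23187    = c(LOBULATED = 0.03, DELOBULATED = 0.05,
                     DIFFUSED = 0.10, SPREAD = 0.82),
    HD_A23187    = c(LOBULATED = 0.10, DELOBULATED = 0.25,
                     DIFFUSED = 0.25, SPREAD = 0.40)
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}

#' Configuration of a synthetic nucleus population
#'
#' @param class_proportions Named numeric vector of mixture weights over the
#'   four stages, or a preset name (see [preset_proportions()]). Must be
#'   non-negative and sum to 1 (within 1e-9).
#' @param cells_per_image Non-negative integer, nuclei per image.
#' @param n_images Positive integer.
#' @param image_shape Integer (rows, cols); each component at least 64.
#' @param background_level Mean background intensity (counts).
#' @param noise_sd Gaussian read-noise s.d. (counts).
#' @param overlap_allowed If `FALSE` (default) nuclei are placed by rejection
#'   sampling with a pairwise clearance so instances never touch.
#' @param pixel_size Micrometres per pixel (metadata only).
#' @param seed Integer seed; the population is a pure function of
#'   (config, seed).
#' @return A list of class `"population_config"`.
#' @export
population_config <- function(class_proportions = "unstimulated",
                              cells_per_image = 20L,
                              n_images = 5L,
                              image_shape = c(1024L, 1024L),
                              background_level = 300,
                              noise_sd = 30,
                              overlap_allowed = FALSE,
                              pixel_size = 1.0,
                              seed = 1L) {
  if (is.character(class_proportions)) {
    class_proportions <- preset_proportions(class_proportions)
  }
  lv <- morphology_levels()
  if (!all(lv %in% names(class_proportions))) {
    stop("class_proportions must be named over: ", paste(lv, collapse = ", "))
  }
  p <- as.numeric(class_proportions[lv])
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("class proportions must be non-negative and sum to 1")
  }
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2 || any(image_shape < 64)) {
    stop("image_shape must be two integers, each >= 64")
  }
  if (cells_per_image < 0) stop("cells_per_image must be non-negative")
  if (n_images < 1) stop("n_images must be positive")
  structure(list(
    class_proportions = stats::setNames(p, lv),
    cells_per_image = as.integer(cells_per_image),
    n_images = as.integer(n_images),
    image_shape = image_shape,
    background_level = background_level,
    noise_sd = noise_sd,
    overlap_allowed = isTRUE(overlap_allowed),
    pixel_size = pixel_size,
    seed = as.integer(seed)
  ), class = "population_config")
}

# Rendering parameter block. Stage geometry: progressive chromatin
# decondensation means later stages are larger, less regular and dimmer.
# Adjacent stage ranges are deliberately close so that morphometric
# distributions overlap and classification is imperfect.
render_defaults <- function() {
  list(
    lob_n_lobes   = 3:5,
    lob_axis      = c(5, 9),     # lobe semi-axes, px
    lob_span      = 12,          # lobe centres within this radius of centre
    lob_overlap   = c(0.55, 0.95), # centre spacing as fraction of radius sum
    delob_axis    = c(9, 14),    # single-ellipse semi-axes, px
    delob_wobble_p = 0.20,       # fraction with residual boundary waviness
    delob_wobble_amp = c(0.08, 0.20),
    diff_radius   = c(16, 24),   # diffused-NET equivalent radius, px
    diff_edge_sigma = 2.5,       # blurred chromatin edge, px
    spread_radius = c(30, 60),   # spread-NET equivalent radius, px
    spread_noise_w = 0.7,        # boundary-irregularity weight
    spread_noise_scale = 1 / 7,  # noise correlation length / radius
    spread_min_hcf = 1.4,
    level_bright  = c(2400, 3600),  # condensed chromatin, counts
    level_diff    = c(1440, 2160),  # ~40% dimmer than bright
    level_spread  = c(800, 1400),
    texture_amp   = 0.18,
    edge_sigma    = 1.2
  )
}

# Standardized smooth Gaussian random field.
smooth_noise <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma > 0) z <- gaussian_smooth(z, sigma)
  s <- stats::sd(z)
  if (s > 0) z <- (z - mean(z)) / s
  z
}

# Binary ellipse on an existing patch grid (pixel-centre test).
ellipse_on_grid <- function(nr, nc, cy, cx, a, b, theta) {
  rw <- matrix(seq_len(nr), nr, nc) - cy
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  u <- rw * cos(theta) + cl * sin(theta)
  v <- -rw * sin(theta) + cl * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

n_components <- function(mask) {
  max(EBImage::bwlabel(mask + 0L))
}

render_lobulated <- function(pars) {
  for (try in 1:25) {
    k <- sample(pars$lob_n_lobes, 1)
    ax <- matrix(stats::runif(2 * k, pars$lob_axis[1], pars$lob_axis[2]), k, 2)
    th <- stats::runif(k, 0, pi)
    ctr <- matrix(0, k, 2)
    for (j in seq_len(k)[-1]) {
      anchor <- sample(j - 1, 1)
      rsum <- mean(ax[anchor, ]) + mean(ax[j, ])
      d <- stats::runif(1, pars$lob_overlap[1], pars$lob_overlap[2]) * rsum
      phi <- stats::runif(1, 0, 2 * pi)
      cand <- ctr[anchor, ] + d * c(cos(phi), sin(phi))
      if (sqrt(sum(cand^2)) > pars$lob_span) {
        cand <- cand * pars$lob_span / sqrt(sum(cand^2))
      }
      ctr[j, ] <- cand
    }
    ext <- ceiling(max(sqrt(rowSums(ctr^2)) + apply(ax, 1, max))) + 5L
    n <- 2L * ext + 1L
    m <- matrix(FALSE, n, n)
    for (j in seq_len(k)) {
      m <- m | ellipse_on_grid(n, n, ext + 1 + ctr[j, 1], ext + 1 + ctr[j, 2],
                               ax[j, 1], ax[j, 2], th[j])
    }
    if (n_components(m) == 1) return(m)
  }
  stop("failed to render a connected lobulated nucleus")
}

render_delobulated <- function(pars) {
  a <- stats::runif(1, pars$delob_axis[1], pars$delob_axis[2])
  b <- stats::runif(1, pars$delob_axis[1], pars$delob_axis[2])
  th <- stats::runif(1, 0, pi)
  ext <- ceiling(max(a, b) * 1.15) + 5L
  n <- 2L * ext + 1L
  # delobulation is gradual: a fraction of nuclei keep mild residual
  # surface waviness from the receding lobes
  wobble <- stats::runif(1) < pars$delob_wobble_p
  if (!wobble) {
    return(ellipse_on_grid(n, n, ext + 1, ext + 1, a, b, th))
  }
  amp <- stats::runif(1, pars$delob_wobble_amp[1], pars$delob_wobble_amp[2])
  ks <- sample(3:6, 2)
  w <- stats::runif(2); w <- w / sum(w)
  ph <- stats::runif(2, 0, 2 * pi)
  rw <- matrix(seq_len(n), n, n) - (ext + 1)
  cl <- matrix(seq_len(n), n, n, byrow = TRUE) - (ext + 1)
  u <- rw * cos(th) + cl * sin(th)
  v <- -rw * sin(th) + cl * cos(th)
  phi <- atan2(v, u)
  rho <- 1 + amp * (w[1] * cos(ks[1] * phi + ph[1]) +
                    w[2] * cos(ks[2] * phi + ph[2]))
  (u / a)^2 + (v / b)^2 <= rho^2
}

render_diffused <- function(pars) {
  re <- stats::runif(1, pars$diff_radius[1], pars$diff_radius[2])
  ext <- ceiling(re) + 7L
  n <- 2L * ext + 1L
  ellipse_on_grid(n, n, ext + 1, ext + 1, re, re, 0)
}

render_spread <- function(pars) {
  for (try in 1:60) {
    re <- stats::runif(1, pars$spread_radius[1], pars$spread_radius[2])
    ext <- ceiling(1.6 * re) + 6L
    n <- 2L * ext + 1L
    z <- smooth_noise(n, n, sigma = re * pars$spread_noise_scale)
    rw <- matrix(seq_len(n), n, n) - (ext + 1)
    cl <- matrix(seq_len(n), n, n, byrow = TRUE) - (ext + 1)
    d <- sqrt(rw^2 + cl^2)
    g <- 1 - (d / re)^1.7 + pars$spread_noise_w * z
    target <- pi * re^2
    # threshold at the quantile matching the target area, then keep the
    # component under the patch centre and fill its holes
    t0 <- stats::quantile(g, 1 - target / length(g), names = FALSE)
    bw <- g > t0
    if (!bw[ext + 1, ext + 1]) next
    lab <- EBImage::bwlabel(bw + 0L)
    comp <- lab == lab[ext + 1, ext + 1]
    m <- as.matrix(EBImage::fillHull(EBImage::Image(comp + 0L))) > 0
    if (abs(sqrt(sum(m) / pi) - re) / re > 0.1) next
    hcf <- heywood_circularity(mask_perimeter(m), sum(m))
    if (hcf >= pars$spread_min_hcf) return(m)
  }
  stop("failed to render a spread NET with the required boundary irregularity")
}

#' Render one nucleus patch for a given NETosis stage
#'
#' Draws stage geometry from the current RNG state and returns a binary mask
#' patch together with a matching intensity patch (background not included).
#' Lobulated nuclei are unions of 3-5 overlapping ellipse lobes; delobulated
#' nuclei are single smooth ellipses; diffused NETs are larger blurred-edge
#' disks about 40% dimmer; spread NETs are large, dim, ragged regions carved
#' from thresholded smoothed noise with Heywood circularity at least 1.4.
#'
#' @param cls A single morphology class name.
#' @param pars Rendering parameter list (defaults to the package calibration).
#' @return List with elements `mask` (logical matrix), `intensity` (numeric
#'   matrix, counts), `class`, `level` (mean chromatin intensity drawn) and
#'   `extent` (half patch size, px).
#' @export
render_cell <- function(cls, pars = render_defaults()) {
  cls <- match.arg(cls, morphology_levels())
  m <- switch(cls,
    LOBULATED   = render_lobulated(pars),
    DELOBULATED = render_delobulated(pars),
    DIFFUSED    = render_diffused(pars),
    SPREAD      = render_spread(pars)
  )
  level <- switch(cls,
    LOBULATED   = stats::runif(1, pars$level_bright[1], pars$level_bright[2]),
    DELOBULATED = stats::runif(1, pars$level_bright[1], pars$level_bright[2]),
    DIFFUSED    = stats::runif(1, pars$level_diff[1], pars$level_diff[2]),
    SPREAD      = stats::runif(1, pars$level_spread[1], pars$level_spread[2])
  )
  edge_sigma <- if (cls == "DIFFUSED") pars$diff_edge_sigma else pars$edge_sigma
  profile <- gaussian_smooth(m + 0, edge_sigma)
  profile[profile < 0] <- 0
  tex <- 1 + pars$texture_amp * smooth_noise(nrow(m), ncol(m), sigma = 3)
  intensity <- level * profile * pmax(tex, 0.2)
  list(mask = m, intensity = intensity, class = cls, level = level,
       extent = (nrow(m) - 1L) / 2L)
}

#' Draw stage labels from a mixture
#'
#' Multinomial draw of `n` morphology classes from the given proportions.
#' Exposed so that mixture behaviour can be examined at large `n` without
#' rendering pixels.
#'
#' @param n Number of cells.
#' @param proportions Named proportions over the four stages (or preset name).
#' @return Character vector of length `n`.
#' @export
draw_classes <- function(n, proportions) {
  if (is.character(proportions)) proportions <- preset_proportions(proportions)
  lv <- morphology_levels()
  p <- as.numeric(proportions[lv])
  if (any(is.na(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("class proportions must be non-negative and sum to 1")
  }
  sample(lv, n, replace = TRUE, prob = p)
}

# Place rendered cells into one image frame by rejection sampling.
# Returns centre coordinates (rows of [row, col]) or raises a placement error.
place_centres <- function(extents, shape, overlap_allowed, min_gap = 4,
                          max_tries = 5000L) {
  k <- length(extents)
  ctr <- matrix(NA_real_, k, 2)
  ord <- order(extents, decreasing = TRUE)
  for (i in ord) {
    e <- extents[i]
    lo <- e + 2; hi_r <- shape[1] - e - 1; hi_c <- shape[2] - e - 1
    if (hi_r <= lo || hi_c <= lo) {
      stop("placement error: image too small for an object of extent ", e)
    }
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(stats::runif(1, lo, hi_r), stats::runif(1, lo, hi_c))
      if (!overlap_allowed) {
        others <- which(!is.na(ctr[, 1]))
        if (length(others) > 0) {
          dd <- sqrt((ctr[others, 1] - cand[1])^2 +
                     (ctr[others, 2] - cand[2])^2)
          if (any(dd < extents[others] + e + min_gap)) next
        }
      }
      ctr[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("placement error: could not place ", k,
           " non-overlapping cells in a ", shape[1], "x", shape[2], " image")
    }
  }
  ctr
}

compose_image <- function(cells, centres, config) {
  shape <- config$image_shape
  img <- matrix(config$background_level, shape[1], shape[2])
  lab <- matrix(0L, shape[1], shape[2])
  truth <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cc <- cells[[i]]
    e <- cc$extent
    r0 <- round(centres[i, 1]) - e; c0 <- round(centres[i, 2]) - e
    rows <- r0:(r0 + 2 * e); cols <- c0:(c0 + 2 * e)
    img[rows, cols] <- img[rows, cols] + cc$intensity
    sub <- lab[rows, cols]
    sub[cc$mask & sub == 0L] <- i
    lab[rows, cols] <- sub
    pix <- which(lab == i, arr.ind = TRUE)
    truth[[i]] <- data.frame(
      object_id = i,
      class = cc$class,
      centroid_row = mean(pix[, 1]),
      centroid_col = mean(pix[, 2]),
      area_px2 = nrow(pix)
    )
  }
  if (config$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, config$noise_sd)
  }
  img <- round(pmin(pmax(img, 0), 65535))
  storage.mode(lab) <- "integer"
  list(image = img, mask = lab, truth = do.call(rbind, truth))
}

#' Generate a seeded synthetic population of nuclei with ground truth
#'
#' Renders `n_images` fluorescence images of Sytox-stained nuclei whose
#' stages are drawn multinomially from the configured mixture, together with
#' instance label masks and a per-object ground-truth table. Identical
#' configuration and seed give bit-identical output.
#'
#' @param config A [population_config()], or a preset name (in which case the
#'   remaining configuration takes its defaults).
#' @param classes Optional explicit character vector of stage labels (length
#'   `n_images * cells_per_image`) overriding the multinomial draw; used to
#'   build exactly balanced training populations.
#' @return A list of class `"nucleus_population"` with elements `images`
#'   (list of integer matrices, 16-bit range), `masks` (list of integer label
#'   matrices, 0 = background), `truth` (data.frame: image_id, object_id,
#'   class, centroid_row, centroid_col, area_px2) and `config`.
#' @export
#' @examples
#' pop <- make_population(population_config(
#'   "unstimulated", cells_per_image = 4, n_images = 1,
#'   image_shape = c(256, 256), seed = 7))
#' pop$truth
make_population <- function(config, classes = NULL) {
  if (is.character(config)) config <- population_config(config)
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  total <- config$n_images * config$cells_per_image
  if (is.null(classes)) {
    classes <- if (total > 0) {
      draw_classes(total, config$class_proportions)
    } else character(0)
  } else {
    classes <- as.character(classes)
    if (length(classes) != total) {
      stop("classes must have length n_images * cells_per_image")
    }
  }
  images <- vector("list", config$n_images)
  masks <- vector("list", config$n_images)
  truth <- vector("list", config$n_images)
  for (im in seq_len(config$n_images)) {
    idx <- if (config$cells_per_image > 0) {
      ((im - 1) * config$cells_per_image + 1):(im * config$cells_per_image)
    } else integer(0)
    cells <- lapply(classes[idx], render_cell)
    if (length(cells) > 0) {
      centres <- place_centres(vapply(cells, `[[`, numeric(1), "extent"),
                               config$image_shape, config$overlap_allowed)
      comp <- compose_image(cells, centres, config)
      comp$truth <- cbind(image_id = im, comp$truth)
    } else {
      img <- matrix(config$background_level, config$image_shape[1],
                    config$image_shape[2])
      if (config$noise_sd > 0) {
        img <- img + stats::rnorm(length(img), 0, config$noise_sd)
      }
      comp <- list(image = round(pmin(pmax(img, 0), 65535)),
                   mask = matrix(0L, config$image_shape[1],
                                 config$image_shape[2]),
                   truth = data.frame(image_id = integer(0),
                                      object_id = integer(0),
                                      class = character(0),
                                      centroid_row = numeric(0),
                                      centroid_col = numeric(0),
                                      area_px2 = numeric(0)))
    }
    images[[im]] <- comp$image
    masks[[im]] <- comp$mask
    truth[[im]] <- comp$truth
  }
  structure(list(images = images, masks = masks,
                 truth = do.call(rbind, truth), config = config),
            class = "nucleus_population")
}

#' Exactly balanced labelled population
#'
#' Convenience wrapper around [make_population()] that renders exactly
#' `n_per_class` nuclei of each stage (shuffled across images) - the layout
#' used to build the default classifier training set.
#'
#' @param n_per_class Cells per stage.
#' @param seed Integer seed.
#' @param cells_per_image Cells per image frame.
#' @param image_shape Image size (rows, cols).
#' @return A `"nucleus_population"`.
#' @export
make_balanced_population <- function(n_per_class = 500L, seed = 0L,
                                     cells_per_image = 20L,
                                     image_shape = c(1024L, 1024L)) {
  total <- 4L * as.integer(n_per_class)
  n_images <- ceiling(total / cells_per_image)
  if (n_images * cells_per_image != total) {
    stop("4 * n_per_class must be divisible by cells_per_image")
  }
  cfg <- population_config(cells_per_image = cells_per_image,
                           n_images = n_images, image_shape = image_shape,
                           class_proportions = c(LOBULATED = 0.25,
                                                 DELOBULATED = 0.25,
                                                 DIFFUSED = 0.25,
                                                 SPREAD = 0.25),
                           seed = seed)
  set.seed(seed)
  classes <- sample(rep(morphology_levels(), each = n_per_class))
  make_population(cfg, classes = classes)
}

#' Simulate a Sytox-green DNA standard curve
#'
#' Plate-reader fluorescence for a grid of plasmid-DNA standards; the default
#' grid spans the 0.1-5 ng/ml range used for cfDNA quantification.
#'
#' @param concentrations DNA standard concentrations, ng/ml (non-negative).
#' @param slope True slope, RFU per ng/ml.
#' @param intercept True intercept (blank fluorescence), RFU.
#' @param noise_sd Gaussian reader noise, RFU.
#' @param seed Optional integer seed.
#' @return data.frame with columns `concentration_ng_ml`, `rfu`.
#' @export
simulate_standard_curve <- function(concentrations = c(0.1, 0.25, 0.5, 1,
                                                       2, 3, 4, 5),
                                    slope = 1000, intercept = 50,
                                    noise_sd = 25, seed = NULL) {
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  rfu <- intercept + slope * concentrations +
    stats::rnorm(length(concentrations), 0, noise_sd)
  data.frame(concentration_ng_ml = concentrations, rfu = rfu)
}

#' Simulate CFU records for a killing assay
#'
#' The noiseless surviving count is `control_cfu * (1 - killing_pct/100)`
#' rounded to the nearest integer; with `noise = TRUE` the surviving count is
#' Poisson with that mean (the standard error model for colony counts).
#'
#' @param control_cfu Control (bacteria-alone) CFU/ml, positive.
#' @param killing_pct True killing percentage, at most 100 (negative values
#'   encode net growth).
#' @param noise Poisson-sample the surviving count?
#' @param condition Condition label.
#' @param replicate Integer replicate ids (recycled).
#' @param seed Optional integer seed.
#' @return data.frame with columns `condition`, `replicate`, `control_cfu`,
#'   `sample_cfu`.
#' @export
simulate_cfu <- function(control_cfu, killing_pct, noise = FALSE,
                         condition = "sample", replicate = 1L, seed = NULL) {
  if (any(control_cfu <= 0)) stop("control_cfu must be positive")
  if (any(killing_pct > 100)) stop("killing_pct cannot exceed 100")
  if (!is.null(seed)) set.seed(seed)
  n <- max(length(control_cfu), length(killing_pct), length(replicate))
  control_cfu <- rep_len(control_cfu, n)
  killing_pct <- rep_len(killing_pct, n)
  replicate <- rep_len(as.integer(replicate), n)
  mu <- control_cfu * (1 - killing_pct / 100)
  sample_cfu <- if (noise) stats::rpois(n, mu) else round(mu)
  data.frame(condition = rep_len(condition, n), replicate = replicate,
             control_cfu = control_cfu, sample_cfu = sample_cfu)
}

#' Simulate routine blood counts for two donor groups
#'
#' Lognormal per-donor counts of neutrophils, eosinophils, lymphocytes and
#' monocytes (cells/ul) for healthy controls (HC) and hemodialysis patients
#' (HD). Neutrophil levels do not differ between groups; HD eosinophils are
#' scaled by `eos_scale_hd` (default 1.88, the elevation the assay suite is
#' designed to recover).
#'
#' @param n_hc,n_hd Donors per group.
#' @param eos_scale_hd Multiplicative HD eosinophil elevation.
#' @param seed Integer seed.
#' @return data.frame: donor_id, group, timepoint ("pre"), neutrophils,
#'   eosinophils, lymphocytes, monocytes.
#' @export
simulate_blood_counts <- function(n_hc = 40L, n_hd = 46L,
                                  eos_scale_hd = 1.88, seed = 1L) {
  set.seed(seed)
  one_group <- function(n, group, prefix, eos_scale) {
    data.frame(
      donor_id = paste0(prefix, seq_len(n)),
      group = group, timepoint = "pre",
      neutrophils = stats::rlnorm(n, log(4200), 0.30),
      eosinophils = stats::rlnorm(n, log(180) + log(eos_scale), 0.35),
      lymphocytes = stats::rlnorm(n, log(1800), 0.30),
      monocytes = stats::rlnorm(n, log(450), 0.30)
    )
  }
  rbind(one_group(n_hc, "HC", "HC", 1),
        one_group(n_hd, "HD", "HD", eos_scale_hd))
}

#' Simulate paired pre/post-dialysis blood counts
#'
#' Post-dialysis counts equal pre-dialysis counts perturbed by lognormal
#' noise with no systematic shift, emulating the observation that a dialysis
#' session leaves circulating immune-cell levels unchanged.
#'
#' @param n Number of paired donors.
#' @param change_sd s.d. of the per-donor log-ratio post/pre.
#' @param seed Integer seed.
#' @return data.frame in the same layout as [simulate_blood_counts()], two
#'   rows (`pre`, `post`) per donor, group `"HD"`.
#' @export
simulate_dialysis_counts <- function(n = 42L, change_sd = 0.10, seed = 1L) {
  set.seed(seed)
  pre <- data.frame(
    donor_id = paste0("HD", seq_len(n)), group = "HD", timepoint = "pre",
    neutrophils = stats::rlnorm(n, log(4200), 0.30),
    eosinophils = stats::rlnorm(n, log(180) + log(1.88), 0.35),
    lymphocytes = stats::rlnorm(n, log(1800), 0.30),
    monocytes = stats::rlnorm(n, log(450), 0.30)
  )
  post <- pre
  post$timepoint <- "post"
  for (col in c("neutrophils", "eosinophils", "lymphocytes", "monocytes")) {
    post[[col]] <- pre[[col]] * exp(stats::rnorm(n, 0, change_sd))
  }
  rbind(pre, post)
}
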