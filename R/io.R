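# On-disk formats: 16-bit single-channel TIFF for images and label masks,
# CSV with fixed headers for ground truth and feature tables, JSON sidecars
# echoing generation parameters.

#' Write a 16-bit single-channel TIFF
#'
#' @param pixels Numeric matrix in the 0-65535 range (intensities or
#'   integer labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(pixels, path) {
  if (any(pixels < 0) || any(pixels > 65535)) {
    stop("pixel values must lie in 0..65535")
  }
  EBImage::writeImage(EBImage::Image(pixels / 65535), path,
                      type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit single-channel TIFF (or PNG)
#'
#' @param path File path.
#' @return Integer matrix on the 0-65535 scale.
#' @export
read_image_tiff <- function(path) {
  img <- EBImage::readImage(path)
  m <- round(as.matrix(EBImage::imageData(img)) * 65535)
  storage.mode(m) <- "integer"
  m
}

#' Write a synthetic population to a directory
#'
#' Images under `images/`, label masks under `masks/` (both 16-bit TIFF;
#' mask value k = object k), ground truth as `truth.csv` and the full
#' generation parameters as a `config.json` sidecar.
#'
#' @param population A `"nucleus_population"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "nucleus_population"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(population$images)) {
    write_image_tiff(population$images[[i]],
                     file.path(dir, "images", sprintf("img_%03d.tif", i)))
    write_image_tiff(population$masks[[i]],
                     file.path(dir, "masks", sprintf("mask_%03d.tif", i)))
  }
  utils::write.csv(population$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- unclass(population$config)
  cfg$class_proportions <- as.list(cfg$class_proportions)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a population written by [write_population()]
#'
#' @param dir Directory path.
#' @return A `"nucleus_population"`.
#' @export
read_population <- function(dir) {
  img_files <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  mask_files <- sort(list.files(file.path(dir, "masks"), full.names = TRUE))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg_obj <- population_config(
    class_proportions = unlist(cfg$class_proportions),
    cells_per_image = cfg$cells_per_image, n_images = cfg$n_images,
    image_shape = cfg$image_shape,
    background_level = cfg$background_level, noise_sd = cfg$noise_sd,
    overlap_allowed = cfg$overlap_allowed, pixel_size = cfg$pixel_size,
    seed = cfg$seed)
  structure(list(images = lapply(img_files, read_image_tiff),
                 masks = lapply(mask_files, read_image_tiff),
                 truth = truth, config = cfg_obj),
            class = "nucleus_population")
}

#' Write a feature table as CSV with the canonical header order
#'
#' @param features Output of [extract_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  cols <- c("image_id", "object_id", extended_feature_names())
  utils::write.csv(features[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Object-summary CSV for a label mask
#'
#' One row per object: object id, centroid (row, col) and area in px^2.
#'
#' @param mask Integer label matrix.
#' @param path Output path.
#' @return The summary data.frame, invisibly.
#' @export
write_object_summary <- function(mask, path) {
  labs <- sort(unique(mask[mask > 0L]))
  rows <- lapply(labs, function(lb) {
    pix <- which(mask == lb, arr.ind = TRUE)
    data.frame(object_id = lb, centroid_row = mean(pix[, 1]),
               centroid_col = mean(pix[, 2]), area_px2 = nrow(pix))
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(object_id = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0), area_px2 = numeric(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
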