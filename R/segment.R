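# Instance segmentation of nuclei: Gaussian smoothing, global threshold,
# distance-transform watershed to split touching objects, then size/border
# filtering. A classical segmenter rather than a learned one: deterministic,
# dependency-light, and sufficient for single-channel Sytox images in which
# nuclei are bright on a dark background.

#' Segmentation parameters
#'
#' @param smoothing_sigma Gaussian pre-smoothing sigma, px.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Intensity threshold (counts) when
#'   `threshold_method = "fixed"`.
#' @param min_distance Minimum separation (px) of distance-transform maxima
#'   used as watershed seeds when splitting touching objects.
#' @param ws_tolerance Minimum height (px, in distance-map units) by which a
#'   local maximum must rise above its saddle to seed a split. The default
#'   (15) keeps multi-lobed and ragged single nuclei intact; small values
#'   split touching nuclei more aggressively.
#' @param min_area Objects smaller than this (px^2) are removed.
#' @param clear_border Remove objects touching any image edge (truncated
#'   morphology corrupts shape features).
#' @param refine_objects Re-cut each detected object at background plus half
#'   of its own interior brightness (within its watershed territory), so the
#'   measured boundary sits at the half-maximum of that object regardless of
#'   stage brightness.
#' @return List of class `"segmentation_params"`.
#' @export
segmentation_params <- function(smoothing_sigma = 2,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_distance = 10,
                                ws_tolerance = 15,
                                min_area = 60,
                                clear_border = TRUE,
                                refine_objects = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (smoothing_sigma < 0) stop("smoothing_sigma must be >= 0")
  if (min_area < 0) stop("min_area must be >= 0")
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    stop("fixed_threshold is required when threshold_method = 'fixed'")
  }
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_distance = min_distance,
                 ws_tolerance = ws_tolerance,
                 min_area = min_area,
                 clear_border = isTRUE(clear_border),
                 refine_objects = isTRUE(refine_objects)),
            class = "segmentation_params")
}

#' Segment nuclei from a single-channel fluorescence image
#'
#' Pipeline: Gaussian smoothing, global threshold (Otsu on the smoothed
#' image, or a fixed intensity), distance-transform watershed to split
#' touching objects, then [filter_labels()]. Deterministic for fixed inputs.
#' A blank (constant) image yields an empty mask, not an error.
#'
#' @param image Numeric intensity matrix (16-bit range).
#' @param params A [segmentation_params()].
#' @return Integer label matrix; 0 = background, labels contiguous 1..K.
#' @export
segment_nuclei <- function(image, params = segmentation_params()) {
  if (length(image) == 0) stop("image is empty")
  img <- image / 65535
  if (params$smoothing_sigma > 0) {
    img <- gaussian_smooth(img, params$smoothing_sigma)
  }
  thr <- if (params$threshold_method == "otsu") {
    if (max(img) - min(img) < 1e-12) {
      Inf  # constant image: nothing to find
    } else {
      # Otsu on log intensities: fluorescent nuclei span several-fold
      # brightness across stages, and the log transform keeps the global
      # threshold between background and the dimmest stage instead of
      # drifting into the middle of the stage brightness range.
      lg <- log1p(img * 65535)
      expm1(EBImage::otsu(EBImage::Image(lg), range = range(lg))) / 65535
    }
  } else {
    params$fixed_threshold / 65535
  }
  bw <- img > thr
  if (!any(bw)) {
    return(matrix(0L, nrow(image), ncol(image)))
  }
  dm <- EBImage::distmap(EBImage::Image(bw + 0))
  ws <- EBImage::watershed(dm, tolerance = params$ws_tolerance,
                           ext = params$min_distance)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(image), ncol(image))
  if (params$refine_objects) {
    lab <- refine_objects(img, lab)
  }
  filter_labels(lab, min_area = params$min_area,
                clear_border = params$clear_border)
}

# Per-object half-maximum refinement. The global threshold must sit below
# the dimmest stage, which dilates bright nuclei (their blurred intensity
# skirt crosses a low threshold well outside the true boundary). Each
# object is therefore re-cut at background + half of its own interior
# brightness, restricted to its watershed territory, which recovers the
# half-maximum boundary independent of stage brightness. Refinement only
# removes pixels from a label, so labels never collide.
refine_objects <- function(img, lab) {
  if (max(lab) == 0L) return(lab)
  bg <- stats::median(img)
  out <- lab
  for (lb in seq_len(max(lab))) {
    pix <- which(lab == lb, arr.ind = TRUE)
    if (nrow(pix) == 0) next
    r0 <- max(1L, min(pix[, 1]) - 2L); r1 <- min(nrow(lab), max(pix[, 1]) + 2L)
    c0 <- max(1L, min(pix[, 2]) - 2L); c1 <- min(ncol(lab), max(pix[, 2]) + 2L)
    box_img <- img[r0:r1, c0:c1]
    box_lab <- lab[r0:r1, c0:c1]
    level <- stats::quantile(img[pix] - bg, 0.75, names = FALSE)
    ti <- bg + 0.5 * level
    cand <- box_img > ti & box_lab == lb
    if (!any(cand)) next
    cc <- EBImage::bwlabel(cand + 0L)
    # keep the dominant component above the half-maximum, holes filled
    areas <- tabulate(cc[cc > 0], nbins = max(cc))
    main <- which.max(areas)
    m <- as.matrix(EBImage::fillHull(EBImage::Image((cc == main) + 0L))) > 0
    sub <- out[r0:r1, c0:c1]
    sub[sub == lb] <- 0L
    sub[m & box_lab == lb] <- lb
    out[r0:r1, c0:c1] <- sub
  }
  out
}

#' Filter and relabel an instance mask
#'
#' Removes objects smaller than `min_area` and (optionally) objects touching
#' any image edge, then renumbers the surviving labels contiguously 1..K in
#' increasing order of their original label.
#'
#' @param mask Integer label matrix (0 = background).
#' @param min_area Minimum object area, px^2.
#' @param clear_border Remove edge-touching objects?
#' @return Filtered, contiguously relabelled integer matrix.
#' @export
filter_labels <- function(mask, min_area = 0, clear_border = FALSE) {
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  labs <- mask[mask > 0L]
  if (length(labs) == 0) return(mask)
  K <- max(labs)
  areas <- tabulate(labs, nbins = K)
  keep <- areas >= min_area & areas > 0
  if (clear_border) {
    border <- c(mask[1, ], mask[nrow(mask), ], mask[, 1], mask[, ncol(mask)])
    keep[unique(border[border > 0L])] <- FALSE
  }
  map <- integer(K)
  map[which(keep)] <- seq_len(sum(keep))
  out <- mask
  out[out > 0L] <- map[out[out > 0L]]
  out
}

#' Per-object overlap between a predicted and a ground-truth mask
#'
#' Matches each ground-truth object to the predicted label occupying the
#' majority of its pixels and reports the Jaccard index of the pair (0 when
#' a truth object has no overlapping prediction).
#'
#' @param predicted Integer label matrix.
#' @param truth_mask Integer label matrix of the same shape.
#' @return data.frame: truth_id, predicted_id (0 = unmatched), jaccard.
#' @export
mask_overlap <- function(predicted, truth_mask) {
  stopifnot(all(dim(predicted) == dim(truth_mask)))
  ids <- sort(unique(truth_mask[truth_mask > 0L]))
  rows <- lapply(ids, function(tid) {
    sel <- truth_mask == tid
    hits <- predicted[sel]
    hits <- hits[hits > 0L]
    if (length(hits) == 0) {
      return(data.frame(truth_id = tid, predicted_id = 0L, jaccard = 0))
    }
    pid <- as.integer(names(which.max(table(hits))))
    inter <- sum(sel & predicted == pid)
    uni <- sum(sel | predicted == pid)
    data.frame(truth_id = tid, predicted_id = pid, jaccard = inter / uni)
  })
  do.call(rbind, rows)
}
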