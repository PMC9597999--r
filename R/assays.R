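# Plate-assay quantification: cfDNA from Sytox-green fluorescence via a
# DNA standard curve, and bacterial-killing percentages from CFU counts.

#' Fit a DNA standard curve
#'
#' Ordinary least-squares line RFU = intercept + slope * concentration over
#' the DNA standards (a free intercept; the blank is not forced to zero).
#'
#' @param concentrations DNA standard concentrations, ng/ml (at least two
#'   distinct values).
#' @param rfu Measured fluorescence, RFU.
#' @return List of class `"standard_curve"`: `slope`, `intercept`,
#'   `r_squared` (squared Pearson correlation), `n_points`, `range`.
#' @export
#' @examples
#' fit_standard_curve(c(1, 2, 3), c(1050, 2050, 3050))
fit_standard_curve <- function(concentrations, rfu) {
  if (length(concentrations) != length(rfu)) {
    stop("concentrations and rfu must have equal length")
  }
  if (length(concentrations) < 2) stop("need at least 2 standard points")
  if (length(unique(concentrations)) < 2) {
    stop("need at least 2 distinct concentrations")
  }
  fit <- stats::lm(rfu ~ concentrations)
  co <- stats::coef(fit)
  r2 <- stats::cor(concentrations, rfu)^2
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2, n_points = length(rfu),
                 range = range(concentrations)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: RFU = %.2f + %.2f x conc (r^2 = %.4f, n = %d, %.2g-%.2g ng/ml)\n",
    x$intercept, x$slope, x$r_squared, x$n_points, x$range[1], x$range[2]))
  invisible(x)
}

#' Convert fluorescence readings to cfDNA concentration
#'
#' Inverts the standard curve: `(rfu - intercept) / slope`. Readings below
#' the blank (negative concentration) are reported as 0 and flagged in the
#' `below_blank` attribute.
#'
#' @param curve A `"standard_curve"` with positive slope.
#' @param rfu Fluorescence readings, RFU.
#' @return Numeric cfDNA concentrations, ng/ml, with a logical attribute
#'   `below_blank`.
#' @export
rfu_to_cfdna <- function(curve, rfu) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope <= 0) stop("standard curve slope must be positive")
  conc <- (rfu - curve$intercept) / curve$slope
  below <- conc < 0
  conc[below] <- 0
  attr(conc, "below_blank") <- below
  conc
}

#' Bacterial-killing percentage from CFU counts
#'
#' `100 * (1 - sample_cfu / control_cfu)`, the killing percentage relative
#' to the bacteria-alone control. Negative values (net growth) are allowed
#' and flagged in the `net_growth` attribute.
#'
#' @param sample_cfu Surviving CFU/ml in the test condition (>= 0).
#' @param control_cfu CFU/ml of the control culture (> 0).
#' @return Killing percentages with a logical `net_growth` attribute.
#' @export
#' @examples
#' killing_percent(2707, 10000)  # 72.93
killing_percent <- function(sample_cfu, control_cfu) {
  if (any(control_cfu <= 0)) stop("control_cfu must be positive")
  if (any(sample_cfu < 0)) stop("sample_cfu must be non-negative")
  pct <- 100 * (1 - sample_cfu / control_cfu)
  attr(pct, "net_growth") <- pct < 0
  pct
}

#' CFU/ml from a plated serial dilution
#'
#' @param colonies Colony count on the plate (>= 0).
#' @param dilution_factor Total dilution factor (>= 1).
#' @param plated_volume_ml Plated volume, ml (> 0).
#' @return CFU/ml = `colonies * dilution_factor / plated_volume_ml`.
#' @export
cfu_from_dilution <- function(colonies, dilution_factor, plated_volume_ml) {
  if (any(colonies < 0)) stop("colonies must be non-negative")
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  if (any(plated_volume_ml <= 0)) stop("plated_volume_ml must be positive")
  colonies * dilution_factor / plated_volume_ml
}

#' Replicate summary of killing percentages
#'
#' Mean and s.d. of the per-replicate killing percentage for each
#' (condition, mode) group; no outlier rejection.
#'
#' @param records data.frame with columns `condition`, `mode` (e.g.
#'   "total", "extracellular", "extracellular+DNase"), `replicate`,
#'   `control_cfu`, `sample_cfu`.
#' @return data.frame: condition, mode, n, mean_killing, sd_killing.
#' @export
killing_summary <- function(records) {
  need <- c("condition", "mode", "control_cfu", "sample_cfu")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  records$killing <- as.numeric(killing_percent(records$sample_cfu,
                                                records$control_cfu))
  agg_m <- stats::aggregate(killing ~ condition + mode, records, mean)
  names(agg_m)[3] <- "mean_killing"
  agg_s <- stats::aggregate(killing ~ condition + mode, records,
                            function(v) if (length(v) > 1) stats::sd(v) else NA_real_)
  names(agg_s)[3] <- "sd_killing"
  agg_n <- stats::aggregate(killing ~ condition + mode, records, length)
  names(agg_n)[3] <- "n"
  out <- merge(merge(agg_n, agg_m, by = c("condition", "mode")),
               agg_s, by = c("condition", "mode"))
  out[order(out$condition, out$mode), ]
}

#' NET-attributable extracellular killing
#'
#' Difference between the mean extracellular killing (phagocytosis blocked
#' with cytochalasin D) and the mean killing with DNase I added (which
#' degrades NET DNA): the component of extracellular killing attributable
#' to NETs. On noisy data the difference can come out negative; it is then
#' flagged rather than truncated.
#'
#' @param summary Output of [killing_summary()].
#' @param condition Condition label to extract.
#' @param extracellular_mode,dnase_mode Mode labels in the summary.
#' @return List: `net_attributable` (percentage points), `flagged_negative`.
#' @export
net_attributable_killing <- function(summary, condition,
                                     extracellular_mode = "extracellular",
                                     dnase_mode = "extracellular+DNase") {
  sel <- summary$condition == condition
  ex <- summary$mean_killing[sel & summary$mode == extracellular_mode]
  dn <- summary$mean_killing[sel & summary$mode == dnase_mode]
  if (length(ex) != 1 || length(dn) != 1) {
    stop("condition '", condition, "' needs exactly one '",
         extracellular_mode, "' and one '", dnase_mode, "' row")
  }
  diff <- ex - dn
  list(net_attributable = diff, flagged_negative = diff < 0)
}
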