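# Population-level readouts: per-donor/condition stage distributions,
# condition comparisons, and the simple blood-count statistics (paired
# pre/post-dialysis t-tests and the neutrophil/eosinophil ratio).

#' Per-donor and pooled stage distributions
#'
#' Aggregates per-cell stage calls into counts and fractions of the four
#' stages for every (donor, condition) pair, plus pooled per-condition
#' fractions and per-donor mean and s.d. of the fractions.
#'
#' @param predictions data.frame with columns `donor_id`, `condition`,
#'   `class` (one row per cell).
#' @return List of class `"class_distribution"`: `per_donor` (donor_id,
#'   condition, class, count, fraction, n_cells), `pooled` (condition,
#'   class, count, fraction, n_cells, donor_mean, donor_sd).
#' @export
class_distribution <- function(predictions) {
  lv <- morphology_levels()
  if (nrow(predictions) == 0) {
    return(structure(list(
      per_donor = data.frame(donor_id = character(0), condition = character(0),
                             class = character(0), count = integer(0),
                             fraction = numeric(0), n_cells = integer(0)),
      pooled = data.frame(condition = character(0), class = character(0),
                          count = integer(0), fraction = numeric(0),
                          n_cells = integer(0), donor_mean = numeric(0),
                          donor_sd = numeric(0))
    ), class = "class_distribution"))
  }
  need <- c("donor_id", "condition", "class")
  if (!all(need %in% names(predictions))) {
    stop("predictions must have columns: ", paste(need, collapse = ", "))
  }
  cls <- factor(as.character(predictions$class), levels = lv)
  if (anyNA(cls)) stop("predictions contain classes outside the four stages")
  tab <- as.data.frame(table(donor_id = predictions$donor_id,
                             condition = predictions$condition,
                             class = cls))
  names(tab)[4] <- "count"
  totals <- stats::aggregate(count ~ donor_id + condition, tab, sum)
  names(totals)[3] <- "n_cells"
  per_donor <- merge(tab, totals, by = c("donor_id", "condition"))
  per_donor <- per_donor[per_donor$n_cells > 0, ]
  per_donor$fraction <- per_donor$count / per_donor$n_cells
  per_donor <- per_donor[order(per_donor$condition, per_donor$donor_id,
                               match(per_donor$class, lv)),
                         c("donor_id", "condition", "class", "count",
                           "fraction", "n_cells")]
  pooled_tab <- stats::aggregate(count ~ condition + class, per_donor, sum)
  pooled_tot <- stats::aggregate(count ~ condition, pooled_tab, sum)
  names(pooled_tot)[2] <- "n_cells"
  pooled <- merge(pooled_tab, pooled_tot, by = "condition")
  pooled$fraction <- pooled$count / pooled$n_cells
  dmean <- stats::aggregate(fraction ~ condition + class, per_donor, mean)
  names(dmean)[3] <- "donor_mean"
  dsd <- stats::aggregate(fraction ~ condition + class, per_donor,
                          function(v) if (length(v) > 1) stats::sd(v) else NA_real_)
  names(dsd)[3] <- "donor_sd"
  pooled <- merge(merge(pooled, dmean, by = c("condition", "class")),
                  dsd, by = c("condition", "class"))
  pooled <- pooled[order(pooled$condition, match(pooled$class, lv)),
                   c("condition", "class", "count", "fraction", "n_cells",
                     "donor_mean", "donor_sd")]
  rownames(per_donor) <- rownames(pooled) <- NULL
  structure(list(per_donor = per_donor, pooled = pooled),
            class = "class_distribution")
}

#' @export
print.class_distribution <- function(x, ...) {
  cat("Stage distribution over",
      length(unique(x$per_donor$donor_id)), "donor(s),",
      length(unique(x$per_donor$condition)), "condition(s)\n")
  print(x$pooled, digits = 3)
  invisible(x)
}

pooled_counts <- function(dist) {
  lv <- morphology_levels()
  out <- stats::setNames(rep(0, 4), lv)
  if (nrow(dist$pooled) == 0) return(out)
  agg <- stats::aggregate(count ~ class, dist$pooled, sum)
  out[as.character(agg$class)] <- agg$count
  out
}

#' Chi-square comparison of two stage distributions
#'
#' Pearson chi-square (no continuity correction) on the pooled 2 x 4 count
#' table of the two distributions. Stages with zero total count across both
#' groups are dropped from the table (they contribute no information and
#' would make the expected counts degenerate).
#'
#' @param dist_a,dist_b `"class_distribution"` objects over the same stages.
#' @return List: `statistic`, `p_value`, `df`, `table` (the 2 x K counts).
#' @export
compare_conditions <- function(dist_a, dist_b) {
  ca <- pooled_counts(dist_a)
  cb <- pooled_counts(dist_b)
  if (sum(ca) == 0 || sum(cb) == 0) {
    stop("both distributions must have a positive total count")
  }
  tab <- rbind(a = ca, b = cb)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (identical(unname(ca), unname(cb)) || ncol(tab) < 2) {
    # identical tables, or a single shared stage: no compositional evidence
    return(list(statistic = 0, p_value = 1,
                df = max(ncol(tab) - 1, 0), table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = unname(ct$parameter), table = tab)
}

#' Paired pre/post-dialysis comparison of a blood-count cell type
#'
#' Two-sided paired t-test on per-donor (post - pre) differences, with the
#' mean percentage change. Donors lacking either timepoint are excluded and
#' counted. When every difference is exactly zero the statistic is reported
#' as 0 with p = 1 (the no-change case).
#'
#' @param counts Blood-count data.frame (see [simulate_dialysis_counts()]):
#'   columns donor_id, timepoint ("pre"/"post") and the cell-type columns.
#' @param cell_type Column to test, e.g. `"neutrophils"`.
#' @return List: `statistic`, `p_value`, `mean_pct_change`, `n_pairs`,
#'   `n_excluded`.
#' @export
paired_pre_post <- function(counts, cell_type) {
  if (!cell_type %in% names(counts)) {
    stop("unknown cell type column: ", cell_type)
  }
  pre <- counts[counts$timepoint == "pre", c("donor_id", cell_type)]
  post <- counts[counts$timepoint == "post", c("donor_id", cell_type)]
  donors <- intersect(pre$donor_id, post$donor_id)
  n_excluded <- length(setdiff(union(pre$donor_id, post$donor_id), donors))
  if (n_excluded > 0) {
    warning(n_excluded, " unpaired donor(s) excluded")
  }
  if (length(donors) < 2) stop("need at least 2 complete pre/post pairs")
  x_pre <- pre[[cell_type]][match(donors, pre$donor_id)]
  x_post <- post[[cell_type]][match(donors, post$donor_id)]
  d <- x_post - x_pre
  pct <- mean((x_post - x_pre) / x_pre) * 100
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(statistic = 0, p_value = 1, mean_pct_change = pct,
                  n_pairs = length(donors), n_excluded = n_excluded))
    }
    return(list(statistic = sign(mean(d)) * Inf, p_value = 0,
                mean_pct_change = pct, n_pairs = length(donors),
                n_excluded = n_excluded))
  }
  tt <- stats::t.test(x_post, x_pre, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_pct_change = pct, n_pairs = length(donors),
       n_excluded = n_excluded)
}

#' Neutrophil/eosinophil ratio per donor, with group medians
#'
#' Donors with zero eosinophils have an undefined ratio and are excluded
#' (and counted), matching the density-of-ratio presentation of this
#' readout.
#'
#' @param counts Blood-count data.frame with columns donor_id, group,
#'   neutrophils, eosinophils.
#' @return List: `per_donor` (donor_id, group, ratio), `group_medians`
#'   (named numeric), `n_excluded`.
#' @export
neut_eos_ratio <- function(counts) {
  ok <- counts$eosinophils > 0
  n_excluded <- sum(!ok)
  kept <- counts[ok, ]
  if (nrow(kept) == 0) stop("all donors excluded (zero eosinophils)")
  per_donor <- data.frame(donor_id = kept$donor_id, group = kept$group,
                          ratio = kept$neutrophils / kept$eosinophils)
  med <- tapply(per_donor$ratio, per_donor$group, stats::median)
  list(per_donor = per_donor,
       group_medians = stats::setNames(as.numeric(med), names(med)),
       n_excluded = n_excluded)
}
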