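# End-to-end orchestration: simulate -> segment -> features -> classify ->
# distributions, with every random draw derived from one base seed.

# Deterministic per-task seed stream (kept inside 32-bit integer range).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 104729 * 48271 + k * 7919 + 12345) %%
             2147483647)
}

#' Pipeline configuration
#'
#' @param conditions Named character vector mapping condition labels to
#'   mixture presets (see [preset_proportions()]).
#' @param donors_per_condition Donors simulated per condition.
#' @param cells_per_donor Cells per donor (must be divisible by
#'   `cells_per_image`).
#' @param cells_per_image Cells per image frame.
#' @param image_shape Image size (rows, cols).
#' @param segmentation A [segmentation_params()].
#' @param n_train_per_class Training-set size per stage for the default
#'   classifier (ignored when `model` is supplied).
#' @param split Training fraction for the classifier.
#' @param seed Base seed; all stage seeds derive from it.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "segment", "features", "classify", "distribution")`.
#'   Later stages require the earlier ones.
#' @param model Optional pre-fitted `"net_classifier"`; when `NULL` the
#'   default classifier is trained as part of the run.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(conditions = c(unstimulated = "unstimulated",
                                           HC_A23187 = "HC_A23187",
                                           HD_A23187 = "HD_A23187"),
                            donors_per_condition = 6L,
                            cells_per_donor = 100L,
                            cells_per_image = 20L,
                            image_shape = c(1024L, 1024L),
                            segmentation = segmentation_params(),
                            n_train_per_class = 500L,
                            split = 0.7,
                            seed = 0L,
                            stages = c("simulate", "segment", "features",
                                       "classify", "distribution"),
                            model = NULL) {
  all_stages <- c("simulate", "segment", "features", "classify",
                  "distribution")
  stages <- intersect(all_stages, stages)
  if (length(stages) > 0) {
    needed <- all_stages[seq_len(max(match(stages, all_stages)))]
    if (!all(needed %in% stages)) {
      stop("stages must be a prefix of the pipeline: ",
           paste(all_stages, collapse = " -> "))
    }
  }
  if (cells_per_donor %% cells_per_image != 0) {
    stop("cells_per_donor must be divisible by cells_per_image")
  }
  structure(list(conditions = conditions,
                 donors_per_condition = as.integer(donors_per_condition),
                 cells_per_donor = as.integer(cells_per_donor),
                 cells_per_image = as.integer(cells_per_image),
                 image_shape = as.integer(image_shape),
                 segmentation = segmentation,
                 n_train_per_class = as.integer(n_train_per_class),
                 split = split, seed = as.integer(seed),
                 stages = stages, model = model),
            class = "pipeline_config")
}

#' Run the NETosis quantification pipeline
#'
#' Executes the enabled stages in order. For each condition and donor a
#' seeded population is rendered, segmented and measured; the classifier
#' (supplied, or trained on the default balanced set) assigns a stage to
#' every segmented object; stage distributions are aggregated per donor and
#' condition and the stimulated conditions are compared by chi-square.
#' The whole run is a pure function of the configuration and its seed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `"net_run_report"`: `seed`, `stages`,
#'   `n_cells_simulated`, `n_objects_segmented`, `n_cells_classified`,
#'   `validation` (classifier report, when trained), `predictions`
#'   (per-cell calls), `distribution` (a `"class_distribution"`),
#'   `comparison` (chi-square between the two stimulated conditions, when
#'   present) and `config_echo`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- structure(list(seed = config$seed, stages = config$stages,
                           n_cells_simulated = 0L,
                           n_objects_segmented = 0L,
                           n_cells_classified = 0L,
                           validation = NULL, predictions = NULL,
                           distribution = NULL, comparison = NULL,
                           config_echo = config[setdiff(names(config),
                                                        "model")]),
                      class = "net_run_report")
  if (length(config$stages) == 0) return(report)

  model <- config$model
  if (is.null(model) && "classify" %in% config$stages) {
    fit <- default_classifier(n_per_class = config$n_train_per_class,
                              seed = derive_seed(config$seed, 1L),
                              split = config$split)
    model <- fit$model
    report$validation <- fit$report
  }

  pred_rows <- list()
  n_images_per_donor <- config$cells_per_donor %/% config$cells_per_image
  for (ci in seq_along(config$conditions)) {
    cond <- names(config$conditions)[ci]
    if (is.null(cond) || cond == "") cond <- config$conditions[[ci]]
    for (d in seq_len(config$donors_per_condition)) {
      pop_seed <- derive_seed(config$seed, 100L * ci + d)
      cfg <- population_config(
        class_proportions = config$conditions[[ci]],
        cells_per_image = config$cells_per_image,
        n_images = n_images_per_donor,
        image_shape = config$image_shape,
        seed = pop_seed)
      pop <- make_population(cfg)
      report$n_cells_simulated <- report$n_cells_simulated + nrow(pop$truth)
      if (!"segment" %in% config$stages) next
      masks <- lapply(pop$images, segment_nuclei,
                      params = config$segmentation)
      n_obj <- sum(vapply(masks, max, numeric(1)))
      report$n_objects_segmented <- report$n_objects_segmented + n_obj
      if (!"features" %in% config$stages) next
      feats <- extract_features_all(pop$images, masks)
      if (!"classify" %in% config$stages) next
      cls <- predict(model, feats)
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        donor_id = paste0(cond, "_donor", d), condition = cond,
        image_id = feats$image_id, object_id = feats$object_id,
        class = as.character(cls))
    }
  }
  if (length(pred_rows) > 0) {
    report$predictions <- do.call(rbind, pred_rows)
    report$n_cells_classified <- nrow(report$predictions)
  }
  if ("distribution" %in% config$stages && !is.null(report$predictions)) {
    report$distribution <- class_distribution(report$predictions)
    conds <- unique(report$predictions$condition)
    stim <- setdiff(conds, "unstimulated")
    if (length(stim) == 2) {
      da <- class_distribution(
        report$predictions[report$predictions$condition == stim[1], ])
      db <- class_distribution(
        report$predictions[report$predictions$condition == stim[2], ])
      report$comparison <- c(list(conditions = stim),
                             compare_conditions(da, db))
    }
  }
  report
}

#' @export
print.net_run_report <- function(x, ...) {
  cat("NETosis pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("  stages: ", paste(x$stages, collapse = " -> "), "\n", sep = "")
  cat("  cells simulated: ", x$n_cells_simulated,
      "; segmented: ", x$n_objects_segmented,
      "; classified: ", x$n_cells_classified, "\n", sep = "")
  if (!is.null(x$validation)) {
    cat(sprintf("  classifier validation accuracy: %.3f\n",
                x$validation$accuracy))
  }
  if (!is.null(x$distribution)) print(x$distribution)
  invisible(x)
}

#' Write a run report as JSON
#'
#' Serializes the scalar sections, validation report, pooled distribution
#' and comparison (per-cell predictions are written separately as CSV if
#' needed).
#'
#' @param report A `"net_run_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  out <- list(
    seed = report$seed, stages = report$stages,
    n_cells_simulated = report$n_cells_simulated,
    n_objects_segmented = report$n_objects_segmented,
    n_cells_classified = report$n_cells_classified
  )
  if (!is.null(report$validation)) {
    out$validation <- list(
      accuracy = report$validation$accuracy,
      n_train = report$validation$n_train,
      n_valid = report$validation$n_valid,
      confusion = as.data.frame.matrix(report$validation$confusion))
  }
  if (!is.null(report$distribution)) {
    out$pooled_distribution <- report$distribution$pooled
  }
  if (!is.null(report$comparison)) {
    out$comparison <- report$comparison[c("conditions", "statistic",
                                          "p_value", "df")]
  }
  cfg <- report$config_echo
  cfg$segmentation <- unclass(cfg$segmentation)
  out$config <- cfg
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
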