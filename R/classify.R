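# Four-class nuclear-morphology classifier: a random forest over the
# morphometric feature table, trained on a stratified 70/30 split of
# labelled objects and reported against the held-out 30%.

match_labels <- function(features, labels) {
  # labels: character/factor aligned with rows, or a data.frame carrying
  # image_id + object_id + class (e.g. a ground-truth table)
  if (is.data.frame(labels)) {
    need <- c("image_id", "object_id", "class")
    if (!all(need %in% names(labels))) {
      stop("label table must have columns: ", paste(need, collapse = ", "))
    }
    key_f <- paste(features$image_id, features$object_id)
    key_l <- paste(labels$image_id, labels$object_id)
    idx <- match(key_f, key_l)
    if (anyNA(idx)) {
      stop("id mismatch: ", sum(is.na(idx)),
           " feature row(s) have no matching label")
    }
    as.character(labels$class)[idx]
  } else {
    if (length(labels) != nrow(features)) {
      stop("labels must align with feature rows")
    }
    as.character(labels)
  }
}

#' Train and validate the nuclear-morphology classifier
#'
#' Stratified split of the labelled objects into a training fraction
#' (default 70%) and a validation remainder; a random forest (200 trees,
#' per-class balanced in-bag sampling) is fitted on the training partition
#' only and the validation report is computed on the held-out partition
#' only. A fixed seed makes the split and the fitted forest reproducible.
#'
#' @param features Feature table from [extract_features()].
#' @param labels Stage labels: a vector aligned with `features` rows, or a
#'   ground-truth data.frame with image_id, object_id, class.
#' @param split Training fraction, in (0, 1).
#' @param seed Integer seed.
#' @param feature_set `"extended"` (default, all eight features) or
#'   `"core"` (area, perimeter, Heywood circularity, integrated density).
#' @param ntree Number of trees.
#' @return List with `model` (a `"net_classifier"`) and `report` (a
#'   `"net_validation"`, see [confusion_report()]).
#' @export
train_classifier <- function(features, labels, split = 0.7, seed = 0L,
                             feature_set = c("extended", "core"),
                             ntree = 200L) {
  feature_set <- match.arg(feature_set)
  if (split <= 0 || split >= 1) stop("split must be in (0, 1)")
  y <- match_labels(features, labels)
  lv <- morphology_levels()
  missing_cls <- setdiff(lv, unique(y))
  if (length(missing_cls) > 0) {
    stop("class absent from labels: ", paste(missing_cls, collapse = ", "))
  }
  if (length(unique(y)) < 2) stop("need at least 2 classes to train")
  counts <- table(factor(y, levels = lv))
  if (any(counts < 20)) {
    stop("need at least 20 labelled objects per class; got minimum ",
         min(counts))
  }
  cols <- if (feature_set == "extended") extended_feature_names()
          else core_feature_names()
  miss <- setdiff(cols, names(features))
  if (length(miss) > 0) {
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  }
  yf <- factor(y, levels = lv)
  set.seed(seed)
  train_idx <- unlist(lapply(lv, function(cl) {
    ix <- which(yf == cl)
    sample(ix, floor(split * length(ix)))
  }), use.names = FALSE)
  valid_idx <- setdiff(seq_len(nrow(features)), train_idx)
  x <- features[, cols, drop = FALSE]
  nmin <- min(table(yf[train_idx]))
  forest <- randomForest::randomForest(
    x = x[train_idx, , drop = FALSE], y = droplevels(yf[train_idx]),
    ntree = ntree, strata = droplevels(yf[train_idx]),
    sampsize = rep(nmin, length(lv))
  )
  model <- structure(list(
    forest = forest, feature_names = cols, feature_set = feature_set,
    classes = lv, split = split, seed = seed, ntree = ntree,
    train_idx = sort(train_idx), valid_idx = valid_idx,
    n_train = length(train_idx), n_valid = length(valid_idx)
  ), class = "net_classifier")
  pred <- predict(model, features[valid_idx, , drop = FALSE])
  report <- confusion_report(yf[valid_idx], pred,
                             n_train = length(train_idx))
  list(model = model, report = report)
}

#' @export
print.net_classifier <- function(x, ...) {
  cat("Nuclear-morphology random forest (", x$ntree, " trees, ",
      x$feature_set, " feature set)\n", sep = "")
  cat("  trained on ", x$n_train, " objects (split ", x$split,
      ", seed ", x$seed, "), validated on ", x$n_valid, "\n", sep = "")
  invisible(x)
}

#' Predict morphology classes for a feature table
#'
#' @param object A `"net_classifier"`.
#' @param features Feature table; must contain every column the model was
#'   trained on (an informative error lists any that are missing).
#' @param ... Unused.
#' @return Factor of stage labels, one per row.
#' @export
predict.net_classifier <- function(object, features, ...) {
  miss <- setdiff(object$feature_names, names(features))
  if (length(miss) > 0) {
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(features) == 0) {
    return(factor(character(0), levels = object$classes))
  }
  p <- predict(object$forest,
               newdata = features[, object$feature_names, drop = FALSE])
  factor(as.character(p), levels = object$classes)
}

#' Confusion matrix, accuracy and per-class precision/recall
#'
#' @param truth True stage labels.
#' @param predicted Predicted stage labels.
#' @param n_train Training-set size recorded in the report (metadata).
#' @return List of class `"net_validation"`: `accuracy`
#'   (trace / total), `confusion` (4x4 counts, rows = truth), `precision`,
#'   `recall` (per class), `n_train`, `n_valid`.
#' @export
confusion_report <- function(truth, predicted, n_train = NA_integer_) {
  lv <- morphology_levels()
  truth <- factor(as.character(truth), levels = lv)
  predicted <- factor(as.character(predicted), levels = lv)
  cm <- table(truth = truth, predicted = predicted)
  total <- sum(cm)
  acc <- if (total > 0) sum(diag(cm)) / total else NA_real_
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  structure(list(accuracy = acc, confusion = cm,
                 precision = prec, recall = rec,
                 n_train = n_train, n_valid = total),
            class = "net_validation")
}

#' @export
print.net_validation <- function(x, ...) {
  cat(sprintf("Validation: accuracy %.3f on %d held-out objects\n",
              x$accuracy, x$n_valid))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a fitted classifier against labelled features
#'
#' @param model A `"net_classifier"`.
#' @param features Feature table.
#' @param labels Stage labels (vector or ground-truth data.frame; an id
#'   mismatch between features and labels is an error).
#' @return A `"net_validation"` report.
#' @export
evaluate_classifier <- function(model, features, labels) {
  y <- match_labels(features, labels)
  pred <- predict(model, features)
  confusion_report(y, pred, n_train = model$n_train)
}

# Build the default labelled training material: a balanced population run
# through the segmentation and morphometry stages, with truth labels
# transferred onto segmented objects via the truth centroids.
labelled_features <- function(population,
                              params = segmentation_params()) {
  masks_pred <- lapply(population$images, segment_nuclei, params = params)
  feats <- extract_features_all(population$images, masks_pred)
  truth <- population$truth
  lab <- rep(NA_character_, nrow(feats))
  dropped <- 0L
  for (im in unique(truth$image_id)) {
    tr <- truth[truth$image_id == im, ]
    pm <- masks_pred[[im]]
    hit <- pm[cbind(pmin(pmax(round(tr$centroid_row), 1), nrow(pm)),
                    pmin(pmax(round(tr$centroid_col), 1), ncol(pm)))]
    ok <- hit > 0 & !duplicated(hit) & !duplicated(hit, fromLast = TRUE)
    dropped <- dropped + sum(!ok)
    sel <- feats$image_id == im
    lab[sel][match(hit[ok], feats$object_id[sel])] <- tr$class[ok]
  }
  keep <- !is.na(lab)
  structure(list(features = feats[keep, , drop = FALSE],
                 labels = lab[keep],
                 n_unmatched = dropped + sum(!keep)),
            class = "labelled_features")
}

#' Default labelled training set
#'
#' Renders a balanced population (`n_per_class` nuclei per stage), segments
#' it with the default parameters, extracts features and transfers the
#' ground-truth stage of each nucleus onto its segmented object (matched at
#' the truth centroid; ambiguous or unsegmented nuclei are dropped and
#' counted). Training on segmented - rather than ground-truth - masks keeps
#' the training and deployment feature distributions identical.
#'
#' @param n_per_class Nuclei per stage (default 500).
#' @param seed Integer seed.
#' @return List: `features`, `labels`, `n_unmatched`.
#' @export
default_training_set <- function(n_per_class = 500L, seed = 0L) {
  pop <- make_balanced_population(n_per_class = n_per_class, seed = seed)
  labelled_features(pop)
}

#' Train the default nuclear-morphology classifier
#'
#' [default_training_set()] followed by [train_classifier()] with the
#' default 70/30 stratified split.
#'
#' @inheritParams default_training_set
#' @inheritParams train_classifier
#' @return List with `model` and `report` (see [train_classifier()]).
#' @export
default_classifier <- function(n_per_class = 500L, seed = 0L, split = 0.7,
                               feature_set = "extended") {
  ts <- default_training_set(n_per_class = n_per_class, seed = seed)
  train_classifier(ts$features, ts$labels, split = split, seed = seed,
                   feature_set = feature_set)
}
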