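#' The four NETosis nuclear-morphology stages
#'
#' During NET formation a neutrophil nucleus progresses from the resting
#' multi-lobed shape through chromatin decondensation to a fully released
#' extracellular chromatin cloud. The four stages, in order of progression,
#' are `LOBULATED`, `DELOBULATED`, `DIFFUSED` (diffused NETs) and `SPREAD`
#' (spread NETs).
#'
#' @return Character vector of the four stage names, in progression order.
#' @export
#' @examples
#' morphology_levels()
morphology_levels <- function() {
  c("LOBULATED", "DELOBULATED", "DIFFUSED", "SPREAD")
}

#' Coerce a vector to an ordered morphology factor
#'
#' @param x character or factor vector of stage names.
#' @return Ordered factor over the four stages (progression order).
#' @export
morphology_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), morphology_levels())
  if (length(bad) > 0) {
    stop("unknown morphology class(es): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = morphology_levels(), ordered = TRUE)
}
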