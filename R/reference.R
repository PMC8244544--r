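#' Published reference metrics of the four-model ablation
#'
#' The reported test-set metrics of the four segmentation variants (A: plain;
#' B: + data augmentation; C: + SE blocks; D: + both), shipped with the
#' package so that metric-definition consistency (MPA = mean of the two CPAs;
#' improvement deltas = differences of table entries) can be checked
#' mechanically.
#'
#' @return data.frame with columns `model`, `data_augment`, `se_blocks`,
#'   `pa`, `cpa_background`, `cpa_aperture`, `mpa`, `miou`.
#' @export
reference_metrics <- function() {
  read.csv(system.file("extdata", "reference_metrics.csv",
                       package = "stomatrack"),
           stringsAsFactors = FALSE)
}

#' @rdname reference_metrics
#' @return for `reference_improvements()`: the reported improvement deltas in
#'   percentage points, with the table rows they difference (`minuend` -
#'   `subtrahend`).
#' @export
reference_improvements <- function() {
  read.csv(system.file("extdata", "reference_improvements.csv",
                       package = "stomatrack"),
           stringsAsFactors = FALSE)
}
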