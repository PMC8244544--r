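#' Aperture kinetics specification
#'
#' Describes how the open-aperture area of one stoma evolves over time.
#' Three models are supported:
#' \describe{
#'   \item{`constant`}{area stays at its initial value.}
#'   \item{`linear`}{area changes at `slope` px^2/s, clamped at 0.}
#'   \item{`logistic_closure`}{stress-induced closing: area follows a
#'     decreasing logistic from the initial area towards `A_end`, with rate
#'     `k` (1/s) and midpoint `t0` (s). The most negative area change rate
#'     occurs at `t = t0`.}
#' }
#'
#' @param model one of `"constant"`, `"linear"`, `"logistic_closure"`.
#' @param slope px^2/s, linear model only.
#' @param A_end px^2, final area of the logistic closure.
#' @param k 1/s, logistic rate; larger values close the aperture faster.
#' @param t0 s, logistic midpoint (time of fastest closure).
#' @return an object of class `kinetics_spec`.
#' @examples
#' kin <- kinetics_spec("logistic_closure", A_end = 0, k = 0.05, t0 = 120)
#' aperture_area(kin, A0 = 600, t = c(0, 120, 600))
#' @export
kinetics_spec <- function(model = c("constant", "linear", "logistic_closure"),
                          slope = 0, A_end = 0, k = 0.05, t0 = 0) {
  model <- match.arg(model)
  if (model == "logistic_closure") {
    stopifnot(k > 0, A_end >= 0)
  }
  structure(list(model = model, slope = slope, A_end = A_end, k = k, t0 = t0),
            class = "kinetics_spec")
}

#' Evaluate aperture area under a kinetics model
#'
#' @param kin a [kinetics_spec()].
#' @param A0 initial area at `t = 0`, px^2.
#' @param t time(s) in seconds, vectorized.
#' @return areas in px^2, never negative.
#' @export
aperture_area <- function(kin, A0, t) {
  stopifnot(inherits(kin, "kinetics_spec"), A0 >= 0)
  a <- switch(kin$model,
    constant = rep(A0, length(t)),
    linear = A0 + kin$slope * t,
    logistic_closure = {
      # parameterized so A(t) -> A0 for t << t0 and -> A_end for t >> t0
      kin$A_end + (A0 - kin$A_end) / (1 + exp(kin$k * (t - kin$t0)))
    }
  )
  pmax(a, 0)
}
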