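#' Stomatal opening area (SOA) time series
#'
#' @param stoma_id identifier of the tracked stoma.
#' @param times sampling times in seconds, strictly increasing.
#' @param soa aperture pixel counts, non-negative.
#' @return an object of class `soa_series`.
#' @export
soa_series <- function(stoma_id, times, soa) {
  stopifnot(length(times) == length(soa), all(diff(times) > 0),
            all(soa >= 0))
  structure(list(stoma_id = stoma_id, times = as.numeric(times),
                 soa = as.numeric(soa)),
            class = "soa_series")
}

#' @export
print.soa_series <- function(x, ...) {
  cat(sprintf("<soa_series stoma %s: %d samples, t in [%g, %g] s, SOA %g..%g px>\n",
              x$stoma_id, length(x$times), min(x$times), max(x$times),
              min(x$soa), max(x$soa)))
  invisible(x)
}

#' SOA from a stack of predicted masks
#'
#' Counts class-1 (aperture) pixels in each mask at its native resolution.
#'
#' @param mask_stack list of `{0,1}` integer mask matrices, one per time
#'   point.
#' @param times sampling times in seconds.
#' @param stoma_id identifier carried into the series.
#' @return an [soa_series()].
#' @export
compute_soa <- function(mask_stack, times, stoma_id = 1L) {
  if (length(mask_stack) != length(times)) {
    stop("one mask per time point required")
  }
  counts <- vapply(mask_stack, function(m) {
    if (!all(m %in% c(0L, 1L))) stop("mask contains values outside {0, 1}")
    sum(m == 1L)
  }, numeric(1))
  soa_series(stoma_id, times, counts)
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(k) {
    lo <- max(1L, k - half)
    hi <- min(n, k + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Rate-of-change curve of an SOA series
#'
#' The first derivative of the (optionally smoothed) SOA curve: central
#' finite differences at interior points, one-sided at the ends. Raw pixel
#' counts are noisy, so a moving average (default 5 samples) is applied
#' before differencing.
#'
#' @param series an [soa_series()].
#' @param smooth_window moving-average window in samples (1 disables
#'   smoothing).
#' @return list of class `rate_series` with `stoma_id`, `times`, `rate`
#'   (px/s).
#' @export
rate_curve <- function(series, smooth_window = 5L) {
  stopifnot(inherits(series, "soa_series"))
  n <- length(series$times)
  if (n < 2) stop("need at least 2 points to differentiate")
  s <- moving_average(series$soa, smooth_window)
  t <- series$times
  rate <- numeric(n)
  rate[1] <- (s[2] - s[1]) / (t[2] - t[1])
  rate[n] <- (s[n] - s[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    k <- 2:(n - 1)
    rate[k] <- (s[k + 1] - s[k - 1]) / (t[k + 1] - t[k - 1])
  }
  structure(list(stoma_id = series$stoma_id, times = t, rate = rate),
            class = "rate_series")
}

#' Time of fastest closure
#'
#' The sample time at which the rate curve is most negative; for logistic
#' closure kinetics this estimates the midpoint `t0`.
#'
#' @param rs a `rate_series` from [rate_curve()].
#' @return time in seconds.
#' @export
min_rate_time <- function(rs) {
  stopifnot(inherits(rs, "rate_series"))
  rs$times[which.min(rs$rate)]
}

#' Cross-stoma summary of SOA series
#'
#' Per-time mean, median and quartiles across stomata (the numbers behind a
#' box plot over time). Series not sharing the reference grid are linearly
#' interpolated onto the grid of the first series.
#'
#' @param series_list list of [soa_series()].
#' @return data.frame with columns `time_s`, `mean`, `median`, `q25`, `q75`,
#'   `n`.
#' @export
summarize_series <- function(series_list) {
  if (length(series_list) == 0) stop("empty series list")
  stopifnot(all(vapply(series_list, inherits, logical(1), "soa_series")))
  grid <- series_list[[1]]$times
  vals <- vapply(series_list, function(s) {
    if (length(s$times) == length(grid) && all(s$times == grid)) {
      s$soa
    } else {
      approx(s$times, s$soa, xout = grid, rule = 2)$y
    }
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  data.frame(time_s = grid,
             mean = rowMeans(vals),
             median = apply(vals, 1, median),
             q25 = apply(vals, 1, quantile, probs = 0.25, names = FALSE),
             q75 = apply(vals, 1, quantile, probs = 0.75, names = FALSE),
             n = ncol(vals))
}

#' Mean SOA across stomata as a series
#'
#' @param series_list list of [soa_series()].
#' @return an [soa_series()] of the per-time mean (id `"mean"`).
#' @export
mean_soa_series <- function(series_list) {
  sm <- summarize_series(series_list)
  soa_series("mean", sm$time_s, sm$mean)
}

#' Correlate mean SOA with gas-exchange parameters
#'
#' Interpolates the mean SOA series linearly onto the gas-exchange time grid
#' (the instrument's 30-s log is the coarser, authoritative clock) and
#' reports the Pearson correlation coefficient of SOA with each of Pn, Ci,
#' Gs and Tr over the overlapping time range.
#'
#' @param mean_soa an [soa_series()] (typically from [mean_soa_series()]).
#' @param gas data.frame as returned by [read_gas_exchange()].
#' @return data.frame with columns `parameter`, `r`, `n`. Zero-variance
#'   inputs yield `NA` with a warning.
#' @export
correlate_soa_gas <- function(mean_soa, gas) {
  stopifnot(inherits(mean_soa, "soa_series"))
  need <- c("time_s", "Pn", "Ci", "Gs", "Tr")
  stopifnot(all(need %in% names(gas)))
  keep <- gas$time_s >= min(mean_soa$times) & gas$time_s <= max(mean_soa$times)
  if (sum(keep) < 3) stop("fewer than 3 overlapping time points")
  g <- gas[keep, ]
  soa_on_grid <- approx(mean_soa$times, mean_soa$soa, xout = g$time_s)$y
  params <- c("Pn", "Ci", "Gs", "Tr")
  r <- vapply(params, function(pn) {
    y <- g[[pn]]
    if (stats::sd(soa_on_grid) == 0 || stats::sd(y) == 0) {
      warning("zero-variance input for ", pn, "; correlation undefined")
      return(NA_real_)
    }
    cor(soa_on_grid, y)
  }, numeric(1))
  data.frame(parameter = params, r = unname(r), n = nrow(g))
}

#' Plot SOA series over time
#'
#' Simple base-graphics line plot of one or more SOA series.
#'
#' @param series_list list of [soa_series()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot_soa_series <- function(series_list, ...) {
  stopifnot(length(series_list) > 0)
  grid <- series_list[[1]]$times
  vals <- vapply(series_list, function(s) {
    approx(s$times, s$soa, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  graphics::matplot(grid, matrix(vals, nrow = length(grid)), type = "l",
                    lty = 1, xlab = "time (s)", ylab = "SOA (px)", ...)
  graphics::legend("topright",
                   legend = vapply(series_list,
                                   function(s) as.character(s$stoma_id),
                                   character(1)),
                   col = seq_along(series_list), lty = 1, cex = 0.8)
  invisible(NULL)
}
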