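#' Growth rate from a log-area time series by best-window OLS
#'
#' Fits an ordinary least-squares line to every contiguous window of
#' `window` timepoints of ln(colony area) vs time and returns the slope of
#' the best-fitting window. "Best" is the window with maximal R-squared, with
#' ties broken by the latest window start (growth accelerates out of lag, so
#' later windows are the exponential phase). Windows with zero ln-area
#' variance get R-squared 0, so a constant series returns slope 0.
#'
#' @param timepoints numeric vector of times (hours), strictly increasing.
#' @param log_area numeric vector of ln(area), same length.
#' @param window window length in timepoints (default 7).
#' @return the per-hour slope of the selected window, with attributes
#'   `window_start` (index) and `r_squared`.
#' @export
fit_window_growth_rate <- function(timepoints, log_area, window = 7L) {
  n <- length(timepoints)
  stopifnot(length(log_area) == n, window >= 2)
  if (n < window)
    stop("time series shorter than the fitting window", call. = FALSE)
  if (any(diff(timepoints) <= 0))
    stop("'timepoints' must be strictly increasing", call. = FALSE)
  best <- list(r2 = -Inf, slope = NA_real_, start = NA_integer_)
  for (start in seq_len(n - window + 1L)) {
    idx <- start:(start + window - 1L)
    x <- timepoints[idx]; y <- log_area[idx]
    sxx <- sum((x - mean(x))^2)
    syy <- sum((y - mean(y))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    r2 <- if (syy <= .Machine$double.eps) 0 else (sxy^2 / (sxx * syy))
    if (r2 >= best$r2 - 1e-12) {           # >= with tolerance: latest start
      best <- list(r2 = r2, slope = slope, start = start)
    }
  }
  structure(best$slope, window_start = best$start, r_squared = best$r2)
}
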