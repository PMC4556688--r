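## DSC transition-temperature extraction: linear baseline subtraction from
## the curve tails, moving-average smoothing, global-extremum search with
## parabolic sub-grid refinement.

#' Subtract a linear baseline fitted to the curve tails
#'
#' Fits heat_flow ~ temperature by least squares on the first and last
#' `fit_fraction` of points (where no transition is expected) and subtracts
#' the fitted line. The fit is stored as attribute `baseline_params`
#' (intercept, slope).
#'
#' @param curve a [thermogram]
#' @param fit_fraction fraction of points in each tail, in (0, 0.4]
#' @return baseline-corrected [thermogram]
#' @export
subtract_linear_baseline <- function(curve, fit_fraction = 0.1) {
  stopifnot(inherits(curve, "thermogram"))
  if (fit_fraction <= 0 || fit_fraction > 0.4)
    stop("fit_fraction must be in (0, 0.4]", call. = FALSE)
  n <- length(curve$temperature_C)
  k <- floor(fit_fraction * n)
  if (k < 3L)
    stop("degenerate baseline fit: fewer than 3 points per tail",
         call. = FALSE)
  sel <- c(seq_len(k), seq(n - k + 1L, n))
  fit <- stats::lm(hf ~ tt, data = data.frame(tt = curve$temperature_C[sel],
                                              hf = curve$heat_flow[sel]))
  corrected <- curve$heat_flow -
    stats::predict(fit, data.frame(tt = curve$temperature_C))
  out <- thermogram(curve$temperature_C, corrected, curve$sample_id)
  attr(out, "baseline_params") <- stats::setNames(stats::coef(fit),
                                                  c("intercept", "slope"))
  out
}

## parabola vertex through three (t, y) points; falls back to the middle
## abscissa when the points are collinear
parabola_vertex <- function(t1, t2, t3, y1, y2, y3) {
  num <- (t2 - t1)^2 * (y2 - y3) - (t2 - t3)^2 * (y2 - y1)
  den <- (t2 - t1) * (y2 - y3) - (t2 - t3) * (y2 - y1)
  if (abs(den) < 1e-12 * max(abs(num), 1)) return(t2)
  t2 - 0.5 * num / den
}

#' Locate the denaturation transition temperature
#'
#' Smooths the (ideally baseline-corrected) curve with a moving average,
#' finds the global extremum of the absolute signal (so endotherm-up and
#' endotherm-down conventions both work), and refines the peak position by
#' parabolic interpolation through the extremum and its two neighbours.
#' Equal extrema resolve to the lowest temperature. A peak is only accepted
#' when its magnitude exceeds three times the noise level estimated from the
#' curve tails.
#'
#' @param curve a [thermogram], typically after [subtract_linear_baseline()]
#' @param smoothing_window odd moving-average width, points
#' @return object of class `transition_result`: `transition_temp_C`,
#'   `peak_height` (absolute corrected signal at the peak sample),
#'   `baseline_params` (from the input curve, or c(0, 0))
#' @export
find_transition_temperature <- function(curve, smoothing_window = 5L) {
  stopifnot(inherits(curve, "thermogram"))
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L)
    stop("smoothing_window must be a positive odd integer", call. = FALSE)
  tt <- curve$temperature_C
  y <- curve$heat_flow
  n <- length(y)
  if (smoothing_window > 1L) {
    sm <- stats::filter(y, rep(1 / smoothing_window, smoothing_window),
                        sides = 2)
    y <- ifelse(is.na(sm), y, as.numeric(sm))
  }
  a <- abs(y)
  i <- which.max(a)                  # first maximum = lowest temperature
  k <- max(3L, floor(0.1 * n))
  tail_sd <- stats::sd(c(y[seq_len(k)], y[seq(n - k + 1L, n)]))
  if (a[i] == 0 || (is.finite(tail_sd) && tail_sd > 0 && a[i] < 3 * tail_sd))
    stop("no significant peak: extremum below 3x tail noise", call. = FALSE)
  temp <- tt[i]
  if (i > 1L && i < n) {
    temp <- parabola_vertex(tt[i - 1L], tt[i], tt[i + 1L],
                            a[i - 1L], a[i], a[i + 1L])
    temp <- min(max(temp, tt[i - 1L]), tt[i + 1L])
  }
  structure(list(transition_temp_C = temp, peak_height = a[i],
                 baseline_params = attr(curve, "baseline_params") %||%
                   c(intercept = 0, slope = 0)),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf("<transition: %.2f degC (peak height %.3g)>\n",
              x$transition_temp_C, x$peak_height))
  invisible(x)
}

#' Baseline-correct a thermogram and extract its transition temperature
#'
#' Convenience wrapper: [subtract_linear_baseline()] then
#' [find_transition_temperature()].
#'
#' @inheritParams subtract_linear_baseline
#' @inheritParams find_transition_temperature
#' @return a `transition_result`
#' @export
transition_temperature <- function(curve, fit_fraction = 0.1,
                                   smoothing_window = 5L) {
  find_transition_temperature(subtract_linear_baseline(curve, fit_fraction),
                              smoothing_window)
}
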