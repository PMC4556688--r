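#' DSC thermogram container
#'
#' @param temperature_C strictly increasing temperatures within 10-95 degC,
#'   at least 20 points (the calorimeter scan range)
#' @param heat_flow heat-flow values, same length
#' @param sample_id character tag
#' @return an object of class `thermogram`
#' @export
thermogram <- function(temperature_C, heat_flow, sample_id = "sample") {
  if (length(temperature_C) < 20L)
    stop("thermogram needs at least 20 points", call. = FALSE)
  if (length(heat_flow) != length(temperature_C))
    stop("temperature and heat flow lengths differ", call. = FALSE)
  if (any(diff(temperature_C) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)
  if (min(temperature_C) < 10 - 1e-9 || max(temperature_C) > 95 + 1e-9)
    stop("temperatures must lie within the 10-95 degC scan range",
         call. = FALSE)
  structure(list(temperature_C = as.numeric(temperature_C),
                 heat_flow = as.numeric(heat_flow),
                 sample_id = as.character(sample_id)),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram '%s': %d points, %.1f-%.1f degC>\n", x$sample_id,
              length(x$temperature_C), min(x$temperature_C),
              max(x$temperature_C)))
  invisible(x)
}

#' Generate a synthetic single-endotherm DSC thermogram
#'
#' heat_flow(T) = baseline_slope * (T - T_low) +
#'   peak_amplitude * exp(-((T - peak)^2) / (2 width^2)) + noise.
#' With zero noise the curve has exactly one peak-attributable extremum.
#'
#' @param peak_temp_C transition peak temperature, within the scan range
#' @param peak_width_C Gaussian SD of the endotherm, degC
#' @param peak_amplitude peak height above baseline
#' @param baseline_slope linear baseline slope (heat flow per degC)
#' @param noise_sd SD of additive Gaussian noise
#' @param temp_range_C scan range (low, high), within 10-95 degC
#' @param step_C temperature grid spacing, degC
#' @param seed integer seed
#' @param sample_id character tag
#' @return a [thermogram]
#' @export
generate_thermogram <- function(peak_temp_C, peak_width_C = 4,
                                peak_amplitude = 1, baseline_slope = 0.01,
                                noise_sd = 0, temp_range_C = c(10, 95),
                                step_C = 0.1, seed = 1L,
                                sample_id = "synthetic") {
  if (temp_range_C[1] < 10 || temp_range_C[2] > 95 ||
      temp_range_C[1] >= temp_range_C[2])
    stop("temp_range_C must be an increasing range within [10, 95]",
         call. = FALSE)
  if (peak_temp_C < temp_range_C[1] || peak_temp_C > temp_range_C[2])
    stop("peak_temp_C outside the scan range", call. = FALSE)
  stopifnot_scalar_positive(peak_width_C, "peak_width_C")
  stopifnot_scalar_positive(step_C, "step_C")
  if (peak_amplitude < 0 || noise_sd < 0)
    stop("peak_amplitude and noise_sd must be nonnegative", call. = FALSE)
  tt <- seq(temp_range_C[1], temp_range_C[2], by = step_C)
  hf <- baseline_slope * (tt - temp_range_C[1]) +
    peak_amplitude * exp(-((tt - peak_temp_C)^2) / (2 * peak_width_C^2))
  if (noise_sd > 0)
    hf <- hf + with_seed(seed, stats::rnorm(length(tt), 0, noise_sd))
  thermogram(tt, hf, sample_id)
}

#' Read / write thermograms as two-column CSV
#'
#' Columns `temperature_C, heat_flow`.
#'
#' @param path CSV path
#' @param sample_id character tag (read)
#' @return a [thermogram] (read); `path` invisibly (write)
#' @export
read_thermogram <- function(path, sample_id = basename(path)) {
  d <- utils::read.csv(path)
  thermogram(d$temperature_C, d$heat_flow, sample_id)
}

#' @rdname read_thermogram
#' @param tg a [thermogram]
#' @export
write_thermogram <- function(tg, path) {
  utils::write.csv(data.frame(temperature_C = tg$temperature_C,
                              heat_flow = tg$heat_flow),
                   path, row.names = FALSE)
  invisible(path)
}
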