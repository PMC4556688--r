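## Structural readouts: equivalent diameters, nearest-neighbour
## interfibrillar distances, randomized-window spot density.

#' Fibril diameters of non-border components
#'
#' Border-touching components have censored areas and are excluded, so the
#' diameter distribution is unbiased.
#'
#' @param components a `fibril_components` data frame
#' @return numeric vector of equivalent-circle diameters, nm
#' @export
diameters <- function(components) {
  components$diameter_nm[!components$on_border]
}

#' Nearest-neighbour distances between fibril centres
#'
#' For each centroid, the Euclidean distance to its closest other centroid,
#' converted to nanometres; output order matches input order. The search
#' uses a grid of buckets (cell list), so it stays near-linear in the number
#' of points. With `radii_px` supplied, distances are surface-to-surface:
#' both radii of the nearest pair are subtracted from the centre distance.
#'
#' @param centroids n x 2 matrix of (row, col) pixel coordinates, n >= 2
#' @param nm_per_px calibration, nanometres per pixel
#' @param radii_px optional per-point radii for edge-to-edge distances
#' @return numeric vector of length n, nm
#' @export
nearest_neighbor_distances <- function(centroids, nm_per_px = 1,
                                       radii_px = NULL) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2L) stop("need at least two centroids", call. = FALSE)
  stopifnot_scalar_positive(nm_per_px, "nm_per_px")

  rng_r <- range(centroids[, 1]); rng_c <- range(centroids[, 2])
  ext <- max(rng_r[2] - rng_r[1], rng_c[2] - rng_c[1], 1e-9)
  cell <- max(ext / max(1, floor(sqrt(n))), 1e-9)
  ci <- floor((centroids[, 1] - rng_r[1]) / cell)
  cj <- floor((centroids[, 2] - rng_c[1]) / cell)
  ncell <- max(ci, cj) + 1L
  key <- ci * ncell + cj
  buckets <- split(seq_len(n), key)
  bkey <- as.numeric(names(buckets))

  nn_idx <- integer(n)
  nn_d <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf; best_j <- NA_integer_
    k <- 0L
    repeat {
      ## candidate points in cells at Chebyshev ring k around this cell
      ii <- (ci[i] - k):(ci[i] + k)
      jj <- (cj[i] - k):(cj[i] + k)
      ring <- unique(c(outer(ii, c(cj[i] - k, cj[i] + k),
                             function(a, b) a * ncell + b),
                       outer(c(ci[i] - k, ci[i] + k), jj,
                             function(a, b) a * ncell + b)))
      cand <- unlist(buckets[match(ring, bkey)], use.names = FALSE)
      cand <- cand[!is.na(cand) & cand != i]
      if (length(cand)) {
        d <- sqrt((centroids[cand, 1] - centroids[i, 1])^2 +
                  (centroids[cand, 2] - centroids[i, 2])^2)
        j <- which.min(d)
        if (d[j] < best) { best <- d[j]; best_j <- cand[j] }
      }
      ## any unexplored point lies at distance >= k * cell
      if (best <= k * cell) break
      k <- k + 1L
      if (k > 2L * ncell) break   # all cells exhausted
    }
    nn_idx[i] <- best_j
    nn_d[i] <- best
  }
  if (!is.null(radii_px)) nn_d <- nn_d - radii_px - radii_px[nn_idx]
  nn_d * nm_per_px
}

#' Randomized-window spot density
#'
#' Draws `n_windows` axis-aligned square windows uniformly at random, fully
#' inside the image, counts centroids in each (half-open containment
#' \[r, r+w) x \[c, c+w), so a point on a shared edge is counted once) and
#' returns the median count. Repeating the random placement many times and
#' taking the median makes the estimate robust to local clustering; the
#' defaults are a 300 x 300 px window placed 200 times.
#'
#' @param centroids n x 2 matrix of (row, col) pixel coordinates (may be
#'   empty)
#' @param image_shape_px integer pair (rows, cols)
#' @param window_size_px square window side, px; must fit inside the image
#' @param n_windows number of random placements, >= 1
#' @param seed integer seed for the window positions
#' @return list with `density_median` (median spots per window) and
#'   `window_counts` (integer vector of all counts)
#' @export
window_density <- function(centroids, image_shape_px,
                           window_size_px = 300L, n_windows = 200L,
                           seed = 1L) {
  h <- image_shape_px[1]; w <- image_shape_px[2]
  if (window_size_px > min(h, w))
    stop("window larger than the image", call. = FALSE)
  if (n_windows < 1L) stop("n_windows must be >= 1", call. = FALSE)
  centroids <- matrix(as.numeric(centroids), ncol = 2)
  counts <- with_seed(seed, {
    r0 <- stats::runif(n_windows, 0.5, h + 0.5 - window_size_px)
    c0 <- stats::runif(n_windows, 0.5, w + 0.5 - window_size_px)
    vapply(seq_len(n_windows), function(k) {
      sum(centroids[, 1] >= r0[k] & centroids[, 1] < r0[k] + window_size_px &
          centroids[, 2] >= c0[k] & centroids[, 2] < c0[k] + window_size_px)
    }, integer(1))
  })
  list(density_median = stats::median(counts), window_counts = counts)
}

#' Morphometry summary for one segmented micrograph
#'
#' Aggregates the three structural readouts of a segmented image: fibril
#' diameters (non-border components), nearest-neighbour distances (all
#' components, center-to-center) and randomized-window density, reported
#' both as spots per window and per square micrometre.
#'
#' @param components filtered `fibril_components` from [segment_micrograph()]
#' @param image the source [micrograph]
#' @param window_size_px,n_windows,seed see [window_density()]
#' @return object of class `morphometry_result`: `image_id`, `n_fibrils`,
#'   `diameters_nm`, `nn_distances_nm`, `density_median`, `density_per_um2`,
#'   `window_size_px`, `n_windows`, `seed`
#' @export
summarize_image <- function(components, image, window_size_px = 300L,
                            n_windows = 200L, seed = 1L) {
  stopifnot(inherits(image, "micrograph"))
  n <- nrow(components)
  cen <- cbind(components$row, components$col)
  nn <- if (n >= 2L)
    nearest_neighbor_distances(cen, image$nm_per_px) else numeric(0)
  wd <- window_density(cen, dim(image), window_size_px, n_windows, seed)
  window_area_um2 <- (window_size_px * image$nm_per_px)^2 / 1e6
  structure(list(
    image_id = image$source_id, n_fibrils = n,
    diameters_nm = diameters(components), nn_distances_nm = nn,
    density_median = wd$density_median,
    density_per_um2 = wd$density_median / window_area_um2,
    window_size_px = as.integer(window_size_px),
    n_windows = as.integer(n_windows), seed = as.integer(seed)),
    class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry '%s': %d fibrils>\n", x$image_id, x$n_fibrils))
  if (length(x$diameters_nm))
    cat(sprintf("  diameter     %.2f +/- %.2f nm (n = %d, border-censored excluded)\n",
                mean(x$diameters_nm), stats::sd(x$diameters_nm),
                length(x$diameters_nm)))
  if (length(x$nn_distances_nm))
    cat(sprintf("  NN distance  %.2f +/- %.2f nm\n",
                mean(x$nn_distances_nm), stats::sd(x$nn_distances_nm)))
  cat(sprintf("  density      %.1f spots / %d px window (%.1f per um^2; %d windows)\n",
              x$density_median, x$window_size_px, x$density_per_um2,
              x$n_windows))
  invisible(x)
}

#' One-row data frame view of a morphometry result
#'
#' @param x a [summarize_image()] result
#' @param ... unused
#' @return data frame with summary columns (means and SDs of the readouts)
#' @export
as.data.frame.morphometry_result <- function(x, ...) {
  data.frame(
    image_id = x$image_id, n_fibrils = x$n_fibrils,
    diameter_mean_nm = if (length(x$diameters_nm)) mean(x$diameters_nm) else NA_real_,
    diameter_sd_nm = if (length(x$diameters_nm) > 1) stats::sd(x$diameters_nm) else NA_real_,
    nn_distance_mean_nm = if (length(x$nn_distances_nm)) mean(x$nn_distances_nm) else NA_real_,
    nn_distance_sd_nm = if (length(x$nn_distances_nm) > 1) stats::sd(x$nn_distances_nm) else NA_real_,
    density_median = x$density_median,
    density_per_um2 = x$density_per_um2,
    window_size_px = x$window_size_px, n_windows = x$n_windows,
    seed = x$seed)
}
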