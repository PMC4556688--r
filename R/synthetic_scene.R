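## Ground-truth scene generation for transverse-section TEM emulation.
## Fibril cross-sections are hard disks placed by random sequential
## adsorption (RSA); elongated artifacts are thick line segments whose
## near-unit eccentricity exercises the component-filtering rule.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## normal truncated at > lower, by rejection (diameters must be positive)
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lower])
  }
  out[seq_len(n)]
}

#' Generate a synthetic fibril scene
#'
#' Places `round(density * area)` non-overlapping disks (fibril
#' cross-sections) by random sequential adsorption, honouring a hard-disk
#' condition: every pair of centers is at least `r_i + r_j + min_gap` apart.
#' Diameters are drawn from a normal distribution truncated at zero.
#' Optional artifacts are elongated segments (length at least five mean
#' diameters) that a fibril detector should reject on eccentricity.
#'
#' @param density_per_um2 target areal density, fibrils per square micrometre
#' @param diam_mean_nm mean fibril diameter, nm
#' @param diam_sd_nm SD of fibril diameter, nm
#' @param min_gap_nm minimum surface-to-surface gap between fibrils, nm
#' @param n_artifacts number of elongated artifact segments
#' @param image_shape_px integer pair (rows, cols)
#' @param nm_per_px calibration, nanometres per pixel
#' @param seed integer seed; identical seeds give identical scenes
#' @return an object of class `synthetic_scene` with fields `height_px`,
#'   `width_px`, `nm_per_px`, `centers` (n x 2 matrix, row/col pixel
#'   coordinates), `radii_px`, `artifacts` (data frame of segment endpoints
#'   and thickness), `seed`
#' @export
generate_scene <- function(density_per_um2, diam_mean_nm = 40.67,
                           diam_sd_nm = 2, min_gap_nm = 4,
                           n_artifacts = 0L,
                           image_shape_px = c(1024L, 1024L),
                           nm_per_px = 1, seed = 1L) {
  stopifnot_scalar_positive(nm_per_px, "nm_per_px")
  if (density_per_um2 < 0) stop("density must be nonnegative", call. = FALSE)
  stopifnot_scalar_positive(diam_mean_nm, "diam_mean_nm")
  if (diam_sd_nm < 0 || min_gap_nm < 0)
    stop("diam_sd_nm and min_gap_nm must be nonnegative", call. = FALSE)
  h <- as.integer(image_shape_px[1]); w <- as.integer(image_shape_px[2])
  area_um2 <- h * w * nm_per_px^2 / 1e6
  n <- as.integer(round(density_per_um2 * area_um2))

  ## feasibility: effective disk packing fraction must stay below 0.5
  r_eff_px <- (diam_mean_nm / 2 + min_gap_nm / 2) / nm_per_px
  if (n > 0 && n * pi * r_eff_px^2 / (h * w) >= 0.5)
    stop("requested density is infeasible: disk packing fraction >= 0.5",
         call. = FALSE)

  with_seed(seed, {
    radii_px <- rnorm_trunc(n, diam_mean_nm / 2, diam_sd_nm / 2) / nm_per_px
    gap_px <- min_gap_nm / nm_per_px
    centers <- matrix(numeric(0), ncol = 2)
    if (n > 0) {
      centers <- matrix(NA_real_, n, 2)
      placed <- 0L
      rejections <- 0L
      while (placed < n) {
        cand <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
        ok <- TRUE
        if (placed > 0L) {
          d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
                (centers[seq_len(placed), 2] - cand[2])^2
          lim <- (radii_px[seq_len(placed)] + radii_px[placed + 1L] + gap_px)^2
          ok <- all(d2 >= lim)
        }
        if (ok) {
          placed <- placed + 1L
          centers[placed, ] <- cand
          rejections <- 0L
        } else {
          rejections <- rejections + 1L
          if (rejections >= 10000L)
            stop("infeasible density: 10^4 consecutive placement rejections",
                 call. = FALSE)
        }
      }
    }
    artifacts <- data.frame(a_row = numeric(0), a_col = numeric(0),
                            b_row = numeric(0), b_col = numeric(0),
                            thickness_px = numeric(0))
    if (n_artifacts > 0L) {
      ## artifacts are placed clear of every fibril disk (same hard-gap rule)
      ## so each rendered component is purely fibril or purely artifact and
      ## ground-truth counts stay recoverable after eccentricity filtering
      thick <- max(3, 0.15 * diam_mean_nm / nm_per_px)
      placed <- 0L
      rejections <- 0L
      while (placed < n_artifacts) {
        len <- stats::runif(1, 5, 7) * diam_mean_nm / nm_per_px
        ang <- stats::runif(1, 0, pi)
        cr <- stats::runif(1, 1, h); cc <- stats::runif(1, 1, w)
        a <- c(cr - len / 2 * sin(ang), cc - len / 2 * cos(ang))
        b <- c(cr + len / 2 * sin(ang), cc + len / 2 * cos(ang))
        ok <- TRUE
        if (n > 0) {
          d <- .dist_to_segment(centers[, 1], centers[, 2],
                                a[1], a[2], b[1], b[2])
          ok <- all(d >= radii_px + thick / 2 + gap_px)
        }
        if (ok) {
          placed <- placed + 1L
          artifacts[placed, ] <- c(a[1], a[2], b[1], b[2], thick)
          rejections <- 0L
        } else {
          rejections <- rejections + 1L
          ## long segments have a far smaller acceptance region than disks,
          ## so the artifact stage gets a larger rejection budget
          if (rejections >= 100000L)
            stop("infeasible density: 10^5 consecutive artifact rejections",
                 call. = FALSE)
        }
      }
    }
    structure(list(height_px = h, width_px = w, nm_per_px = nm_per_px,
                   centers = centers, radii_px = radii_px,
                   artifacts = artifacts, seed = as.integer(seed)),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene: %d x %d px @ %.3g nm/px, %d fibrils, %d artifacts>\n",
    x$height_px, x$width_px, x$nm_per_px, nrow(x$centers),
    nrow(x$artifacts)))
  invisible(x)
}

#' True areal density of a scene
#'
#' @param scene a [generate_scene()] result
#' @param window_size_px if given, density is returned as the expected count
#'   in a square window of this side; otherwise per square micrometre
#' @return a scalar density
#' @export
scene_true_density <- function(scene, window_size_px = NULL) {
  n <- nrow(scene$centers)
  if (is.null(window_size_px))
    n / (scene$height_px * scene$width_px * scene$nm_per_px^2 / 1e6)
  else n * window_size_px^2 / (scene$height_px * scene$width_px)
}

## distance from pixels (r, c) to segment a-b, vectorized over pixels
.dist_to_segment <- function(r, c, ar, ac, br, bc) {
  vr <- br - ar; vc <- bc - ac
  l2 <- vr^2 + vc^2
  t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((r - ar) * vr + (c - ac) * vc) / l2))
  sqrt((r - (ar + t * vr))^2 + (c - (ac + t * vc))^2)
}

#' Render a scene as a calibrated micrograph
#'
#' Fibrils are drawn as bright disks (intensity 0.85) on a darker background
#' (0.25), matching the segmenter's default `bright_objects` polarity.
#' Optional Gaussian blur, additive Gaussian noise and a zero-mean linear
#' illumination gradient across columns are applied, then intensities are
#' clipped to \[0, 1\]. The generating scene is attached as attribute
#' `"scene"` so ground truth stays linked to the image.
#'
#' @param scene a [generate_scene()] result
#' @param noise_sd SD of additive Gaussian noise
#' @param blur_sigma_px Gaussian blur SD in pixels (0 = none)
#' @param gradient_amplitude peak-to-peak amplitude of the linear gradient
#' @param seed noise seed; defaults to a sub-seed split from the scene seed
#'   so rendering is deterministic per scene
#' @return a [micrograph]
#' @export
render_micrograph <- function(scene, noise_sd = 0.05, blur_sigma_px = 1,
                              gradient_amplitude = 0,
                              seed = split_seed(scene$seed, 1L)) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (noise_sd < 0 || blur_sigma_px < 0)
    stop("noise_sd and blur_sigma_px must be nonnegative", call. = FALSE)
  h <- scene$height_px; w <- scene$width_px
  img <- matrix(0.25, h, w)

  paint <- function(img, rows, cols, inside) {
    if (!length(rows)) return(img)
    sub <- img[rows, cols, drop = FALSE]
    sub[inside] <- 0.85
    img[rows, cols] <- sub
    img
  }
  n <- nrow(scene$centers)
  for (i in seq_len(n)) {
    r0 <- scene$centers[i, 1]; c0 <- scene$centers[i, 2]
    rad <- scene$radii_px[i]
    rows <- max(1L, floor(r0 - rad)):min(h, ceiling(r0 + rad))
    cols <- max(1L, floor(c0 - rad)):min(w, ceiling(c0 + rad))
    inside <- outer((rows - r0)^2, (cols - c0)^2, `+`) <= rad^2
    img <- paint(img, rows, cols, inside)
  }
  for (i in seq_len(nrow(scene$artifacts))) {
    a <- scene$artifacts[i, ]
    half <- a$thickness_px / 2
    rows <- max(1L, floor(min(a$a_row, a$b_row) - half)):
            min(h, ceiling(max(a$a_row, a$b_row) + half))
    cols <- max(1L, floor(min(a$a_col, a$b_col) - half)):
            min(w, ceiling(max(a$a_col, a$b_col) + half))
    rr <- matrix(rows, length(rows), length(cols))
    cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    inside <- .dist_to_segment(rr, cc, a$a_row, a$a_col, a$b_row, a$b_col) <= half
    img <- paint(img, rows, cols, inside)
  }
  if (gradient_amplitude != 0) {
    grad <- gradient_amplitude * ((seq_len(w) - 1) / (w - 1) - 0.5)
    img <- img + matrix(grad, h, w, byrow = TRUE)
  }
  if (blur_sigma_px > 0) img <- EBImage::gblur(img, sigma = blur_sigma_px)
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(h * w, 0, noise_sd), h, w))
  img[img < 0] <- 0
  img[img > 1] <- 1
  out <- micrograph(img, scene$nm_per_px,
                    source_id = sprintf("synthetic-seed%d", scene$seed))
  attr(out, "scene") <- scene
  out
}

#' Write scene annotations as CSV
#'
#' One row per object: `center_row_px, center_col_px, radius_px, is_artifact`.
#' Artifact rows carry the segment midpoint and half-length as radius.
#'
#' @param scene a [generate_scene()] result
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_scene_annotations <- function(scene, path) {
  fib <- data.frame(center_row_px = scene$centers[, 1],
                    center_col_px = scene$centers[, 2],
                    radius_px = scene$radii_px, is_artifact = FALSE)
  art <- scene$artifacts
  if (nrow(art)) {
    fib <- rbind(fib, data.frame(
      center_row_px = (art$a_row + art$b_row) / 2,
      center_col_px = (art$a_col + art$b_col) / 2,
      radius_px = sqrt((art$b_row - art$a_row)^2 +
                       (art$b_col - art$a_col)^2) / 2,
      is_artifact = TRUE))
  }
  utils::write.csv(fib, path, row.names = FALSE)
  invisible(path)
}
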