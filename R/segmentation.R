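## Segmentation chain: adaptive local-mean binarization -> morphological
## opening -> 8-connected component labeling with moment features ->
## eccentricity / area filtering.

as_pixels <- function(image) {
  if (inherits(image, "micrograph")) image$pixels
  else if (is.matrix(image) && is.numeric(image)) image
  else stop("expected a micrograph or numeric matrix", call. = FALSE)
}

## local mean over a block_size x block_size window with symmetric
## (edge-inclusive reflective) border padding, via a summed-area table
local_mean <- function(pixels, block_size) {
  h <- nrow(pixels); w <- ncol(pixels)
  p <- (block_size - 1L) %/% 2L
  ri <- c(p:1, 1:h, h:(h - p + 1L))[seq_len(h + 2L * p)]
  ci <- c(p:1, 1:w, w:(w - p + 1L))[seq_len(w + 2L * p)]
  pad <- pixels[ri, ci, drop = FALSE]
  ## summed-area table with a zero first row/col
  s <- rbind(0, cbind(0, pad))
  s <- apply(s, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  i1 <- seq_len(h); j1 <- seq_len(w)         # top-left corner (in padded)
  i2 <- i1 + block_size; j2 <- j1 + block_size
  (s[i2, j2] - s[i1, j2] - s[i2, j1] + s[i1, j1]) / block_size^2
}

#' Adaptive local-mean binarization
#'
#' A pixel is foreground iff its intensity exceeds the mean of the
#' `block_size_px` x `block_size_px` block centred on it by more than
#' `offset` (comparison reversed for `dark_objects`). The local mean uses
#' reflective border padding, so the mask is defined at every pixel.
#'
#' @param image a [micrograph] or numeric intensity matrix
#' @param block_size_px odd block side, >= 3 and <= the smaller image side
#' @param offset threshold offset on the \[0, 1\] intensity scale
#' @param polarity `"bright_objects"` (default, matches the synthetic
#'   renderer) or `"dark_objects"`
#' @return logical matrix, `TRUE` = foreground, same shape as the image
#' @export
adaptive_binarize <- function(image, block_size_px = 51L, offset = 0.01,
                              polarity = c("bright_objects",
                                           "dark_objects")) {
  polarity <- match.arg(polarity)
  pixels <- as_pixels(image)
  if (block_size_px %% 2L == 0L)
    stop("block_size_px must be odd", call. = FALSE)
  if (block_size_px < 3L)
    stop("block_size_px must be >= 3", call. = FALSE)
  if (block_size_px > min(dim(pixels)))
    stop("block_size_px larger than the image", call. = FALSE)
  lm <- local_mean(pixels, as.integer(block_size_px))
  diff <- if (polarity == "bright_objects") pixels - lm else lm - pixels
  ## snap summed-area rounding residue so exact ties (flat regions with
  ## offset 0) resolve to background deterministically
  diff[abs(diff) < 1e-12] <- 0
  diff > offset
}

## Euclidean disk structuring element of the given radius
disk_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  (outer((-r:r)^2, (-r:r)^2, `+`) <= r^2) * 1
}

#' Morphological opening with a disk structuring element
#'
#' Erosion followed by dilation; removes foreground features smaller than
#' the disk without enlarging what remains. Radius 0 is the identity.
#'
#' @param mask logical matrix
#' @param radius_px nonnegative integer disk radius
#' @return logical matrix, always a subset of the input foreground
#' @export
morphological_open <- function(mask, radius_px = 2L) {
  stopifnot(is.matrix(mask))
  if (radius_px < 0) stop("radius_px must be nonnegative", call. = FALSE)
  if (radius_px == 0L) return(mask)
  k <- disk_kernel(radius_px)
  m <- EBImage::dilate(EBImage::erode(mask * 1, k), k)
  m > 0.5
}

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

## merge 4-connected labels that touch diagonally -> 8-connectivity
merge_diagonal <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  mx <- max(lab)
  if (mx == 0L || h < 2L || w < 2L) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))   # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (!nrow(pairs)) return(lab)
  pairs <- unique(pairs)
  parent <- seq_len(mx)
  for (k in seq_len(nrow(pairs))) {
    a <- uf_find(parent, pairs[k, 1]); b <- uf_find(parent, pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(mx), function(i) uf_find(parent, i), integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Label connected components and measure moment features
#'
#' 8-connectivity labeling (diagonal contact joins components). Each
#' component carries its centroid, pixel area, eccentricity of the ellipse
#' with the same second central moments (0 for a disk, near 1 for a line)
#' and equivalent-circle diameter `2 * sqrt(area / pi) * nm_per_px`.
#' Components touching the image border are flagged: their area is censored,
#' so they are excluded from diameter statistics but still count as spots
#' for density.
#'
#' @param mask logical matrix
#' @param nm_per_px calibration, nanometres per pixel
#' @return data frame of class `fibril_components` with columns `label`,
#'   `row`, `col` (centroid), `area_px2`, `eccentricity`, `diameter_nm`,
#'   `min_row`, `min_col`, `max_row`, `max_col`, `on_border`
#' @export
label_components <- function(mask, nm_per_px = 1) {
  stopifnot(is.matrix(mask))
  stopifnot_scalar_positive(nm_per_px, "nm_per_px")
  lab <- round(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  lab <- merge_diagonal(lab)
  idx <- which(lab > 0)
  empty <- data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                      area_px2 = integer(0), eccentricity = numeric(0),
                      diameter_nm = numeric(0), min_row = integer(0),
                      min_col = integer(0), max_row = integer(0),
                      max_col = integer(0), on_border = logical(0))
  if (!length(idx)) {
    attr(empty, "nm_per_px") <- nm_per_px
    class(empty) <- c("fibril_components", "data.frame")
    return(empty)
  }
  l <- lab[idx]
  ## double precision: moment sums of large components overflow integers
  r <- as.numeric((idx - 1L) %% nrow(mask) + 1L)
  c_ <- as.numeric((idx - 1L) %/% nrow(mask) + 1L)
  area <- as.integer(tabulate(l))
  sr <- rowsum(r, l); sc <- rowsum(c_, l)
  rbar <- sr / area; cbar <- sc / area
  mu20 <- rowsum(r^2, l) / area - rbar^2
  mu02 <- rowsum(c_^2, l) / area - cbar^2
  mu11 <- rowsum(r * c_, l) / area - rbar * cbar
  tr2 <- (mu20 + mu02) / 2
  d <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr2 + d; l2 <- tr2 - d
  ecc <- ifelse(l1 <= 0, 0, sqrt(pmax(0, 1 - l2 / l1)))
  min_r <- as.integer(tapply(r, l, min)); max_r <- as.integer(tapply(r, l, max))
  min_c <- as.integer(tapply(c_, l, min)); max_c <- as.integer(tapply(c_, l, max))
  out <- data.frame(
    label = seq_along(area), row = as.numeric(rbar), col = as.numeric(cbar),
    area_px2 = area, eccentricity = as.numeric(ecc),
    diameter_nm = 2 * sqrt(area / pi) * nm_per_px,
    min_row = min_r, min_col = min_c, max_row = max_r, max_col = max_c,
    on_border = min_r == 1L | min_c == 1L |
      max_r == nrow(mask) | max_c == ncol(mask))
  attr(out, "nm_per_px") <- nm_per_px
  class(out) <- c("fibril_components", "data.frame")
  out
}

keep_components <- function(components, keep) {
  out <- components[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nm_per_px") <- attr(components, "nm_per_px")
  class(out) <- class(components)
  out
}

#' Filter components by eccentricity
#'
#' Retains components with eccentricity at most `max_eccentricity`, in input
#' order. Elongated artifacts (scratches, section folds) have eccentricity
#' near 1 and are excluded; the default cutoff is 0.90.
#'
#' @param components a [label_components()] result
#' @param max_eccentricity inclusive upper bound in (0, 1]
#' @return filtered `fibril_components`
#' @export
filter_by_eccentricity <- function(components, max_eccentricity = 0.90) {
  keep_components(components, components$eccentricity <= max_eccentricity)
}

#' Filter components by minimum area
#'
#' Removes noise specks below `min_area_px2` pixels.
#'
#' @param components a [label_components()] result
#' @param min_area_px2 inclusive lower bound, px^2
#' @return filtered `fibril_components`
#' @export
filter_by_area <- function(components, min_area_px2 = 30L) {
  keep_components(components, components$area_px2 >= min_area_px2)
}

#' Full segmentation chain for one micrograph
#'
#' Adaptive binarization, opening, 8-connected labeling, then area and
#' eccentricity filtering.
#'
#' @param image a [micrograph]
#' @param block_size_px,offset,polarity see [adaptive_binarize()]
#' @param opening_radius_px see [morphological_open()]
#' @param min_area_px2 see [filter_by_area()]
#' @param max_eccentricity see [filter_by_eccentricity()]
#' @return list with `mask` (logical matrix after opening) and `components`
#'   (filtered `fibril_components`)
#' @export
segment_micrograph <- function(image, block_size_px = 51L, offset = 0.01,
                               polarity = "bright_objects",
                               opening_radius_px = 2L, min_area_px2 = 30L,
                               max_eccentricity = 0.90) {
  stopifnot(inherits(image, "micrograph"))
  mask <- adaptive_binarize(image, block_size_px, offset, polarity)
  mask <- morphological_open(mask, opening_radius_px)
  comp <- label_components(mask, image$nm_per_px)
  comp <- filter_by_area(comp, min_area_px2)
  comp <- filter_by_eccentricity(comp, max_eccentricity)
  list(mask = mask, components = comp)
}
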