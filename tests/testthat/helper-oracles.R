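## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths (loops instead of integral images,
## all-pairs instead of cell lists).

## per-pixel local-mean threshold with symmetric (edge-inclusive) padding
oracle_adaptive_binarize <- function(pixels, block, offset,
                                     bright = TRUE) {
  h <- nrow(pixels); w <- ncol(pixels)
  p <- (block - 1) %/% 2
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- reflect((i - p):(i + p), h)
    ci <- reflect((j - p):(j + p), w)
    lm <- mean(pixels[ri, ci])
    out[i, j] <- if (bright) (pixels[i, j] - lm) > offset
                 else (lm - pixels[i, j]) > offset
  }
  out
}

## exhaustive O(n^2) nearest-neighbour distances
oracle_nn <- function(centroids, nm_per_px = 1) {
  n <- nrow(centroids)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out * nm_per_px
}

## rasterize a disk by the pixel-centre test; returns logical matrix
oracle_rasterize_disk <- function(h, w, r0, c0, radius) {
  outer(seq_len(h), seq_len(w),
        function(i, j) (i - r0)^2 + (j - c0)^2 <= radius^2)
}

## rasterize an axis-aligned ellipse with semi-axes (a, b)
oracle_rasterize_ellipse <- function(h, w, r0, c0, a, b) {
  outer(seq_len(h), seq_len(w),
        function(i, j) ((i - r0) / a)^2 + ((j - c0) / b)^2 <= 1)
}

## eccentricity straight from per-pixel second central moments
oracle_eccentricity <- function(mask) {
  idx <- which(mask)
  r <- (idx - 1) %% nrow(mask) + 1
  c_ <- (idx - 1) %/% nrow(mask) + 1
  mu20 <- mean(r^2) - mean(r)^2
  mu02 <- mean(c_^2) - mean(c_)^2
  mu11 <- mean(r * c_) - mean(r) * mean(c_)
  t2 <- (mu20 + mu02) / 2
  d <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  sqrt(max(0, 1 - (t2 - d) / (t2 + d)))
}

## closed-form pooled-variance two-sample t
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * pt(-abs(t), nx + ny - 2)
  list(t = t, p = p)
}

## small synthetic scene + rendering shared by several tests
make_test_scene <- function(seed = 1, density_per_window = 18,
                            diam = 40.67, n_art = 0, side = 512) {
  generate_scene(density_per_window / (300^2 / 1e6), diam, 2, 4,
                 n_artifacts = n_art, image_shape_px = c(side, side),
                 nm_per_px = 1, seed = seed)
}
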