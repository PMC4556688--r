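test_that("adaptive binarization matches the brute-force local-mean oracle", {
  set.seed(42)
  for (rep in 1:3) {
    px <- matrix(runif(100), 10, 10)
    got <- adaptive_binarize(px, block_size_px = 5L, offset = 0.02)
    expect_identical(got, oracle_adaptive_binarize(px, 5, 0.02))
    got_dark <- adaptive_binarize(px, 5L, 0.02, polarity = "dark_objects")
    expect_identical(got_dark,
                     oracle_adaptive_binarize(px, 5, 0.02, bright = FALSE))
  }
})

test_that("binarization handles constant images, disks and bad arguments", {
  const <- matrix(0.5, 64, 64)
  expect_false(any(adaptive_binarize(const, 9L, offset = 0.01)))

  ## bright disk on dark background: mask covers the interior minus a ring
  disk <- oracle_rasterize_disk(32, 32, 16, 16, 8)
  px <- 0.2 + 0.6 * disk
  mask <- adaptive_binarize(px, 15L, offset = 0)
  interior <- oracle_rasterize_disk(32, 32, 16, 16, 6)
  expect_true(all(mask[interior]))
  expect_identical(mask, oracle_adaptive_binarize(px, 15, 0))

  expect_error(adaptive_binarize(px, 10L), "odd")
  expect_error(adaptive_binarize(px, 65L), "larger")
})

test_that("opening is anti-extensive, identity at radius 0, kills singletons", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(runif(400) < 0.4, 20, 20)
    expect_identical(morphological_open(m, 0L), m)
    opened <- morphological_open(m, 1L)
    expect_true(all(m[opened]))     # opened subset of input
  }
  single <- matrix(FALSE, 16, 16); single[8, 8] <- TRUE
  expect_false(any(morphological_open(single, 1L)))
  ## a disk comfortably larger than the element survives (mostly) intact
  big <- oracle_rasterize_disk(64, 64, 32, 32, 15)
  expect_gt(sum(morphological_open(big, 2L)), 0.95 * sum(big))
})

test_that("component labeling is 8-connected with correct moments", {
  m <- matrix(FALSE, 20, 20)
  m[2:4, 2:4] <- TRUE; m[10:12, 10:12] <- TRUE
  comp <- label_components(m, 1)
  expect_equal(nrow(comp), 2)
  expect_equal(comp$area_px2, c(9L, 9L))
  expect_equal(comp$eccentricity, c(0, 0), tolerance = 1e-12)

  ## diagonal contact joins components (8-connectivity)
  dg <- matrix(FALSE, 10, 10); dg[3, 3] <- TRUE; dg[4, 4] <- TRUE
  expect_equal(nrow(label_components(dg, 1)), 1)

  ## rasterized disk: low eccentricity, diameter ~ 2r
  disk <- oracle_rasterize_disk(64, 64, 32, 32, 20)
  cd <- label_components(disk, 1)
  expect_lt(cd$eccentricity, 0.3)
  expect_equal(cd$diameter_nm, 40, tolerance = 1)
  expect_equal(cd$row, 32, tolerance = 0.01)

  ## 20 x 2 rectangle: eccentricity from closed-form inertia moments
  rect <- matrix(FALSE, 30, 30); rect[5:24, 5:6] <- TRUE
  cr <- label_components(rect, 1)
  mu20 <- (20^2 - 1) / 12; mu02 <- (2^2 - 1) / 12
  expect_gt(cr$eccentricity, 0.95)
  expect_equal(cr$eccentricity, sqrt(1 - mu02 / mu20), tolerance = 1e-9)

  ## border flag
  bm <- matrix(FALSE, 12, 12); bm[1:3, 5:7] <- TRUE; bm[6:8, 5:7] <- TRUE
  cb <- label_components(bm, 1)
  expect_identical(cb$on_border, c(TRUE, FALSE))
})

test_that("eccentricity of rasterized ellipses tracks sqrt(1 - q^2)", {
  for (q in c(0.3, 0.5, 0.8)) {
    a <- 24; b <- a * q
    ell <- oracle_rasterize_ellipse(64, 64, 32, 32, a, b)
    comp <- label_components(ell, 1)
    expect_equal(comp$eccentricity, sqrt(1 - q^2), tolerance = 0.05)
    expect_equal(comp$eccentricity, oracle_eccentricity(ell),
                 tolerance = 1e-9)
  }
})

test_that("filters act on eccentricity and area, preserving order", {
  m <- matrix(FALSE, 40, 80)
  m[5:14, 5:14] <- TRUE          # 10x10 square, ecc 0
  m[20:21, 5:44] <- TRUE         # 2x40 line, ecc ~ 1
  m[30:31, 5:6] <- TRUE          # 2x2 speck
  comp <- label_components(m, 1)
  expect_equal(nrow(comp), 3)

  kept <- filter_by_eccentricity(comp, 0.9)
  expect_equal(kept$area_px2, c(100L, 4L))
  expect_identical(filter_by_eccentricity(comp, 1.0)$label, comp$label)
  empty <- filter_by_eccentricity(comp[0, ], 0.5)
  expect_equal(nrow(empty), 0)

  expect_equal(nrow(filter_by_area(comp, 1L)), 3)
  expect_equal(nrow(filter_by_area(comp, 1000L)), 0)
  set.seed(11)
  for (rep in 1:3) {
    mm <- matrix(runif(900) < 0.3, 30, 30)
    cc <- label_components(mm, 1)
    thr <- sample(1:20, 1)
    expect_equal(filter_by_area(cc, thr)$label,
                 cc$label[cc$area_px2 >= thr])
  }
})

test_that("segmentation recovers ground truth on rendered scenes", {
  sc <- make_test_scene(seed = 31, density_per_window = 18, n_art = 5,
                        side = 512)
  ## noise-free: exact component count (fibrils only, artifacts excluded)
  img0 <- render_micrograph(sc, noise_sd = 0, blur_sigma_px = 0)
  seg0 <- segment_micrograph(img0)
  expect_equal(nrow(seg0$components), nrow(sc$centers))
  expect_true(all(seg0$components$eccentricity <= 0.9))

  ## noisy + blurred: within 5%
  img1 <- render_micrograph(sc, noise_sd = 0.05, blur_sigma_px = 1)
  seg1 <- segment_micrograph(img1)
  expect_lt(abs(nrow(seg1$components) / nrow(sc$centers) - 1), 0.05)

  ## no retained component sits on an artifact stroke (artifacts excluded)
  dist_seg <- fibrilquant:::.dist_to_segment
  cen <- cbind(seg1$components$row, seg1$components$col)
  for (a in seq_len(nrow(sc$artifacts))) {
    s <- sc$artifacts[a, ]
    expect_false(any(dist_seg(cen[, 1], cen[, 2], s$a_row, s$a_col,
                              s$b_row, s$b_col) <= s$thickness_px))
  }
})
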