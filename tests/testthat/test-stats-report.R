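test_that("group summaries use sample SD and reject singletons", {
  t1 <- data.frame(group = "a", value = c(1, 1, 1))
  s1 <- group_summary(t1)
  expect_equal(s1$mean, 1); expect_equal(s1$sd, 0); expect_equal(s1$n, 3)

  t2 <- data.frame(group = c("a", "a", "b", "b"), value = c(2, 4, 5, 9))
  s2 <- group_summary(t2)
  expect_equal(s2$mean[s2$group == "a"], 3)
  expect_equal(s2$sd[s2$group == "a"], sqrt(2))

  expect_error(group_summary(data.frame(group = c("a", "a", "b"),
                                        value = 1:3)), "singleton")

  ## CLT recovery at the control CCT setting
  big <- generate_group_table(
    data.frame(group = "Control", mean = 362, sd = 12, n = 1000), seed = 6)
  expect_lt(abs(group_summary(big)$mean - 362), 1.2)
})

test_that("pairwise Student t-tests match the closed form", {
  tab <- data.frame(group = rep(c("x", "y"), each = 3),
                    value = c(1, 2, 3, 4, 5, 6))
  plan <- data.frame(group_a = "x", group_b = "y")
  res <- pairwise_ttests(tab, plan)
  oracle <- oracle_student_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t_statistic, oracle$t, tolerance = 1e-10)
  expect_equal(res$t_statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(res$p_value, 0.02131, tolerance = 1e-3)
  expect_true(res$significant)

  ## identical groups: t = 0, p = 1
  same <- data.frame(group = rep(c("x", "y"), each = 3),
                     value = rep(c(1, 2, 3), 2))
  r0 <- pairwise_ttests(same, plan)
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_false(r0$significant)

  ## sign antisymmetry
  rev <- pairwise_ttests(tab, data.frame(group_a = "y", group_b = "x"))
  expect_equal(rev$t_statistic, -res$t_statistic)
  expect_equal(rev$p_value, res$p_value)

  expect_error(pairwise_ttests(tab, data.frame(group_a = "x",
                                               group_b = "zzz")), "missing")
})

test_that("default plan encodes the two comparison families", {
  plan <- default_comparison_plan()
  expect_equal(nrow(plan), 8)
  expect_true(all(c("COLG", "ChaseABC") %in%
                  plan$group_a[plan$group_b == "Control"]))
  expect_true(all(plan$group_b %in% c("Control", "COLG", "ChaseABC")))
  expect_true("ChaseABC-CXL+Col" %in% plan$group_a[plan$group_b == "ChaseABC"])
})

test_that("swelling reduction reproduces the printed worked examples", {
  ref <- load_reference_table("cct")
  swl <- ref[ref$measure == "swelled_cct_um", ]
  chase <- percent_swelling_reduction(swl, "ChaseABC-CXL+Col", "ChaseABC-CXL")
  colg <- percent_swelling_reduction(swl, "COLG-CXL+Col", "COLG-CXL")
  ctrl <- percent_swelling_reduction(swl, "Control-CXL+Col", "Control-CXL")
  expect_equal(chase, 100 * (663 - 552) / 663)
  expect_equal(round_half_up(chase), 17)
  expect_equal(round_half_up(colg), 6)
  expect_lte(ctrl, 4)

  ## equal means -> 0; raw value table also accepted
  raw <- data.frame(group = rep(c("a", "b"), each = 2), value = c(5, 5, 5, 5))
  expect_equal(percent_swelling_reduction(raw, "a", "b"), 0)
  zero <- data.frame(group = c("a", "b"), mean = c(1, 0))
  expect_error(percent_swelling_reduction(zero, "a", "b"), "zero")
  expect_error(percent_swelling_reduction(swl, "nope", "ChaseABC-CXL"),
               "not found")
})

test_that("report assembly is idempotent and formats mean +/- SD verbatim", {
  ## summary-table path reproduces the packaged cells
  morph <- load_reference_table("morphometry")
  rep1 <- build_report(morph)
  expect_setequal(names(rep1), c("diameter_nm", "nn_distance_nm", "density"))
  dia <- rep1$diameter_nm
  expect_equal(dia$mean_sd[dia$group == "Control"], "40.67±0.92")
  expect_equal(dia$mean_sd[dia$group == "COLG"], "36.37±2.15")
  tr <- build_report(load_reference_table("transition"))$transition_C
  expect_equal(tr$mean_sd[tr$group == "ChaseABC-CXL"], "74.95±0.72")

  ## idempotence
  expect_identical(rep1, build_report(morph))

  ## raw-value path attaches significance flags
  specs <- data.frame(group = c("Control", "COLG"), mean = c(362, 331),
                      sd = c(12, 10.5), n = 6)
  tab <- generate_group_table(specs, measure = "cct_um", seed = 3)
  rep2 <- build_report(tab)
  expect_true("flag" %in% names(rep2$cct_um))

  ## write_report emits one CSV per measure, deterministically
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_report(rep1, d1); p2 <- write_report(rep1, d2)
  expect_length(p1, 3)
  expect_identical(readLines(p1[1]), readLines(p2[1]))
})

test_that("the t-test is calibrated under the null at small n", {
  ## quick calibration check at n = 6 (full n = 3 case in acceptance suite)
  set.seed(13)
  rej <- mean(replicate(2000, {
    tab <- data.frame(group = rep(c("a", "b"), each = 6), value = rnorm(12))
    pairwise_ttests(tab, data.frame(group_a = "a", group_b = "b"))$p_value < 0.05
  }))
  expect_gt(rej, 0.035); expect_lt(rej, 0.065)
})
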