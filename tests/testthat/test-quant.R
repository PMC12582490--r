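# Calibration, lack-of-fit, LOD/LOQ, recovery and inverse quantification.

test_that("the IS-normalized response follows its definition", {
  expect_equal(is_response(1000, 1000, 5.0), 5.0)
  expect_equal(is_response(0, 1000, 5.0), 0)
  expect_equal(is_response(2500, 1000, 5.0), 12.5)
  expect_error(is_response(100, 0, 5.0), "IS failure")
})

test_that("calibration fitting is exact on noiseless lines and guards degenerate input", {
  x <- rep(c(0.2, 1, 5, 10, 20), each = 3)
  y <- 0.1155 * x + 0.003238
  cal <- fit_calibration(x, y)
  expect_equal(cal$slope, 0.1155, tolerance = 1e-10)
  expect_equal(cal$intercept, 0.003238, tolerance = 1e-10)
  expect_equal(cal$r2, 1, tolerance = 1e-12)
  expect_equal(predict_conc(cal, 0.1155 * 7 + 0.003238), 7, tolerance = 1e-9)
  expect_error(fit_calibration(c(1, 1, 2), c(1, 2, 3)), "3 distinct")
  expect_error(fit_calibration(x, rep(2, length(x))), "constant")
  # weighted variant runs and still recovers the exact line
  calw <- fit_calibration(x, y, weighting = "1/x")
  expect_equal(calw$slope, 0.1155, tolerance = 1e-10)
})

test_that("slope recovery under 2% multiplicative noise is unbiased and precise", {
  set.seed(55)
  x <- rep(c(0.2, 1, 5, 10, 20), each = 3)
  rel_err <- replicate(50, {
    y <- (0.1155 * x + 0.003238) * (1 + rnorm(length(x), 0, 0.02))
    abs(fit_calibration(x, y)$slope - 0.1155) / 0.1155
  })
  expect_lt(median(rel_err), 0.02)
  expect_lt(mean(rel_err), 0.02)
})

test_that("lack-of-fit decomposition satisfies the ANOVA identity (independent oracle)", {
  set.seed(77)
  for (i in 1:100) {
    x <- rep(1:5, each = 3)
    y <- 0.5 + 2 * x + rnorm(15, 0, 0.3)
    lof <- lack_of_fit_test(x, y)
    # oracle: recompute SS_lof directly from level means about the line
    fit <- lm(y ~ x)
    mns <- tapply(y, x, mean)
    lof_direct <- sum(3 * (mns - (coef(fit)[1] + coef(fit)[2] * as.numeric(names(mns))))^2)
    expect_equal(lof$ss_r, lof$ss_eps + lof$ss_lof,
                 tolerance = 1e-9 * max(lof$ss_r, 1e-12))
    expect_equal(lof$ss_lof, lof_direct, tolerance = 1e-8)
    expect_gte(lof$F, 0)
  }
})

test_that("the five-level triplicate design reproduces the tabulated F(3,10) = 3.71", {
  x <- rep(c(0.2, 1, 5, 10, 20), each = 3)
  set.seed(1)
  y <- 0.1 * x + rnorm(15, 0, 0.01)
  lof <- lack_of_fit_test(x, y)
  expect_identical(lof$df, c(3, 10))
  expect_equal(round_half_up(lof$F_crit, 2), 3.71)
})

test_that("noiseless linear data give F = 0 and a linear verdict; curvature is caught", {
  x <- rep(c(0.2, 1, 5, 10, 20), each = 3)
  lof0 <- lack_of_fit_test(x, 2 * x + 1)
  expect_equal(lof0$F, 0)
  expect_equal(lof0$ss_lof, 0, tolerance = 1e-12)
  expect_true(lof0$linear)
  set.seed(9)
  ycur <- 2 * x + 0.05 * x^2 + rnorm(15, 0, 0.05)
  expect_false(lack_of_fit_test(x, ycur)$linear)
  expect_error(lack_of_fit_test(c(1, 2, 3), c(1, 2, 3)), "replicated")
  expect_error(lack_of_fit_test(c(1, 1, 2, 2, 3, 3, 3), 1:7), "balanced")
})

test_that("LOD/LOQ follow the 3x / 10x signal-to-noise rule", {
  r <- lod_loq(spike = 1.0, sn = 150)
  expect_equal(r$lod, 0.02)
  expect_equal(r$loq, 1 / 15, tolerance = 1e-12)
  expect_equal(r$loq / r$lod, 10 / 3, tolerance = 1e-12)
  expect_equal(lod_loq(spike = 1.0, sn = 3)$lod, 1.0)
  # XIC paths: noiseless trace flags the simulation floor; absent peak flags
  run <- gaussian_run(area = 1e5)
  x <- extract_xic(run, 512.960039, 468.970210)
  expect_identical(lod_loq(1.0, xic = x)$flag, "below-noise-floor")
  xa <- extract_xic(gaussian_run(area = 0), 512.960039, 468.970210)
  expect_identical(lod_loq(1.0, xic = xa)$flag, "not-detected")
  # noisy trace yields a finite, positive limit pair
  g <- generate_run(synth_config(conc_ugl = c(PFOS = 1), baseline_mean = 100,
                                 baseline_sd = 30, seed = 5), REG)
  tr <- diagnostic_transition("PFOS", REG)
  xn <- extract_xic(g$run, registry_compound("PFOS", REG)$precursor_mz_theo,
                    tr$product_mz_theo, rt_range = c(8.22, 9.22))
  rn <- lod_loq(1.0, xic = xn)
  expect_identical(rn$flag, "ok")
  expect_gt(rn$lod, 0)
  expect_gt(rn$loq, rn$lod)
})

test_that("recovery and RSD arithmetic reproduce the reported convention", {
  r <- recovery_precision(c(4.60, 4.66, 4.72), spike = 5.0, background = "n.d.")
  expect_equal(round_half_up(r$recovery, 1), 93.2)
  r2 <- recovery_precision(c(9.45, 9.50, 9.55), spike = 10)
  expect_equal(round_half_up(r2$recovery, 1), 95.0)
  expect_equal(recovery_precision(rep(4, 6), spike = 5)$rsd, 0)
  # a nonzero background is subtracted before scaling
  r3 <- recovery_precision(c(6, 6.2), spike = 5, background = 1.1)
  expect_equal(r3$recovery, (6.1 - 1.1) / 5 * 100)
  expect_error(recovery_precision(c(1, 2), spike = 0), "positive")
  expect_error(recovery_precision(3, spike = 5), "2 replicate")
})

test_that("sample quantification inverse-predicts planted levels and flags edge cases", {
  curves <- validate_method(
    generate_calibration_set(c("PFOS", "PFOA"), seed = 2)$data)$curves
  g <- generate_run(synth_config(conc_ugl = c(PFOS = 5, PFOA = 2), seed = 12), REG)
  q <- quantify_sample(g$run, curves, REG)
  expect_equal(q$conc_ngl[q$name == "PFOS"], 5, tolerance = 0.01)
  expect_equal(q$conc_ngl[q$name == "PFOA"], 2, tolerance = 0.01)
  expect_identical(q$flag[q$name == "PFHxA"], "not acquired")
  expect_identical(q$flag[q$name == "PFOS"], "ok")
  # blank: scheduled channels, no analyte signal -> n.d.
  b <- generate_run(synth_config(conc_ugl = c(PFOS = 0, PFOA = 0), seed = 12), REG)
  qb <- quantify_sample(b$run, curves, REG)
  expect_true(all(qb$flag[qb$name %in% c("PFOS", "PFOA")] == "n.d."))
  # above the calibration range: no extrapolated value
  o <- generate_run(synth_config(conc_ugl = c(PFOS = 30), seed = 12), REG)
  qo <- quantify_sample(o$run, curves, REG)
  expect_identical(qo$flag[qo$name == "PFOS"], "over range")
  expect_true(is.na(qo$conc_ngl[qo$name == "PFOS"]))
  # missing curve
  q2 <- quantify_sample(g$run, curves["PFOS"], REG)
  expect_identical(q2$flag[q2$name == "PFOA"], "no curve")
})
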