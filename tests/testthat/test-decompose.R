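test_that("chemoreflex gains are recovered from noise-free synthetic data", {
  # drive-free, LTF-free record: ventilation is pure chemoreflex
  cfg <- noiseless_config(
    drive_amp = c(rest = 0, w40 = 0, light45 = 0, heavy80 = 0),
    ltf = canonical_params(wn = 0.375, zeta = 0.7, A = 0, B = 1e-9,
                           baseline = 0, onset_delay = 2))
  grp <- generate_group(cfg, "co2_3pct")
  fit <- fit_chemo_gains(grp$group)
  expect_true(fit$identifiable)
  expect_true(fit$converged)
  expect_equal(fit$Gc, cfg$chemo$Gc, tolerance = 0.01)
  expect_equal(fit$Gp, cfg$chemo$Gp, tolerance = 0.01)
  expect_lt(fit$residual_sd_lpm, 1e-4)
})

test_that("flat PetCO2 flags the gains as unidentifiable", {
  cfg <- noiseless_config()
  grp <- generate_group(cfg, "co2_3pct")
  tr <- grp$group
  tr$petco2_mmhg <- rep(40, nrow(tr))
  fit <- fit_chemo_gains(tr)
  expect_false(fit$identifiable)
  expect_equal(fit$Gc, 0)
  # residual equals the spread of the uncorrected ventilation deviation
  win <- fit$fit_window
  dve <- tr$ve_lpm - tr$ve_lpm[tr$time_min == 5]
  expect_equal(fit$residual_sd_lpm, stats::sd(dve[win]))
})

test_that("group-averaged residual SD stays near the sampling-noise level", {
  sds <- vapply(1:5, function(s) {
    grp <- generate_group(generator_config(seed = s), "co2_3pct")
    fit_chemo_gains(grp$group)$residual_sd_lpm
  }, numeric(1))
  # group averaging over 7 subjects reduces 1.7 L/min per-subject noise to
  # ~0.64; model mismatch adds a little, but it stays below the printed
  # per-subject 1.73
  expect_lt(mean(sds), 1.73)
  expect_gt(mean(sds), 0.3)
})

test_that("the neural component is the measured deviation minus the fit", {
  cfg <- noiseless_config()
  grp <- generate_group(cfg, "co2_3pct")
  comp <- attr(generate_subject(cfg, "co2_3pct",
                                grp$subject_seeds[1], "s1"), "components")
  # with the true gains supplied, neural = exercise drive + LTF exactly
  fit <- fit_chemo_gains(grp$group)
  fit$params <- cfg$chemo
  fit$Gc <- cfg$chemo$Gc; fit$Gp <- cfg$chemo$Gp
  neural <- neural_component(grp$group, fit)
  expect_equal(neural, comp$drive_lpm + comp$ltf_lpm, tolerance = 1e-6)

  # a record equal to the prediction decomposes to zero
  tr0 <- grp$group
  dpet <- tr0$petco2_mmhg - tr0$petco2_mmhg[tr0$time_min == 5]
  pred <- predict_ventilation(cfg$chemo, c(0, dpet), dt = 30)[-1]
  tr0$ve_lpm <- pred + 30  # constant offset cancels in the deviation
  expect_equal(neural_component(tr0, fit), rep(0, nrow(tr0)),
               tolerance = 1e-9)

  # grid mismatch is an error
  short <- grp$group[-1, ]
  expect_error(neural_component(short, fit), "grid")
})

test_that("rebaselining shifts a series to its reference sample", {
  tt <- seq(0.5, 5, by = 0.5)
  expect_equal(rebaseline(tt, tt, at = 2), tt - 2)
  expect_equal(rebaseline(rep(7, 10), tt, at = 0.5), rep(0, 10))
  r <- rebaseline(sin(tt), tt, at = 3)
  expect_equal(r[tt == 3], 0)
  expect_error(rebaseline(tt, tt, at = 1.23), "grid")
})

test_that("onset detection finds the facilitation threshold crossing", {
  pure <- pure_ltf_series()
  onset <- detect_onset(pure$x, pure$grid$time_min, pure$grid$segment,
                        noise_sd = 0.05)
  expect_gte(as.numeric(onset) - pure$t0, 2.0)
  expect_lte(as.numeric(onset) - pure$t0, 2.5)

  # a single-sample spike does not trigger the 2-consecutive rule
  spike <- numeric(nrow(pure$grid))
  spike[pure$grid$time_min == 21] <- 10
  expect_true(is.na(detect_onset(spike, pure$grid$time_min,
                                 pure$grid$segment, noise_sd = 0.5)))

  # false-positive rate on flat noise stays below ~5%
  set.seed(99)
  rec <- pure$grid$segment == "w40_recovery"
  fp <- mean(replicate(200, {
    xx <- numeric(nrow(pure$grid))
    xx[rec] <- rnorm(sum(rec), 0, 0.64)
    !is.na(detect_onset(xx, pure$grid$time_min, pure$grid$segment,
                        noise_sd = 0.64))
  }))
  expect_lt(fp, 0.08)

  expect_error(detect_onset(pure$x, pure$grid$time_min, pure$grid$segment,
                            noise_sd = 0), "noise_sd")
  expect_error(detect_onset(1:3, 1:3, rep("w40_recovery", 3),
                            noise_sd = 1), "4 samples")
})

test_that("the LTF fit recovers noise-free parameters to 1e-3 relative", {
  pure <- pure_ltf_series()
  fit <- fit_ltf(pure$x, pure$grid$time_min, pure$grid$segment,
                 onset = 19.5)
  p <- fit$params
  expect_equal(p$wn, 0.375, tolerance = 1e-3)
  expect_equal(p$zeta, 0.7, tolerance = 1e-3)
  expect_equal(p$B, 9, tolerance = 1e-3)
  expect_equal(p$baseline, 7.6, tolerance = 1e-3)
  expect_equal(p$onset_delay, 2, tolerance = 1e-3)

  # a flat series fits an essentially zero amplitude
  flat <- numeric(nrow(pure$grid)) + 3
  f0 <- fit_ltf(flat, pure$grid$time_min, pure$grid$segment, onset = 19.5)
  expect_lt(f0$params$B, 0.1)

  expect_error(fit_ltf(pure$x, pure$grid$time_min, pure$grid$segment,
                       onset = 19.5, skip_min = 5.9), "6 samples")
})

test_that("fitting commutes with a constant baseline shift", {
  pure <- pure_ltf_series()
  set.seed(21)
  noisy <- pure$x + rnorm(length(pure$x), 0, 0.3)
  f1 <- fit_ltf(noisy, pure$grid$time_min, pure$grid$segment, onset = 19.5)
  f2 <- fit_ltf(noisy + 4.2, pure$grid$time_min, pure$grid$segment,
                onset = 19.5)
  expect_equal(f2$params$B, f1$params$B, tolerance = 1e-3)
  expect_equal(f2$params$wn, f1$params$wn, tolerance = 1e-3)
  expect_equal(f2$params$zeta, f1$params$zeta, tolerance = 1e-3)
  expect_equal(f2$params$baseline, f1$params$baseline + 4.2,
               tolerance = 1e-3)
})

test_that("extrapolation reports the model steady state", {
  pure <- pure_ltf_series()
  fit <- fit_ltf(pure$x, pure$grid$time_min, pure$grid$segment,
                 onset = 19.5)
  ex <- extrapolate_ltf(fit, horizon_min = 40)
  expect_equal(ex$above_initial_lpm, 9, tolerance = 1e-3)
  expect_equal(ex$asymptote_lpm, 16.6, tolerance = 1e-3)
  expect_equal(tail(ex$series$ve_lpm, 1), ex$asymptote_lpm,
               tolerance = 0.01)

  flat <- fit_ltf(numeric(nrow(pure$grid)), pure$grid$time_min,
                  pure$grid$segment, onset = 19.5)
  exf <- extrapolate_ltf(flat)
  expect_lt(max(exf$series$ve_lpm) - min(exf$series$ve_lpm), 0.1)
})

test_that("the final-augmentation estimate combines both variance sources", {
  finals <- c(10, 14, 18, 20, 15, 17, 22)
  a <- augmentation_estimate(finals, fit_sd = 1.73)
  expect_equal(a$estimate_lpm, mean(finals))
  expect_equal(a$combined_sd_lpm, sqrt(sd(finals)^2 + 1.73^2))
  expect_equal(a$se_lpm, a$combined_sd_lpm / sqrt(7))
  expect_lt(a$p, 0.001)

  b <- augmentation_estimate(finals, fit_sd = 0)
  expect_equal(b$combined_sd_lpm, sd(finals))

  cc <- augmentation_estimate(rep(5, 4), fit_sd = 0)
  expect_equal(cc$estimate_lpm, 5)
  expect_equal(cc$se_lpm, 0)

  expect_error(augmentation_estimate(3, fit_sd = 1), "two subjects")
})

test_that("the full pipeline yields coherent estimates on default groups", {
  res <- lapply(1:8, function(s) {
    grp <- generate_group(generator_config(seed = s), "co2_3pct")
    decompose_ltf(grp$group, grp$subjects)
  })
  endw <- vapply(res, function(r) r$end_window_estimate_lpm, numeric(1))
  # the end-of-window augmentation is well identified: truth is the
  # baseline 7.6 plus the step response 4 min past onset (= 12.38)
  expect_equal(mean(endw), 12.38, tolerance = 0.15)
  for (r in res) {
    expect_true(r$chemofit$identifiable)
    expect_equal(r$asymptote_above_control_lpm,
                 r$ltf_fit$params$baseline + r$ltf_fit$params$B)
    expect_equal(r$augmentation$n, 7)
    expect_true(is.finite(r$augmentation$se_lpm))
    expect_equal(r$augmentation$estimate_lpm, mean(r$subject_finals_lpm))
  }
})
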