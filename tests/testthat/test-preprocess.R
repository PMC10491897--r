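test_that("repeat averaging is the elementwise mean and rejects ragged input", {
  expect_equal(average_repeats(list(c(1, 2, 3))), c(1, 2, 3))
  expect_equal(average_repeats(list(c(0, 0), c(2, 2))), c(1, 1))
  expect_error(average_repeats(list(1:3, 1:4)), "ragged")

  # averaging 10 i.i.d. frames shrinks the per-pixel variance ~10-fold
  set.seed(1)
  means <- replicate(2000, mean0 <- average_repeats(
    matrix(stats::rnorm(64 * 10, sd = 2), 64, 10))[1])
  expect_lt(abs(var(means) / (4 / 10) - 1), 0.15)
})

test_that("dark subtraction scales by the integration-time ratio", {
  expect_equal(subtract_dark(c(5, 5), c(5, 5), 0.075, 0.075), c(0, 0))
  expect_equal(subtract_dark(rep(400, 4), rep(100, 4), 0.075, 0.050),
               rep(250, 4))
  expect_equal(subtract_dark(c(3, 4), c(0, 0), 0.075, 0.050), c(3, 4))
  expect_error(subtract_dark(1, 1, 0, 0.05), "times")
  expect_error(subtract_dark(1:3, 1:2, 0.075, 0.05), "lengths")
})

test_that("calibration fitting recovers polynomial pixel maps", {
  px <- c(50, 200, 400, 600, 800, 950)
  truth <- c(795, 0.8, 9e-5)
  wn <- ramanlung:::polyval_asc(truth, px)
  fit <- fit_calibration(px, wn, order = 2)
  expect_lt(fit$rms_residual, 1e-8)
  expect_equal(unname(fit$coefficients), truth, tolerance = 1e-6)

  two <- fit_calibration(c(100, 900), c(900, 1600), order = 1)
  expect_lt(two$rms_residual, 1e-9)

  expect_error(fit_calibration(c(1, 2), c(800, 900), order = 2),
               "underdetermined")
  expect_error(fit_calibration(c(100, 500, 900), c(1600, 900, 1650)[order(c(1600, 900, 1650))],
                               order = 2), "sorted|increasing")

  # half-pixel detection jitter maps to sub-jitter wavenumber residuals
  set.seed(4)
  jit <- px + stats::runif(length(px), -0.5, 0.5)
  fitj <- fit_calibration(sort(jit), wn, order = 2)
  expect_lt(fitj$rms_residual, 0.5 * 0.9)  # 0.9 cm^-1 per pixel
})

test_that("response estimation and correction invert the instrument gain", {
  cert <- 0.2 + exp(-((1:400 - 200) / 150)^2)
  same <- estimate_response(cert, cert)
  expect_equal(same$factors, rep(1, 400), tolerance = 1e-6)
  twice <- estimate_response(2 * cert, cert)
  expect_equal(twice$factors, rep(2, 400), tolerance = 1e-6)
  expect_error(estimate_response(cert, rep(0, 400)), "certified")
  expect_error(estimate_response(-cert, cert), "nonpositive")

  expect_equal(correct_response(c(2, 4), c(1, 1)), c(2, 4))
  expect_equal(correct_response(c(2, 4), c(2, 2)), c(1, 2))
  expect_error(correct_response(1:3, 1:2), "mismatch")

  # synthetic instrument: noise-free recovery of the true response curve
  instr <- instrument_model()
  ref <- synth_reference_frames(instr)
  est <- estimate_response(ref$broadband_frame, ref$certified_shape)
  rel <- est$factors / instr$response_curve - 1
  expect_lt(sqrt(mean(rel^2)), 0.02)
})

test_that("snv follows the population formula and its invariances", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  x <- stats::rnorm(100)
  expect_equal(snv(snv(x)), snv(x), tolerance = 1e-12)
  expect_equal(snv(3.7 * x + 11), snv(x), tolerance = 1e-9)
  expect_equal(mean(snv(x)), 0, tolerance = 1e-12)
  expect_equal(mean(snv(x)^2), 1, tolerance = 1e-12)
  expect_error(snv(rep(2, 10)), "constant")
})

test_that("bubblefill produces a tight envelope below the spectrum", {
  axis <- raman_axis()
  # constant spectrum: baseline equals it exactly
  bf0 <- bubblefill(rep(5, 901), axis, 100)
  expect_equal(bf0$baseline, rep(5, 901))
  expect_equal(bf0$raman, numeric(901))

  # pure broad background: residual under 5% of the amplitude
  bg <- exp(-4 * log(2) * (axis - 1200)^2 / 400^2)
  bf1 <- bubblefill(bg, axis, 100)
  expect_lt(max(abs(bf1$raman)), 0.05)
  expect_true(all(bf1$baseline <= bg + 1e-9))

  # background + one narrow peak: peak height recovered within 10%
  pk <- 0.5 * exp(-4 * log(2) * (axis - 1300)^2 / 15^2)
  bf2 <- bubblefill(bg + pk, axis, 100)
  expect_lt(abs(bf2$raman[axis == 1300] - 0.5) / 0.5, 0.10)

  # envelope and nonnegativity on rough random spectra
  set.seed(2)
  for (i in 1:5) {
    y <- cumsum(stats::rnorm(901, sd = 0.2)) + 3 * sin(axis / 120)
    bf <- bubblefill(y, axis, 100)
    expect_true(all(bf$baseline <= y + 1e-9))
    expect_true(all(bf$raman >= -1e-9))
  }

  # scale equivariance for c > 0
  y <- bg + pk
  bf_scaled <- bubblefill(7 * y, axis, 100)
  expect_equal(bf_scaled$baseline, 7 * bubblefill(y, axis, 100)$baseline,
               tolerance = 1e-9)

  # min_bubble_width >= span: single-bubble degenerate envelope, no error
  wide <- bubblefill(y, axis, 2000)
  expect_true(all(wide$baseline <= y + 1e-9))
  expect_error(bubblefill(y, axis, 0.5), "spacing")
})

test_that("the full chain recovers the generator truth up to baseline removal", {
  instr <- instrument_model()
  cfg <- cohort_config(seed = 1)
  prof <- default_tissue_profiles()$cancer_necrosis
  ref <- synth_reference_frames(instr)
  peaks <- find_peaks(ref$calibration_frame)
  cal <- fit_calibration(peaks, ref$reference_wavenumbers, order = 2,
                         pixel_range = c(1, instr$n_pixels))
  resp <- estimate_response(ref$broadband_frame, ref$certified_shape)
  axis <- raman_axis()
  pure <- synth_pure_spectrum(prof, axis)

  m <- simulate_measurement(prof, instr, cfg, noise = FALSE,
                            background_amplitude = 0)
  ps <- preprocess_measurement(m, cal, resp, cfg)
  target <- snv(bubblefill(pure, axis, 100)$raman)
  expect_lt(sqrt(mean((ps$snv_intensity - target)^2)), 0.01)

  # reconstruction invariant: baseline + residual = resampled spectrum
  expect_lt(max(abs(ps$baseline + ps$raman_before_snv - ps$resampled)), 1e-9)
  # SNV contract on the output
  expect_equal(mean(ps$snv_intensity), 0, tolerance = 1e-9)
  expect_equal(mean(ps$snv_intensity^2), 1, tolerance = 1e-9)

  # resampling preserves band centers within one axis step
  for (b in c(852, 1004, 1449, 1657)) {
    i <- which.max(ps$snv_intensity * (abs(axis - b) < 8))
    expect_lte(abs(axis[i] - b), 1)
  }

  # determinism and robustness
  ps2 <- preprocess_measurement(m, cal, resp, cfg)
  expect_identical(ps$snv_intensity, ps2$snv_intensity)
  set.seed(9)
  md <- simulate_measurement(prof, instr, cfg, quality = "degraded")
  psd <- preprocess_measurement(md, cal, resp, cfg)
  expect_true(all(is.finite(psd$snv_intensity)))

  # with the full fluorescence background the chain still isolates the Raman
  # component (baseline misfit leaves a few percent of residual structure)
  mb <- simulate_measurement(prof, instr, cfg, noise = FALSE)
  psb <- preprocess_measurement(mb, cal, resp, cfg)
  expect_gt(cor(psb$snv_intensity, target), 0.95)
})

test_that("swapping SNV before baseline removal changes the result", {
  instr <- tiny_instrument()
  cfg <- cohort_config(seed = 2)
  prof <- default_tissue_profiles()$normal_benign
  ref <- synth_reference_frames(instr)
  peaks <- find_peaks(ref$calibration_frame)
  cal <- fit_calibration(peaks, ref$reference_wavenumbers, order = 1,
                         pixel_range = c(1, instr$n_pixels))
  resp <- estimate_response(ref$broadband_frame, ref$certified_shape)
  set.seed(3)
  m <- simulate_measurement(prof, instr, cfg)
  a <- preprocess_measurement(m, cal, resp, cfg)
  b <- preprocess_measurement(m, cal, resp, cfg,
                              preprocess_params(snv_before_baseline = TRUE))
  expect_gt(max(abs(a$snv_intensity - b$snv_intensity)), 0.01)
})

test_that("stage failures carry the stage name", {
  instr <- tiny_instrument()
  cfg <- cohort_config(seed = 2)
  prof <- default_tissue_profiles()$normal_benign
  set.seed(1)
  m <- simulate_measurement(prof, instr, cfg)
  bad_cal <- structure(list(coefficients = c(2000, -1), order = 1),
                       class = "calibration_fit")
  expect_error(preprocess_measurement(m, bad_cal, rep(1, 128), cfg),
               "\\[resample\\]")
})
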