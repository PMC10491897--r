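test_that("pure spectra follow the band model: identity, maxima, linearity", {
  axis <- raman_axis()
  expect_equal(synth_pure_spectrum(list(), axis), numeric(length(axis)))

  one <- synth_pure_spectrum(list(band_spec(1657, 20, 1)), axis)
  expect_equal(one[axis == 1657], 1.0)
  expect_true(all(one >= 0) && all(one <= 1))

  b1 <- list(band_spec(900, 15, 2))
  b2 <- list(band_spec(1500, 25, 3))
  expect_equal(synth_pure_spectrum(c(b1, b2), axis),
               synth_pure_spectrum(b1, axis) + synth_pure_spectrum(b2, axis))

  expect_error(synth_pure_spectrum(list(band_spec(250, 10, 1)), axis), "250")
})

test_that("background is smooth, nonnegative and obeys the trivial limits", {
  axis <- raman_axis()
  expect_equal(synth_background(axis, amplitude = 0), numeric(length(axis)))
  flat <- synth_background(axis, amplitude = 3.5, decay_scale = Inf,
                           bumps = list())
  expect_equal(flat, rep(3.5, length(axis)))
  expect_error(synth_background(axis, amplitude = -1), "amplitude")

  # curvature of the default background stays below that of a 20 cm^-1
  # Lorentzian of equal amplitude
  bg <- synth_background(axis, amplitude = 1)
  lor <- synth_pure_spectrum(list(band_spec(1250, 20, 1)), axis)
  curv <- function(y) max(abs(diff(diff(y))))
  expect_lt(curv(bg), curv(lor))
  expect_true(all(bg >= 0))
})

test_that("measurement simulation matches the detection model", {
  instr <- tiny_instrument(dark_rate = 0,
                           response_curve = rep(1, 128),
                           background_scale = 0)
  cfg <- cohort_config(seed = 1)
  prof <- default_tissue_profiles()$normal_benign
  m <- simulate_measurement(prof, instr, cfg, noise = FALSE,
                            background_amplitude = 0)
  pure <- synth_pure_spectrum(prof, instr$wavenumbers)
  for (j in seq_len(ncol(m$repeat_frames))) {
    expect_equal(m$repeat_frames[, j], pure * cfg$integration_time_s)
  }
  expect_equal(m$dark_frame, numeric(128))
})

test_that("dark frame counts average to dark_rate x integration time", {
  instr <- tiny_instrument(dark_rate = 300, read_noise_sd = 3)
  cfg <- cohort_config(seed = 1, n_repeats = 2)
  prof <- tissue_profile("normal_benign", list(band_spec(1000, 20, 0)))
  set.seed(7)
  n_frames <- 1e4
  mean_dark <- instr$dark_rate * cfg$dark_integration_time_s
  acc <- mean(replicate(n_frames, {
    mean(ramanlung:::sample_counts(rep(mean_dark, instr$n_pixels), 1,
                                   instr$read_noise_sd))
  }))
  expect_lt(abs(acc - mean_dark) / mean_dark, 0.01)
  # the dark frame produced by simulate_measurement uses the same sampler
  set.seed(7)
  m <- simulate_measurement(prof, instr, cfg, background_amplitude = 0)
  expect_lt(abs(mean(m$dark_frame) - mean_dark) / mean_dark, 0.15)
})

test_that("same seed gives bit-identical measurements", {
  instr <- tiny_instrument()
  cfg <- cohort_config(seed = 5)
  prof <- default_tissue_profiles()$cancer_necrosis
  set.seed(123)
  m1 <- simulate_measurement(prof, instr, cfg)
  set.seed(123)
  m2 <- simulate_measurement(prof, instr, cfg)
  expect_identical(m1, m2)
})

test_that("cohorts respect counts, quality flags and determinism", {
  instr <- tiny_instrument()
  cfg <- cohort_config(seed = 3)
  co <- generate_cohort(cfg, instrument = instr)
  expect_lte(length(co$measurements), 200)
  labs <- vapply(co$measurements, `[[`, character(1), "label")
  expect_gt(sum(labs == "normal_benign"), 90)
  expect_gt(sum(labs == "cancer_necrosis"), 85)

  co0 <- generate_cohort(cohort_config(seed = 3, low_quality_fraction = 0),
                         instrument = instr)
  expect_true(all(vapply(co0$measurements, `[[`, character(1), "quality") ==
                    "normal"))

  co2 <- generate_cohort(cfg, instrument = instr)
  expect_identical(serialize(co, NULL), serialize(co2, NULL))
})

test_that("degraded fraction matches the configured rate across seeds", {
  instr <- tiny_instrument()
  fracs <- vapply(1:50, function(s) {
    co <- generate_cohort(cohort_config(seed = s, n_repeats = 1),
                          instrument = instr)
    mean(vapply(co$measurements, `[[`, character(1), "quality") == "degraded")
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.33), 0.02)
})

test_that("class contrast lives only at the amide I and tyrosine bands", {
  axis <- raman_axis()
  profs <- default_tissue_profiles()
  diff <- synth_pure_spectrum(profs$cancer_necrosis, axis) -
    synth_pure_spectrum(profs$normal_benign, axis)
  expect_gt(diff[axis == 1657], 0)
  expect_gt(diff[axis == 852], 0)
  # away from the two marker bands only Lorentzian tails remain
  far <- abs(axis - 1657) > 100 & abs(axis - 852) > 100
  expect_lt(max(abs(diff[far])), 0.03 * max(diff))
})

test_that("degraded acquisitions have lower per-pixel SNR", {
  instr <- tiny_instrument()
  cfg <- cohort_config(seed = 1)
  prof <- default_tissue_profiles()$normal_benign
  frames_of <- function(quality) {
    set.seed(11)
    m <- simulate_measurement(prof, instr, cfg, quality = quality)
    m$repeat_frames
  }
  sd_norm <- apply(frames_of("normal"), 1, sd)
  sd_deg <- apply(frames_of("degraded"), 1, sd)
  expect_gt(mean(sd_deg > sd_norm), 0.97)
  expect_gt(median(sd_deg / sd_norm), 10)
})

test_that("reference frames encode calibration peaks and the response", {
  instr <- small_instrument()
  ref <- synth_reference_frames(instr)
  # each calibration peak's maximum pixel maps back to its reference line
  # within half a pixel spacing
  for (p in ref$reference_wavenumbers) {
    i <- which.max(ref$calibration_frame *
                     (abs(instr$wavenumbers - p) < 20))
    expect_lt(abs(instr$wavenumbers[i] - p), diff(instr$wavenumbers[i + 0:1]))
  }
  flat <- small_instrument(response_curve = rep(1, 512))
  ref1 <- synth_reference_frames(flat)
  expect_equal(ref1$broadband_frame, ref1$certified_shape)

  five <- synth_reference_frames(instr,
                                 reference_peaks = c(900, 1100, 1300, 1500,
                                                     1650))
  y <- five$calibration_frame
  n <- length(y)
  maxima <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n] &
                    y[2:(n - 1)] > max(y) / 2) + 1L
  expect_length(maxima, 5)

  expect_error(synth_reference_frames(instr, reference_peaks = numeric(0)),
               "non-empty")
})
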