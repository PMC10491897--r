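# Spectral preprocessing chain: repeat averaging, dark-count subtraction,
# instrument response correction, wavenumber calibration/resampling onto the
# common fingerprint axis, BubbleFill baseline removal, SNV normalization.

#' Average repeat frames
#'
#' @param frames pixels x repeats matrix, or list of equal-length vectors.
#' @return elementwise arithmetic mean vector.
#' @export
average_repeats <- function(frames) {
  if (is.list(frames)) {
    lens <- lengths(frames)
    if (!length(frames)) stop("at least one frame required")
    if (length(unique(lens)) != 1L) stop("frames have ragged lengths")
    frames <- matrix(unlist(frames), nrow = lens[1])
  }
  if (!is.matrix(frames)) frames <- matrix(frames, ncol = 1)
  rowMeans(frames)
}

#' Subtract a dark frame with integration-time scaling
#'
#' Dark counts are proportional to integration time, so a dark frame acquired
#' over `dark_time` is rescaled by `frame_time / dark_time` before
#' subtraction. Values may go slightly negative; they are deliberately not
#' clipped (clipping would bias the subsequent baseline fit).
#'
#' @param frame averaged intensity vector.
#' @param dark_frame dark-count vector (same length).
#' @param frame_time,dark_time integration times in seconds (> 0).
#' @return corrected intensity vector.
#' @export
subtract_dark <- function(frame, dark_frame, frame_time, dark_time) {
  if (length(frame) != length(dark_frame)) stop("frame lengths differ")
  if (frame_time <= 0 || dark_time <= 0) stop("integration times must be > 0")
  frame - dark_frame * (frame_time / dark_time)
}

#' Locate peaks in a reference frame
#'
#' Simple local-maximum scan with parabolic sub-pixel refinement, used to find
#' the calibration-standard lines in a pseudo-acetaminophen frame.
#'
#' @param y intensity vector.
#' @param min_height_frac peaks below this fraction of the global maximum are
#'   ignored.
#' @param min_distance minimum separation between reported peaks (pixels).
#' @return numeric vector of (sub-pixel) peak positions, sorted.
#' @export
find_peaks <- function(y, min_height_frac = 0.3, min_distance = 5) {
  n <- length(y)
  thr <- min_height_frac * max(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n] &
                 y[2:(n - 1)] >= thr) + 1L
  if (!length(idx)) return(numeric(0))
  # enforce minimum distance, keeping the taller peak
  keep <- idx[order(-y[idx])]
  sel <- numeric(0)
  for (i in keep) {
    if (!length(sel) || all(abs(sel - i) >= min_distance)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  vapply(sel, function(i) {
    # parabola through (i-1, i, i+1)
    a <- y[i - 1]; b <- y[i]; c <- y[i + 1]
    den <- a - 2 * b + c
    if (den == 0) return(as.numeric(i))
    i + 0.5 * (a - c) / den
  }, numeric(1))
}

#' Fit the pixel-to-wavenumber calibration polynomial
#'
#' Least-squares polynomial mapping detected reference-peak pixel positions to
#' their certified wavenumbers.
#'
#' @param peak_pixels sorted peak positions (pixels, sub-pixel allowed).
#' @param reference_wavenumbers certified wavenumbers (cm^-1), same length,
#'   sorted.
#' @param order polynomial order; needs at least `order + 1` peaks.
#' @param pixel_range range over which the fitted map must be strictly
#'   increasing (default: the peak range; pass `c(1, n_pixels)` for the whole
#'   detector).
#' @return object of class `calibration_fit` with `coefficients` (ascending
#'   powers), `order`, `residuals` (cm^-1) and `rms_residual`.
#' @export
fit_calibration <- function(peak_pixels, reference_wavenumbers, order = 2,
                            pixel_range = range(peak_pixels)) {
  if (length(peak_pixels) != length(reference_wavenumbers)) {
    stop("peak and reference lists must have the same length")
  }
  if (length(peak_pixels) < order + 1) {
    stop(sprintf("calibration underdetermined: %d peaks for order %d",
                 length(peak_pixels), order))
  }
  if (is.unsorted(peak_pixels) || is.unsorted(reference_wavenumbers)) {
    stop("peak_pixels and reference_wavenumbers must be sorted ascending")
  }
  X <- outer(peak_pixels, 0:order, `^`)
  coefs <- qr.solve(X, reference_wavenumbers)
  fitted <- drop(X %*% coefs)
  res <- reference_wavenumbers - fitted
  grid <- seq(pixel_range[1], pixel_range[2], length.out = 512)
  if (any(diff(polyval_asc(coefs, grid)) <= 0)) {
    stop("fitted calibration map is not strictly increasing over the pixel range")
  }
  structure(list(coefficients = coefs, order = order, residuals = res,
                 rms_residual = sqrt(mean(res^2))),
            class = "calibration_fit")
}

#' Apply a calibration fit to pixel indices
#' @param fit a [fit_calibration()] result.
#' @param pixels pixel indices.
#' @return wavenumbers (cm^-1).
#' @export
predict_calibration <- function(fit, pixels) {
  polyval_asc(fit$coefficients, pixels)
}

#' Estimate the instrument response from a broadband standard
#'
#' Per-pixel ratio of the measured reference frame to the certified shape of
#' the standard, smoothed. The absolute scale of the factors carries the
#' acquisition gain of the reference measurement; it cancels later under SNV
#' normalization.
#'
#' @param measured_reference measured broadband frame.
#' @param certified_shape certified emission shape (> 0 everywhere).
#' @param smooth_window Savitzky-Golay window (points, odd); `0` disables
#'   smoothing.
#' @return object of class `response_curve`: list with positive `factors` and
#'   `smooth_window`.
#' @export
estimate_response <- function(measured_reference, certified_shape,
                              smooth_window = 31) {
  if (length(measured_reference) != length(certified_shape)) {
    stop("frame lengths differ")
  }
  if (any(certified_shape <= 0)) stop("certified_shape must be > 0 everywhere")
  ratio <- measured_reference / certified_shape
  if (smooth_window > 2) {
    if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1
    ratio <- signal::sgolayfilt(ratio, p = 2, n = smooth_window)
  }
  if (any(ratio <= 0)) {
    stop("nonpositive response factors after smoothing")
  }
  structure(list(factors = ratio, smooth_window = smooth_window),
            class = "response_curve")
}

#' Divide out the instrument response
#' @param spectrum intensity vector.
#' @param response a [estimate_response()] result or a bare positive vector.
#' @return corrected intensity vector.
#' @export
correct_response <- function(spectrum, response) {
  factors <- if (inherits(response, "response_curve")) response$factors else response
  if (length(spectrum) != length(factors)) stop("length mismatch")
  spectrum / factors
}

#' Resample a spectrum onto the common fingerprint axis
#'
#' Linear interpolation from the calibrated per-pixel wavenumbers onto the
#' regular 800--1700 cm^-1 grid.
#'
#' @param intensity intensity vector on `wn_in`.
#' @param wn_in calibrated wavenumbers (strictly increasing).
#' @param axis_out target axis (default [raman_axis()]).
#' @return intensity vector on `axis_out`.
#' @export
resample_spectrum <- function(intensity, wn_in, axis_out = raman_axis()) {
  if (axis_out[1] < wn_in[1] || axis_out[length(axis_out)] > wn_in[length(wn_in)]) {
    stop("target axis extends beyond the calibrated wavenumber range")
  }
  stats::approx(wn_in, intensity, xout = axis_out, method = "linear")$y
}

#' Standard normal variate normalization
#'
#' `(x - mean(x)) / sd(x)` with the population (1/N) standard deviation, so
#' the output has mean 0 and population sd exactly 1. Invariant under positive
#' affine transforms of the input and idempotent.
#'
#' @param spectrum intensity vector with nonzero spread.
#' @return unitless SNV spectrum.
#' @export
snv <- function(spectrum) {
  m <- mean(spectrum)
  s <- sqrt(mean((spectrum - m)^2))
  if (!is.finite(s) || s == 0) {
    stop("constant spectrum cannot be SNV-normalized (zero variance)")
  }
  (spectrum - m) / s
}

#' Preprocessing parameters
#'
#' @param min_bubble_width BubbleFill bubble-width cutoff (cm^-1).
#' @param axis_step common axis step (cm^-1).
#' @param response_smooth_window window for [estimate_response()].
#' @param snv_before_baseline if `TRUE`, swap the last two stages (SNV before
#'   BubbleFill). Non-standard; provided to demonstrate that stage order
#'   matters.
#' @return list of parameters.
#' @export
preprocess_params <- function(min_bubble_width = 100, axis_step = 1,
                              response_smooth_window = 31,
                              snv_before_baseline = FALSE) {
  list(min_bubble_width = min_bubble_width, axis_step = axis_step,
       response_smooth_window = response_smooth_window,
       snv_before_baseline = snv_before_baseline)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Preprocess one measurement
#'
#' Applies, in order: repeat averaging, scaled dark subtraction, instrument
#' response correction, wavenumber calibration and resampling onto the common
#' axis, BubbleFill baseline removal, SNV normalization. Errors are re-thrown
#' with the failing stage name attached.
#'
#' @param measurement a [simulate_measurement()] result (or any object with
#'   `repeat_frames`, `dark_frame`, `patient_id`, `label`, `category`).
#' @param calibration a [fit_calibration()] result.
#' @param response a [estimate_response()] result (or positive vector).
#' @param config acquisition config supplying the two integration times.
#' @param params a [preprocess_params()] list.
#' @return object of class `processed_spectrum`: `axis`, `snv_intensity`,
#'   `raman_before_snv`, `baseline`, `qf` (`NA` until [compute_quality()]),
#'   `patient_id`, `label`, `category`, `quality`, `provenance`.
#' @export
preprocess_measurement <- function(measurement, calibration, response,
                                   config, params = preprocess_params()) {
  avg <- with_stage("average_repeats", average_repeats(measurement$repeat_frames))
  dk <- with_stage("subtract_dark",
                   subtract_dark(avg, measurement$dark_frame,
                                 config$integration_time_s,
                                 config$dark_integration_time_s))
  rc <- with_stage("correct_response", correct_response(dk, response))
  axis_out <- raman_axis(params$axis_step)
  wn <- predict_calibration(calibration, seq_along(rc))
  rs <- with_stage("resample", resample_spectrum(rc, wn, axis_out))
  if (isTRUE(params$snv_before_baseline)) {
    sv0 <- with_stage("snv", snv(rs))
    bf <- with_stage("bubblefill",
                     bubblefill(sv0, axis_out, params$min_bubble_width))
    sn <- bf$raman
    prov <- c("average_repeats", "subtract_dark", "correct_response",
              "resample", "snv", "bubblefill")
  } else {
    bf <- with_stage("bubblefill",
                     bubblefill(rs, axis_out, params$min_bubble_width))
    sn <- with_stage("snv", snv(bf$raman))
    prov <- c("average_repeats", "subtract_dark", "correct_response",
              "resample", "bubblefill", "snv")
  }
  structure(list(axis = axis_out, snv_intensity = sn,
                 raman_before_snv = bf$raman, baseline = bf$baseline,
                 resampled = rs, qf = NA_real_,
                 patient_id = measurement$patient_id,
                 label = measurement$label, category = measurement$category,
                 quality = if (!is.null(measurement$quality)) measurement$quality else NA_character_,
                 provenance = prov),
            class = "processed_spectrum")
}

#' Preprocess a whole cohort
#'
#' Fits the wavenumber calibration from the cohort's calibration frame,
#' estimates the instrument response from its broadband reference frame, then
#' processes every measurement onto the common axis and computes each
#' spectrum's quality factor.
#'
#' @param cohort a [generate_cohort()] result (or anything with
#'   `measurements`, `reference`, `config`).
#' @param params a [preprocess_params()] list.
#' @param qf_window,qf_order quality-factor smoothing parameters, see
#'   [quality_factor()].
#' @return a [raman_dataset()].
#' @export
preprocess_cohort <- function(cohort, params = preprocess_params(),
                              qf_window = 9, qf_order = 1) {
  ref <- cohort$reference
  peaks <- with_stage("calibration",
                      find_peaks(ref$calibration_frame, min_height_frac = 0.3))
  if (length(peaks) != length(ref$reference_wavenumbers)) {
    stop(sprintf("[calibration] found %d peaks for %d reference lines",
                 length(peaks), length(ref$reference_wavenumbers)))
  }
  n_pix <- length(ref$calibration_frame)
  calibration <- with_stage("calibration",
                            fit_calibration(peaks, ref$reference_wavenumbers,
                                            order = 2,
                                            pixel_range = c(1, n_pix)))
  response <- with_stage("response",
                         estimate_response(ref$broadband_frame,
                                           ref$certified_shape,
                                           params$response_smooth_window))
  spectra <- lapply(cohort$measurements, preprocess_measurement,
                    calibration = calibration, response = response,
                    config = cohort$config, params = params)
  ds <- raman_dataset(spectra)
  ds$calibration <- calibration
  ds$response <- response
  compute_quality(ds, smooth_window = qf_window, poly_order = qf_order)
}
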