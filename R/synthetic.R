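# Synthetic single-point Raman cohort generator.
#
# Emulates the acquisition protocol of a 10-patient lung study: per measurement,
# 10 repeat CCD frames at 75 ms plus a 50 ms laser-off dark frame, a fingerprint
# axis reached through a mildly quadratic pixel-to-wavenumber map, a wavelength
# dependent instrument response, tissue Raman bands riding on a fluorescence
# background that dominates the Raman signal, and a tunable fraction of
# low-quality (noisy) measurements.

#' Common fingerprint wavenumber axis
#'
#' The 800--1700 cm^-1 fingerprint region sampled on a regular grid. All
#' processed spectra live on this axis (901 points at the default 1 cm^-1 step).
#'
#' @param step grid step in cm^-1.
#' @return numeric vector of wavenumbers.
#' @export
raman_axis <- function(step = 1) {
  seq(800, 1700, by = step)
}

#' Describe a single Raman band
#'
#' @param center band center (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), must be positive.
#' @param amplitude peak amplitude at the band center (counts/s in the
#'   generator's internal units), must be nonnegative.
#' @param lineshape `"lorentzian"` (default, the physically standard shape for
#'   Raman bands) or `"gaussian"`.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(center, fwhm, amplitude,
                      lineshape = c("lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center)) {
    stop("band center must be a single finite number")
  }
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0) {
    stop("band fwhm must be > 0")
  }
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0) {
    stop("band amplitude must be >= 0")
  }
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 lineshape = lineshape),
            class = "band_spec")
}

# Evaluate one band's lineshape on an axis; unit peak amplitude times `amplitude`.
eval_band <- function(band, axis) {
  d <- axis - band$center
  if (band$lineshape == "lorentzian") {
    g <- band$fwhm / 2
    band$amplitude * g^2 / (d^2 + g^2)
  } else {
    band$amplitude * exp(-4 * log(2) * d^2 / band$fwhm^2)
  }
}

#' Describe the band content of a tissue class
#'
#' @param label binary class label, `"cancer_necrosis"` or `"normal_benign"`.
#' @param bands list of [band_spec()] objects.
#' @param category fine-grained histology category (assigned per measurement by
#'   [generate_cohort()]; `NA` for a class-level profile).
#' @param band_cv named numeric: coefficients of variation of band amplitudes.
#'   `patient` is the total per-band log-normal CV across patients (shared by
#'   both classes within a patient); `patient_common` is the part of it that
#'   is common-mode across all bands (overall tissue scattering/composition
#'   scale, cancelled later by SNV normalization), the remainder being
#'   band-specific; `measurement` is the independent per-band CV across
#'   repeated measurements.
#' @return object of class `tissue_profile`.
#' @export
tissue_profile <- function(label = c("normal_benign", "cancer_necrosis"),
                           bands,
                           category = NA_character_,
                           band_cv = c(patient = 0.15, patient_common = 0.145,
                                       measurement = 0.05)) {
  label <- match.arg(label)
  if (!length(bands) || !all(vapply(bands, inherits, logical(1), "band_spec"))) {
    stop("bands must be a non-empty list of band_spec objects")
  }
  if (any(band_cv < 0)) stop("band_cv values must be >= 0")
  structure(list(label = label, category = category, bands = bands,
                 band_cv = band_cv),
            class = "tissue_profile")
}

#' Default tissue profiles for the two classes
#'
#' The seven marker bands typical of lung tissue (tyrosine ring breathing at
#' 852, phenylalanine C-H bending at 1037, blood-plasma phosphate at 1080,
#' carotenoids at 1156, CH2/CH3 deformation at 1449, tryptophan/hemoglobin at
#' 1549, and the protein amide I band at 1657 cm^-1), plus a set of minor
#' shared bands (proline 935, the ubiquitous phenylalanine ring-breathing peak
#' at 1004, amide III 1260, lipid CH2 twist 1305, CH deformation 1340,
#' aromatic C=C 1605) that fill out a realistic crowded fingerprint. The
#' cancer/necrosis class differs from normal/benign only by amplitude shifts
#' at the amide I and tyrosine bands (higher in cancer); all other bands are
#' shared.
#'
#' @param effect_1657 relative amplitude increase of the amide I band in the
#'   cancer class (default +30%).
#' @param effect_852 relative amplitude increase of the tyrosine band (default
#'   +15%).
#' @param band_cv passed to [tissue_profile()].
#' @return named list with elements `normal_benign` and `cancer_necrosis`.
#' @export
default_tissue_profiles <- function(effect_1657 = 0.30, effect_852 = 0.15,
                                    band_cv = c(patient = 0.15,
                                                patient_common = 0.145,
                                                measurement = 0.05)) {
  base <- data.frame(
    center = c(852, 935, 1004, 1037, 1080, 1156, 1260, 1305, 1340,
               1449, 1549, 1605, 1657),
    fwhm = c(12, 18, 10, 16, 20, 18, 28, 22, 24, 24, 22, 14, 28),
    amplitude = 8 * c(3000, 1200, 3000, 1400, 1600, 1200, 2200, 2600, 1600,
                      3600, 1000, 1000, 2000)
  )
  mk <- function(amps) {
    lapply(seq_len(nrow(base)), function(i) {
      band_spec(base$center[i], base$fwhm[i], amps[i])
    })
  }
  cancer_amps <- base$amplitude
  cancer_amps[base$center == 1657] <- cancer_amps[base$center == 1657] * (1 + effect_1657)
  cancer_amps[base$center == 852] <- cancer_amps[base$center == 852] * (1 + effect_852)
  list(
    normal_benign = tissue_profile("normal_benign", mk(base$amplitude),
                                   band_cv = band_cv),
    cancer_necrosis = tissue_profile("cancer_necrosis", mk(cancer_amps),
                                     band_cv = band_cv)
  )
}

#' Synthetic instrument model
#'
#' @param n_pixels number of CCD pixels.
#' @param pixel_to_wavenumber coefficients `c(c0, c1, c2, ...)` of the true
#'   pixel-index -> wavenumber polynomial (strictly increasing over the pixel
#'   range; the gentle default quadratic makes calibration fitting nontrivial).
#' @param response_curve per-pixel multiplicative sensitivity (strictly
#'   positive); default is a smooth bell-shaped curve.
#' @param dark_rate dark counts per second per pixel.
#' @param read_noise_sd CCD read noise standard deviation (counts per frame).
#' @param background_scale ratio of the fluorescence background amplitude to
#'   the largest Raman band amplitude. The study regime has fluorescence
#'   dominating the Raman signal; this is exposed as a parameter because no
#'   measured value is available.
#' @return object of class `instrument_model`.
#' @export
instrument_model <- function(n_pixels = 1024,
                             pixel_to_wavenumber = c(794.2, 0.80, 9e-5),
                             response_curve = NULL,
                             dark_rate = 300,
                             read_noise_sd = 3,
                             background_scale = 5) {
  p <- seq_len(n_pixels)
  wn <- polyval_asc(pixel_to_wavenumber, p)
  if (any(diff(wn) <= 0)) {
    stop("pixel_to_wavenumber must be strictly increasing over the pixel range")
  }
  if (is.null(response_curve)) {
    response_curve <- 0.7 + 0.6 * exp(-((p - 420) / 360)^2)
  }
  if (length(response_curve) != n_pixels || any(response_curve <= 0)) {
    stop("response_curve must be strictly positive with one value per pixel")
  }
  structure(list(n_pixels = n_pixels,
                 pixel_to_wavenumber = pixel_to_wavenumber,
                 wavenumbers = wn,
                 response_curve = response_curve,
                 dark_rate = dark_rate,
                 read_noise_sd = read_noise_sd,
                 background_scale = background_scale),
            class = "instrument_model")
}

# Evaluate polynomial with ascending-order coefficients c0 + c1*x + c2*x^2 ...
polyval_asc <- function(coefs, x) {
  out <- numeric(length(x))
  for (i in seq_along(coefs)) out <- out + coefs[i] * x^(i - 1)
  out
}

#' Cohort acquisition configuration
#'
#' Defaults mirror the acquisition protocol of the motivating study: 10
#' patients, up to 10 measurements per class per patient, 10 repeat frames per
#' measurement at 75 ms integration, a 50 ms dark frame, and roughly a third of
#' measurements of low spectral quality.
#'
#' @param n_patients number of patients.
#' @param max_measurements_per_class_per_patient per-class cap per patient.
#' @param n_repeats repeat frames per measurement.
#' @param integration_time_s frame integration time (seconds).
#' @param dark_integration_time_s dark frame integration time (seconds).
#' @param low_quality_fraction proportion of measurements acquired in a
#'   degraded (noisy) condition.
#' @param low_quality_noise_multiplier factor (> 1) applied to both shot and
#'   read noise of degraded measurements.
#' @param seed integer seed controlling all cohort randomness.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 10,
                          max_measurements_per_class_per_patient = 10,
                          n_repeats = 10,
                          integration_time_s = 0.075,
                          dark_integration_time_s = 0.050,
                          low_quality_fraction = 0.33,
                          low_quality_noise_multiplier = 120,
                          seed = 1L) {
  counts <- c(n_patients, max_measurements_per_class_per_patient, n_repeats)
  if (any(counts < 1)) stop("counts must be >= 1")
  if (low_quality_fraction < 0 || low_quality_fraction > 1) {
    stop("low_quality_fraction must be in [0, 1]")
  }
  if (low_quality_noise_multiplier <= 1) {
    stop("low_quality_noise_multiplier must be > 1")
  }
  if (integration_time_s <= 0 || dark_integration_time_s <= 0) {
    stop("integration times must be > 0")
  }
  structure(list(n_patients = as.integer(n_patients),
                 max_measurements_per_class_per_patient =
                   as.integer(max_measurements_per_class_per_patient),
                 n_repeats = as.integer(n_repeats),
                 integration_time_s = integration_time_s,
                 dark_integration_time_s = dark_integration_time_s,
                 low_quality_fraction = low_quality_fraction,
                 low_quality_noise_multiplier = low_quality_noise_multiplier,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Noise-free pure Raman spectrum of a tissue profile
#'
#' Sum over bands of the chosen lineshape, evaluated on `axis`.
#'
#' @param profile a `tissue_profile`, or a list of [band_spec()] objects (an
#'   empty list yields the all-zero spectrum).
#' @param axis sorted ascending wavenumber vector.
#' @param band_factors optional multiplicative factor per band (patient or
#'   measurement level variability).
#' @return intensity vector, same length as `axis`.
#' @export
synth_pure_spectrum <- function(profile, axis, band_factors = NULL) {
  bands <- if (inherits(profile, "tissue_profile")) profile$bands else profile
  if (is.unsorted(axis, strictly = TRUE)) {
    stop("axis must be sorted strictly ascending")
  }
  out <- numeric(length(axis))
  if (!length(bands)) return(out)
  if (is.null(band_factors)) band_factors <- rep(1, length(bands))
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    if (b$center < axis[1] || b$center > axis[length(axis)]) {
      stop(sprintf("band center %.1f cm^-1 lies outside the axis range [%.1f, %.1f]",
                   b$center, axis[1], axis[length(axis)]))
    }
    b$amplitude <- b$amplitude * band_factors[i]
    out <- out + eval_band(b, axis)
  }
  out
}

#' Smooth fluorescence-like background
#'
#' A nonnegative, monotone-decaying exponential envelope plus broad Gaussian
#' bumps; contains no structure narrower than ~200 cm^-1, i.e. far smoother
#' than any Raman band.
#'
#' @param axis wavenumber vector.
#' @param amplitude peak amplitude (>= 0). `amplitude = 0` yields zeros.
#' @param decay_scale e-folding scale of the decaying envelope (cm^-1); `Inf`
#'   with no bumps gives a flat background.
#' @param bumps list of `c(center, fwhm, relative_amplitude)` triples; bump
#'   fwhm should stay >= 200 cm^-1 to keep the background smooth.
#' @return intensity vector.
#' @export
synth_background <- function(axis, amplitude = 1, decay_scale = 600,
                             bumps = list(c(1050, 260, 0.35),
                                          c(1430, 320, 0.25))) {
  if (amplitude < 0) stop("background amplitude must be >= 0")
  base <- exp(-(axis - axis[1]) / decay_scale)
  for (b in bumps) {
    base <- base + b[3] * exp(-4 * log(2) * (axis - b[1])^2 / b[2]^2)
  }
  out <- amplitude * base / max(base)
  pmax(out, 0)
}

# Sample detected counts around a mean: Poisson shot noise (exact when the mean
# is <= 20 counts, Gaussian variance-matched approximation above) plus Gaussian
# read noise; a degraded acquisition scales both noise terms.
sample_counts <- function(mean_counts, noise_multiplier, read_noise_sd) {
  n <- length(mean_counts)
  dev <- numeric(n)
  lo <- mean_counts <= 20
  if (any(lo)) dev[lo] <- stats::rpois(sum(lo), mean_counts[lo]) - mean_counts[lo]
  if (any(!lo)) dev[!lo] <- stats::rnorm(sum(!lo), 0, sqrt(mean_counts[!lo]))
  out <- mean_counts + noise_multiplier * dev +
    stats::rnorm(n, 0, noise_multiplier * read_noise_sd)
  pmax(out, 0)
}

#' Simulate one measurement (repeat frames + dark frame)
#'
#' Each repeat frame follows the detection model
#' `response * (pure_raman + background) * gain * t + dark_rate * t + noise`.
#' Ground-truth components are stored for pipeline verification.
#'
#' @param profile tissue profile of the interrogated site.
#' @param instrument an [instrument_model()].
#' @param config a [cohort_config()].
#' @param quality `"normal"` or `"degraded"`; degraded multiplies all noise by
#'   `config$low_quality_noise_multiplier`.
#' @param noise set `FALSE` for a fully deterministic (noise-free) measurement.
#' @param band_factors per-band multiplicative factors (patient x measurement
#'   variability); default all 1.
#' @param gain overall per-measurement intensity factor (laser power
#'   adjustment); removed later by SNV normalization.
#' @param background_amplitude fluorescence amplitude in counts/s; default
#'   `background_scale` times the largest band amplitude.
#' @return object of class `simulated_measurement` with fields
#'   `repeat_frames` (pixels x repeats matrix), `dark_frame`, `patient_id`,
#'   `label`, `category`, `quality` and `truth`.
#' @export
simulate_measurement <- function(profile, instrument, config,
                                 quality = c("normal", "degraded"),
                                 noise = TRUE, band_factors = NULL, gain = 1,
                                 background_amplitude = NULL) {
  quality <- match.arg(quality)
  wn <- instrument$wavenumbers
  pure <- synth_pure_spectrum(profile, wn, band_factors)
  if (is.null(background_amplitude)) {
    amps <- vapply(profile$bands, `[[`, numeric(1), "amplitude")
    background_amplitude <- instrument$background_scale * max(amps)
  }
  bg <- if (background_amplitude > 0) {
    synth_background(wn, amplitude = background_amplitude)
  } else {
    numeric(length(wn))
  }
  t_f <- config$integration_time_s
  t_d <- config$dark_integration_time_s
  mean_frame <- instrument$response_curve * (pure + bg) * gain * t_f +
    instrument$dark_rate * t_f
  mean_dark <- rep(instrument$dark_rate * t_d, instrument$n_pixels)
  mult <- if (quality == "degraded") config$low_quality_noise_multiplier else 1
  if (noise) {
    frames <- vapply(seq_len(config$n_repeats), function(i) {
      sample_counts(mean_frame, mult, instrument$read_noise_sd)
    }, numeric(instrument$n_pixels))
    dark <- sample_counts(mean_dark, mult, instrument$read_noise_sd)
  } else {
    frames <- matrix(mean_frame, nrow = instrument$n_pixels,
                     ncol = config$n_repeats)
    dark <- mean_dark
  }
  structure(list(repeat_frames = frames, dark_frame = dark,
                 patient_id = NA_character_, label = profile$label,
                 category = profile$category, quality = quality,
                 truth = list(pure_raman = pure, background = bg,
                              applied_response = instrument$response_curve,
                              noise_level = mult, gain = gain,
                              wavenumbers = wn)),
            class = "simulated_measurement")
}

#' Generate a full synthetic cohort
#'
#' Patients carry random per-band log-normal amplitude offsets shared by both
#' classes (between-patient biochemistry); each measurement adds smaller
#' per-measurement band variability, a random overall gain (manual laser-power
#' adjustment), a variable fluorescence amplitude, and is degraded with
#' probability `low_quality_fraction`. Histology categories are drawn from the
#' class-conditional frequencies of the motivating cohort. The cancer class
#' loses a small fraction of measurements so the two classes are approximately
#' balanced (about 100 vs 97 at the defaults).
#'
#' @param config a [cohort_config()].
#' @param profiles named list from [default_tissue_profiles()].
#' @param instrument an [instrument_model()].
#' @return object of class `raman_cohort`: list with `measurements`,
#'   `reference` (pseudo-calibration and broadband reference frames),
#'   `instrument`, `profiles`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            profiles = default_tissue_profiles(),
                            instrument = instrument_model()) {
  set.seed(config$seed)
  cat_freq <- list(
    normal_benign = c(normal_lung = 24, emphysema_bronchiolitis = 76),
    cancer_necrosis = c(adenocarcinoma = 32, squamous_cell_carcinoma = 17,
                        nsclc_nos = 20, small_cell_carcinoma = 10,
                        necrosis = 18)
  )
  n_bands <- length(profiles[[1]]$bands)
  measurements <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", i)
    cv_p <- profiles[[1]]$band_cv[["patient"]]
    cv_c <- profiles[[1]]$band_cv[["patient_common"]]
    if (is.na(cv_c)) cv_c <- 0
    cv_b <- sqrt(max(cv_p^2 - cv_c^2, 0))
    # common-mode scale (cancelled by SNV) times band-specific factors
    pat_factors <- stats::rlnorm(1, meanlog = -cv_c^2 / 2, sdlog = cv_c) *
      stats::rlnorm(n_bands, meanlog = -cv_b^2 / 2, sdlog = cv_b)
    for (cls in c("normal_benign", "cancer_necrosis")) {
      prof <- profiles[[cls]]
      n_meas <- config$max_measurements_per_class_per_patient
      if (cls == "cancer_necrosis") {
        n_meas <- stats::rbinom(1, n_meas, 0.97)
      }
      if (n_meas == 0) next
      cv_m <- prof$band_cv[["measurement"]]
      for (m in seq_len(n_meas)) {
        meas_factors <- pat_factors *
          stats::rlnorm(n_bands, meanlog = -cv_m^2 / 2, sdlog = cv_m)
        gain <- stats::rlnorm(1, meanlog = -0.005, sdlog = 0.1)
        amps <- vapply(prof$bands, `[[`, numeric(1), "amplitude")
        bg_amp <- instrument$background_scale * max(amps) *
          stats::rlnorm(1, meanlog = -0.00125, sdlog = 0.05)
        quality <- if (stats::runif(1) < config$low_quality_fraction) {
          "degraded"
        } else {
          "normal"
        }
        prof$category <- sample(names(cat_freq[[cls]]), 1,
                                prob = cat_freq[[cls]])
        meas <- simulate_measurement(prof, instrument, config,
                                     quality = quality,
                                     band_factors = meas_factors, gain = gain,
                                     background_amplitude = bg_amp)
        meas$patient_id <- pid
        measurements[[length(measurements) + 1L]] <- meas
      }
    }
  }
  reference <- synth_reference_frames(instrument)
  structure(list(measurements = measurements, reference = reference,
                 instrument = instrument, profiles = profiles,
                 config = config),
            class = "raman_cohort")
}

#' @export
print.raman_cohort <- function(x, ...) {
  labs <- vapply(x$measurements, `[[`, character(1), "label")
  qual <- vapply(x$measurements, `[[`, character(1), "quality")
  cat("Synthetic Raman cohort\n")
  cat(sprintf("  patients: %d, measurements: %d (%d cancer/necrosis, %d normal/benign)\n",
              x$config$n_patients, length(labs),
              sum(labs == "cancer_necrosis"), sum(labs == "normal_benign")))
  cat(sprintf("  degraded acquisitions: %d (%.0f%%)\n", sum(qual == "degraded"),
              100 * mean(qual == "degraded")))
  invisible(x)
}

#' Default reference peak table for wavenumber calibration
#'
#' Synthetic calibration standard: a short table of sharp reference lines
#' inside the fingerprint region, patterned after the acetaminophen lines used
#' for Raman shift calibration. Shipped as package data so alternative
#' standards can be substituted.
#'
#' @return numeric vector of reference wavenumbers (cm^-1), sorted.
#' @export
default_reference_peaks <- function() {
  path <- system.file("extdata", "synthetic_calibration_peaks.csv",
                      package = "ramanlung", mustWork = TRUE)
  sort(utils::read.csv(path)$wavenumber)
}

#' Simulate calibration and broadband reference frames
#'
#' The calibration frame carries narrow peaks exactly at the reference
#' wavenumbers (mapped through the instrument's true pixel-to-wavenumber
#' polynomial); the broadband frame is the instrument response times a known
#' smooth certified shape, emulating a certified fluorescence standard.
#'
#' @param instrument an [instrument_model()].
#' @param reference_peaks sorted vector of reference wavenumbers; must be
#'   non-empty.
#' @param noise add Poisson/read noise to both frames.
#' @param peak_amplitude calibration peak amplitude (counts).
#' @return list with `calibration_frame`, `broadband_frame`,
#'   `certified_shape`, `reference_wavenumbers`, and (generator truth)
#'   `wavenumbers`.
#' @export
synth_reference_frames <- function(instrument,
                                   reference_peaks = default_reference_peaks(),
                                   noise = FALSE, peak_amplitude = 1000) {
  if (!length(reference_peaks)) stop("reference_peaks must be non-empty")
  if (is.unsorted(reference_peaks, strictly = TRUE)) {
    stop("reference_peaks must be sorted strictly ascending")
  }
  wn <- instrument$wavenumbers
  cal <- numeric(instrument$n_pixels)
  # instrument-limited line width: about three detector pixels
  line_fwhm <- max(2.5, 3 * stats::median(diff(wn)))
  for (p in reference_peaks) {
    if (p < wn[1] || p > wn[length(wn)]) {
      stop(sprintf("reference peak %.1f cm^-1 outside instrument range", p))
    }
    cal <- cal + peak_amplitude * exp(-4 * log(2) * (wn - p)^2 / line_fwhm^2)
  }
  certified <- 0.2 + exp(-((wn - 1250) / 450)^2)
  broadband <- instrument$response_curve * certified
  if (noise) {
    cal <- sample_counts(cal + 5, 1, instrument$read_noise_sd)
    broadband <- sample_counts(1000 * broadband, 1, instrument$read_noise_sd) / 1000
  }
  list(calibration_frame = cal, broadband_frame = broadband,
       certified_shape = certified, reference_wavenumbers = reference_peaks,
       wavenumbers = wn)
}
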