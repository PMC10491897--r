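# Fixtures built in code: small instruments and datasets so unit tests stay
# fast while the acceptance tests use the full default conditions.

# 128-pixel instrument with a linear pixel map covering the fingerprint axis
tiny_instrument <- function(...) {
  instrument_model(n_pixels = 128, pixel_to_wavenumber = c(787, 7.2), ...)
}

# Mid-sized instrument (quadratic map) for calibration-sensitive tests
small_instrument <- function(...) {
  instrument_model(n_pixels = 512, pixel_to_wavenumber = c(792, 1.6, 3.6e-4),
                   ...)
}

# Assemble a raman_dataset directly from an SNV matrix (bypasses the
# preprocessing chain; used to test quality/classify/evaluate in isolation).
fake_dataset <- function(snv, label, patient_id,
                         category = rep("normal_lung", nrow(snv)),
                         qf = rep(0.9, nrow(snv)),
                         quality = rep("normal", nrow(snv)),
                         axis = raman_axis()) {
  structure(list(axis = axis, snv = snv, raman = snv,
                 label = factor(label,
                                levels = c("cancer_necrosis", "normal_benign")),
                 category = category, patient_id = patient_id,
                 quality = quality, qf = qf),
            class = "raman_dataset")
}

# Toy feature-space cohort with class signal planted in named wavenumber
# columns: 10 patients x n_per spectra each, half of them cancer.
toy_feature_dataset <- function(seed = 1, n_patients = 10, n_per = 12,
                                p = 60, signal_cols = c(10, 40),
                                effect = 1.5, noise_sd = 1,
                                wavenumbers = seq(801, by = 2,
                                                  length.out = p)) {
  set.seed(seed)
  n <- n_patients * n_per
  x <- matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  label <- rep(rep(c("cancer_necrosis", "normal_benign"), each = n_per / 2),
               n_patients)
  patient <- rep(sprintf("P%02d", seq_len(n_patients)), each = n_per)
  x[label == "cancer_necrosis", signal_cols] <-
    x[label == "cancer_necrosis", signal_cols] + effect
  structure(list(x = x, wavenumber = wavenumbers,
                 label = factor(label,
                                levels = c("cancer_necrosis", "normal_benign")),
                 patient_id = patient,
                 category = rep("normal_lung", n), qf = rep(0.9, n)),
            class = "feature_matrix")
}

# SNV by hand for test inputs
snv0 <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

# Brute-force AUC oracle: count positive/negative score pairs, ties one half.
pairwise_auc <- function(scores, labels, positive = "cancer_necrosis") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
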