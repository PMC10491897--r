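# Evaluation: ROC/AUC with operating-point selection, random-label permutation
# control, univariate band statistics, and cohort tallies.

# AUC as the normalized Mann-Whitney pair count, ties counted one half;
# computed via average ranks (exactly equivalent).
auc_mw <- function(scores, labels, positive = "cancer_necrosis") {
  pos <- as.character(labels) == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes required for ROC analysis")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Empirical ROC curve and AUC
#'
#' The AUC is the normalized Mann-Whitney count over all positive/negative
#' score pairs with ties counted one half (identical to the trapezoidal area
#' under the empirical ROC). The operating point maximizes Youden's J
#' (sensitivity + specificity - 1); ties go to the higher sensitivity.
#'
#' @param scores decision scores (higher = more positive); `NA` scores (e.g.
#'   flagged CV folds) are dropped together with their labels.
#' @param labels binary labels.
#' @param positive positive class name.
#' @return object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `operating_point` (threshold, sensitivity,
#'   specificity, accuracy), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = "cancer_necrosis") {
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- as.character(labels)[keep]
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes required for ROC analysis")
  auc <- auc_mw(scores, labels, positive)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]
  acc <- (sens[best] * np + spec[best] * nn) / (np + nn)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc,
                 operating_point = list(threshold = thr[best],
                                        sensitivity = sens[best],
                                        specificity = spec[best],
                                        accuracy = acc),
                 n_pos = np, n_neg = nn),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf("ROC: AUC %.3f (%d positive, %d negative)\n", x$auc, x$n_pos,
              x$n_neg))
  cat(sprintf("operating point (Youden): sensitivity %.2f, specificity %.2f\n",
              op$sensitivity, op$specificity))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}

#' Random-label permutation null
#'
#' Re-runs the full leave-one-patient-out pipeline (inside-fold feature
#' selection and SVM training at fixed hyperparameters) on copies of the
#' dataset whose labels have been randomly reassigned, and summarizes the AUC
#' distribution. A mean near 0.5 shows the real model's performance is not an
#' artefact of overfitting.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param C,k fixed hyperparameters (typically the grid-search winners).
#' @param n_repeats number of permutations (>= 2; 100 by default).
#' @param seed integer seed for the label shuffles.
#' @param patient_level if `TRUE`, labels are shuffled within each patient
#'   block instead of across the whole dataset.
#' @return object of class `permutation_null`: `aucs`, `mean_auc`, `sd_auc`,
#'   `n_repeats`, `n_failed`, `seed`.
#' @export
permutation_null <- function(fm, C, k, n_repeats = 100, seed = 1L,
                             patient_level = FALSE) {
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  set.seed(seed)
  aucs <- rep(NA_real_, n_repeats)
  for (r in seq_len(n_repeats)) {
    fm2 <- fm
    if (patient_level) {
      for (pt in unique(fm$patient_id)) {
        i <- which(fm$patient_id == pt)
        fm2$label[i] <- sample(fm$label[i])
      }
    } else {
      fm2$label <- sample(fm$label)
    }
    aucs[r] <- tryCatch({
      cv <- lopo_cv(fm2, C = C, k = k)
      ok <- !is.na(cv$scores)
      auc_mw(cv$scores[ok], cv$label[ok])
    }, error = function(e) NA_real_)
  }
  ok <- !is.na(aucs)
  structure(list(aucs = aucs, mean_auc = mean(aucs[ok]),
                 sd_auc = stats::sd(aucs[ok]), n_repeats = n_repeats,
                 n_failed = sum(!ok), seed = seed,
                 patient_level = patient_level),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("Permutation null (N = %d): AUC %.2f +/- %.2f\n",
              x$n_repeats, x$mean_auc, x$sd_auc))
  if (x$n_failed) cat(sprintf("  (%d repeats failed and were excluded)\n",
                              x$n_failed))
  invisible(x)
}

#' Univariate band statistics
#'
#' Two-sided Wilcoxon rank-sum test per band comparing the two classes' SNV
#' intensity at the grid point nearest each band center. Significance stars
#' follow the convention `**` for p < 0.01 and `****` for p < 0.0001. A
#' Holm-adjusted column is reported alongside the raw p-values.
#'
#' @param ds a [raman_dataset()].
#' @param band_centers wavenumbers to test (default: the seven fingerprint
#'   bands of [default_tissue_profiles()]).
#' @return data.frame of class `band_stats`: band, wavenumber used, medians
#'   per class, W statistic, p-value, Holm-adjusted p, stars.
#' @export
band_statistics <- function(ds, band_centers = c(852, 1037, 1080, 1156,
                                                 1449, 1549, 1657)) {
  pos <- ds$label == "cancer_necrosis"
  if (sum(pos) < 2 || sum(!pos) < 2) {
    stop("band statistics need at least 2 spectra per class")
  }
  rows <- lapply(band_centers, function(b) {
    if (b < ds$axis[1] || b > ds$axis[length(ds$axis)]) {
      stop(sprintf("band %.1f cm^-1 lies outside the spectral axis", b))
    }
    j <- which.min(abs(ds$axis - b))
    xc <- ds$snv[pos, j]
    xn <- ds$snv[!pos, j]
    wt <- suppressWarnings(stats::wilcox.test(xc, xn, exact = FALSE))
    data.frame(band = b, wavenumber_used = ds$axis[j],
               median_cancer = stats::median(xc),
               median_normal = stats::median(xn),
               statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out$stars <- ifelse(out$p_value < 1e-4, "****",
                      ifelse(out$p_value < 0.01, "**", ""))
  class(out) <- c("band_stats", "data.frame")
  out
}

#' Published cohort sample tally
#'
#' Per-histology acquired sample counts of the motivating 10-patient lung
#' study, with the counts retained after quality-factor filtering. Used as the
#' reference input for [tally_cohort()].
#'
#' @return list with named integer vectors `acquired` and `retained`.
#' @export
lung_cohort_tally <- function() {
  list(
    acquired = c(normal_lung = 24L, emphysema_bronchiolitis = 76L,
                 adenocarcinoma = 32L, squamous_cell_carcinoma = 17L,
                 nsclc_nos = 20L, small_cell_carcinoma = 10L, necrosis = 18L),
    retained = c(normal_lung = 17L, emphysema_bronchiolitis = 53L,
                 adenocarcinoma = 16L, squamous_cell_carcinoma = 5L,
                 nsclc_nos = 15L, small_cell_carcinoma = 10L, necrosis = 16L)
  )
}

#' Cohort bookkeeping
#'
#' Pure arithmetic over per-category acquired (and optionally retained) sample
#' counts: class totals, grand total, cancer:normal ratio before/after
#' retention (rounded to 2 decimals) and the rejection percentage (nearest
#' integer percent).
#'
#' @param acquired named nonnegative integer vector of acquired counts per
#'   histology category.
#' @param retained optional matching vector of retained counts.
#' @param cancer_categories category names counted in the cancer/necrosis
#'   class; all others count as normal/benign.
#' @return object of class `cohort_tally`.
#' @export
tally_cohort <- function(acquired, retained = NULL,
                         cancer_categories = c("adenocarcinoma",
                                               "squamous_cell_carcinoma",
                                               "nsclc_nos",
                                               "small_cell_carcinoma",
                                               "necrosis")) {
  if (any(acquired < 0)) stop("negative counts")
  if (sum(acquired) == 0) stop("empty cohort (all counts zero)")
  is_cancer <- names(acquired) %in% cancer_categories
  out <- list(
    acquired = acquired,
    total = sum(acquired),
    cancer_total = sum(acquired[is_cancer]),
    normal_total = sum(acquired[!is_cancer]),
    class_ratio_before = round(sum(acquired[is_cancer]) /
                                 sum(acquired[!is_cancer]), 2)
  )
  if (!is.null(retained)) {
    if (any(retained < 0)) stop("negative counts")
    if (any(retained > acquired)) stop("retained counts exceed acquired counts")
    is_cancer_r <- names(retained) %in% cancer_categories
    out$retained <- retained
    out$retained_total <- sum(retained)
    out$retained_cancer <- sum(retained[is_cancer_r])
    out$retained_normal <- sum(retained[!is_cancer_r])
    out$class_ratio_after <- round(out$retained_cancer / out$retained_normal, 2)
    out$rejection_percent <- round(100 * (1 - sum(retained) / sum(acquired)))
  }
  structure(out, class = "cohort_tally")
}

#' @export
print.cohort_tally <- function(x, ...) {
  cat(sprintf("Cohort: %d spectra (%d cancer/necrosis, %d normal/benign), ratio %.2f\n",
              x$total, x$cancer_total, x$normal_total, x$class_ratio_before))
  if (!is.null(x$retained)) {
    cat(sprintf("Retained: %d (%d vs %d), ratio %.2f; rejection %d%%\n",
                x$retained_total, x$retained_cancer, x$retained_normal,
                x$class_ratio_after, x$rejection_percent))
  }
  invisible(x)
}
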