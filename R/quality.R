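# Quality factor (QF): a [0,1] score of how much of an SNV spectrum's energy
# sits at Raman-peak-like scales rather than pixel-to-pixel noise.

#' Quality factor of an SNV-normalized spectrum
#'
#' The spectrum is smoothed with a local-polynomial (Savitzky-Golay) filter of
#' the stated window; the QF is the population variance of the smoothed
#' spectrum, clipped to `[0, 1]`. Since the SNV input has unit variance this
#' is the fraction of spectral energy at scales wider than the window: values
#' near 1 indicate genuine tissue Raman structure, values near 0 indicate
#' stochastic noise. The score depends only on the smoothed variance, so it is
#' invariant under a sign flip of the spectrum.
#'
#' @param snv_spectrum SNV-normalized spectrum (mean ~ 0, population sd ~ 1;
#'   anything else is an error).
#' @param smooth_window smoothing window in cm^-1 (default 9).
#' @param poly_order local polynomial order (default 1, i.e. a local linear
#'   fit whose central-point weights equal a moving average).
#' @param axis_step axis step in cm^-1 used to convert the window to points.
#' @return QF in `[0, 1]`.
#' @export
quality_factor <- function(snv_spectrum, smooth_window = 9, poly_order = 1,
                           axis_step = 1) {
  m <- mean(snv_spectrum)
  s <- sqrt(mean((snv_spectrum - m)^2))
  if (abs(m) > 0.01 || abs(s - 1) > 0.01) {
    stop("quality_factor expects an SNV-normalized spectrum (mean 0, sd 1)")
  }
  npts <- max(3L, as.integer(round(smooth_window / axis_step)))
  if (npts %% 2L == 0L) npts <- npts + 1L
  sm <- signal::sgolayfilt(snv_spectrum, p = poly_order, n = npts)
  qf <- mean((sm - mean(sm))^2)
  min(max(qf, 0), 1)
}

#' Fill in quality factors for every spectrum of a dataset
#'
#' @param ds a [raman_dataset()].
#' @param smooth_window,poly_order,axis_step see [quality_factor()].
#' @return the dataset with its `qf` field populated.
#' @export
compute_quality <- function(ds, smooth_window = 9, poly_order = 1,
                            axis_step = 1) {
  ds$qf <- apply(ds$snv, 1, quality_factor, smooth_window = smooth_window,
                 poly_order = poly_order, axis_step = axis_step)
  ds
}

#' Split a dataset at a quality-factor threshold
#'
#' Spectra with QF strictly greater than the threshold are retained. The
#' summary reproduces the cohort bookkeeping: per-category retained counts and
#' the cancer:normal class ratio before and after the cut (rounded to 2
#' decimals for reporting).
#'
#' @param ds a [raman_dataset()] with quality factors computed.
#' @param threshold QF cutoff (default 0.4); strict inequality.
#' @return list with `retained`, `rejected` (datasets) and `summary`
#'   (class `quality_summary`).
#' @export
split_by_qf <- function(ds, threshold = 0.4) {
  n <- n_spectra(ds)
  if (!n) stop("empty dataset")
  if (any(is.na(ds$qf))) stop("quality factors missing; run compute_quality()")
  keep <- ds$qf > threshold
  retained <- ds[keep]
  rejected <- ds[!keep]
  ratio <- function(lab) {
    nn <- sum(lab == "normal_benign")
    if (nn == 0) return(NA_real_)
    round(sum(lab == "cancer_necrosis") / nn, 2)
  }
  summary <- structure(list(
    n_total = n,
    n_retained = sum(keep),
    n_rejected = sum(!keep),
    rejected_fraction = sum(!keep) / n,
    threshold = threshold,
    retained_by_category = table(factor(ds$category)[keep]),
    acquired_by_category = table(factor(ds$category)),
    class_ratio_before = ratio(ds$label),
    class_ratio_after = ratio(ds$label[keep])
  ), class = "quality_summary")
  list(retained = retained, rejected = rejected, summary = summary)
}

#' @export
print.quality_summary <- function(x, ...) {
  cat(sprintf("QF > %.2f: retained %d / %d spectra (%.0f%% rejected)\n",
              x$threshold, x$n_retained, x$n_total,
              100 * x$rejected_fraction))
  cat(sprintf("cancer:normal ratio %.2f before, %.2f after\n",
              x$class_ratio_before, x$class_ratio_after))
  invisible(x)
}
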