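# Labeled dataset container: processed spectra on the common axis with binary
# label, histology category, patient id and quality factor.

#' Assemble processed spectra into a labeled dataset
#'
#' @param spectra list of `processed_spectrum` objects on a common axis.
#' @return object of class `raman_dataset`: list with `axis`, `snv` (spectra x
#'   wavenumbers matrix), `raman` (pre-SNV residuals), `label` (factor with
#'   levels `cancer_necrosis`, `normal_benign`), `category`, `patient_id`,
#'   `quality`, `qf`.
#' @export
raman_dataset <- function(spectra) {
  if (!length(spectra)) stop("no spectra")
  axis <- spectra[[1]]$axis
  for (s in spectra) {
    if (!isTRUE(all.equal(s$axis, axis))) stop("spectra are not on a common axis")
  }
  snv_m <- do.call(rbind, lapply(spectra, `[[`, "snv_intensity"))
  raman_m <- do.call(rbind, lapply(spectra, `[[`, "raman_before_snv"))
  structure(list(
    axis = axis,
    snv = snv_m,
    raman = raman_m,
    label = factor(vapply(spectra, `[[`, character(1), "label"),
                   levels = c("cancer_necrosis", "normal_benign")),
    category = vapply(spectra, `[[`, character(1), "category"),
    patient_id = vapply(spectra, `[[`, character(1), "patient_id"),
    quality = vapply(spectra, function(s) {
      if (is.null(s$quality)) NA_character_ else s$quality
    }, character(1)),
    qf = vapply(spectra, `[[`, numeric(1), "qf")
  ), class = "raman_dataset")
}

#' Number of spectra in a dataset
#' @param ds a `raman_dataset`.
#' @return integer count.
#' @export
n_spectra <- function(ds) nrow(ds$snv)

#' Subset a dataset by spectrum index
#' @param x a `raman_dataset`.
#' @param i spectrum indices (integer or logical).
#' @param ... unused.
#' @export
`[.raman_dataset` <- function(x, i, ...) {
  out <- x
  out$snv <- x$snv[i, , drop = FALSE]
  out$raman <- x$raman[i, , drop = FALSE]
  for (f in c("label", "category", "patient_id", "quality", "qf")) {
    out[[f]] <- x[[f]][i]
  }
  out
}

#' @export
print.raman_dataset <- function(x, ...) {
  cat("Raman dataset:", n_spectra(x), "spectra x", length(x$axis),
      "wavenumbers\n")
  print(table(x$label))
  if (!all(is.na(x$qf))) {
    cat(sprintf("QF: median %.2f, range [%.2f, %.2f]\n",
                stats::median(x$qf), min(x$qf), max(x$qf)))
  }
  invisible(x)
}

#' Plot class-mean SNV spectra
#'
#' Mean +/- one standard deviation per class, the standard visual summary of a
#' processed cohort.
#'
#' @param x a `raman_dataset`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.raman_dataset <- function(x, ...) {
  cls <- levels(x$label)
  cols <- c(cancer_necrosis = "firebrick", normal_benign = "steelblue")
  mu <- lapply(cls, function(cl) colMeans(x$snv[x$label == cl, , drop = FALSE]))
  sd_ <- lapply(cls, function(cl) apply(x$snv[x$label == cl, , drop = FALSE], 2, stats::sd))
  ylim <- range(unlist(Map(function(m, s) c(m - s, m + s), mu, sd_)))
  graphics::plot(x$axis, mu[[1]], type = "n", ylim = ylim,
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "SNV intensity", ...)
  for (k in seq_along(cls)) {
    graphics::polygon(c(x$axis, rev(x$axis)),
                      c(mu[[k]] - sd_[[k]], rev(mu[[k]] + sd_[[k]])),
                      col = grDevices::adjustcolor(cols[cls[k]], alpha.f = 0.2),
                      border = NA)
    graphics::lines(x$axis, mu[[k]], col = cols[cls[k]], lwd = 2)
  }
  graphics::legend("topleft", legend = cls, col = cols[cls], lwd = 2, bty = "n")
  invisible(x)
}
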