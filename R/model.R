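# The fitted cancer-detection model: quality filtering, grid-searched
# hyperparameters, leave-one-patient-out decision scores, ROC analysis and a
# final refit on all retained spectra.

#' Fit the Raman cancer-detection model
#'
#' End-to-end modelling on a processed dataset: (optional) quality-factor
#' filtering, feature-matrix construction with the blood-band exclusion,
#' (C, k) grid search under leave-one-patient-out cross-validation with
#' inside-fold L1-SVM feature selection, ROC analysis of the pooled
#' out-of-fold decision scores at the winning cell, and a final linear SVM
#' refit on all retained spectra for use on new data.
#'
#' @param dataset a [raman_dataset()] with quality factors computed.
#' @param qf_threshold quality-factor cutoff (strict; default 0.4). `NULL`
#'   skips the filter and models the whole dataset.
#' @param exclude_interval wavenumber interval removed from feature selection
#'   (default 1060--1100 cm^-1).
#' @param C_grid,k_grid hyperparameter grids, see [grid_search()].
#' @return object of class `raman_cancer_model` with components `best`
#'   (hyperparameters), `cv` (LOPO predictions), `roc`, `grid`, `qc`
#'   (quality summary or `NULL`), `final` (refit [train_svm()] model),
#'   `selected_wavenumbers` (final-model features), `n_spectra`.
#' @export
raman_cancer_model <- function(dataset, qf_threshold = 0.4,
                               exclude_interval = c(1060, 1100),
                               C_grid = c(0.01, 0.05, 0.1, 0.5, 1, 2, 5),
                               k_grid = 5:20) {
  qc <- NULL
  if (!is.null(qf_threshold)) {
    sp <- split_by_qf(dataset, qf_threshold)
    qc <- sp$summary
    dataset <- sp$retained
    if (!n_spectra(dataset)) stop("empty retained set after QF filtering")
  }
  fm <- build_feature_matrix(dataset, exclude_interval)
  gs <- grid_search(fm, C_grid, k_grid)
  cv <- gs$cv
  ok <- !is.na(cv$scores)
  roc <- roc_auc(cv$scores[ok], cv$label[ok])
  # final refit on all retained spectra at the winning hyperparameters
  rk <- l1_feature_ranking(fm, max_active = gs$best$k)
  sel <- rk$ranking[seq_len(gs$best$k)]
  final <- train_svm(fm$x[, sel, drop = FALSE], fm$label, gs$best$C)
  structure(list(best = gs$best, cv = cv, roc = roc, grid = gs, qc = qc,
                 final = final, selected_wavenumbers = fm$wavenumber[sel],
                 exclude_interval = exclude_interval,
                 qf_threshold = qf_threshold, n_spectra = n_spectra(dataset),
                 axis = dataset$axis),
            class = "raman_cancer_model")
}

#' @export
print.raman_cancer_model <- function(x, ...) {
  cat("Raman cancer-detection model (linear SVM, LOPO-validated)\n")
  if (!is.null(x$qf_threshold)) {
    cat(sprintf("  QF threshold: > %.2f (%d spectra retained)\n",
                x$qf_threshold, x$n_spectra))
  }
  cat(sprintf("  hyperparameters: C = %g, k = %d features\n",
              x$best$C, x$best$k))
  op <- x$roc$operating_point
  cat(sprintf("  LOPO AUC %.3f; sensitivity %.2f, specificity %.2f\n",
              x$roc$auc, op$sensitivity, op$specificity))
  cat("  selected bands (cm^-1):",
      paste(sort(x$selected_wavenumbers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.raman_cancer_model <- function(object, ...) {
  print(object)
  if (!is.null(object$qc)) print(object$qc)
  cat("\nPer-fold selected wavenumbers:\n")
  for (pt in names(object$cv$selected)) {
    cat(sprintf("  %s: %s\n", pt,
                paste(sort(object$cv$selected[[pt]]), collapse = ", ")))
  }
  if (length(object$cv$flagged)) {
    cat("Flagged folds:", paste(object$cv$flagged, collapse = ", "), "\n")
  }
  tab <- object$grid$table
  cat("\nTop grid cells:\n")
  print(utils::head(tab[order(-tab$auc), ], 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.raman_cancer_model <- function(object, ...) {
  stats::setNames(object$final$weights,
                  sprintf("%g", object$selected_wavenumbers))
}

#' Score new spectra with the fitted model
#'
#' @param object a [raman_cancer_model()].
#' @param newdata a [raman_dataset()] on the same axis, or a spectra x
#'   wavenumbers matrix matching the model's axis.
#' @param type `"score"` for decision values, `"class"` for labels at the
#'   Youden operating threshold.
#' @param ... unused.
#' @return numeric scores or character class labels.
#' @export
predict.raman_cancer_model <- function(object, newdata,
                                       type = c("score", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "raman_dataset")) newdata$snv else newdata
  cols <- match(object$selected_wavenumbers, object$axis)
  scores <- drop(x[, cols, drop = FALSE] %*% object$final$weights) +
    object$final$intercept
  if (type == "score") return(scores)
  ifelse(scores >= object$roc$operating_point$threshold,
         object$final$positive, "normal_benign")
}

#' ROC curve of the fitted model
#' @param x a [raman_cancer_model()].
#' @param ... passed to [plot.roc_result()].
#' @export
plot.raman_cancer_model <- function(x, ...) {
  plot(x$roc, ...)
}
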