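# Feature selection and classification: L1-regularised linear SVM ranking over
# a decreasing penalty path, final C-regularised linear SVM, leave-one-patient
# -out cross-validation, and the (C, k) grid search.

#' Build the feature matrix from a processed dataset
#'
#' One column per wavenumber of the common grid, minus the excluded interval
#' (closed; by default 1060--1100 cm^-1, a region that may carry surface-blood
#' contributions rather than tissue signal).
#'
#' @param ds a [raman_dataset()].
#' @param exclude_interval `c(lo, hi)` in cm^-1, or `NULL` to keep everything.
#' @return object of class `feature_matrix`: `x` (spectra x features),
#'   `wavenumber` (column map), `label`, `patient_id`, `category`, `qf`.
#' @export
build_feature_matrix <- function(ds, exclude_interval = c(1060, 1100)) {
  if (!n_spectra(ds)) stop("empty dataset")
  keep <- rep(TRUE, length(ds$axis))
  if (!is.null(exclude_interval) && length(exclude_interval) == 2) {
    keep <- ds$axis < exclude_interval[1] | ds$axis > exclude_interval[2]
  }
  structure(list(x = ds$snv[, keep, drop = FALSE],
                 wavenumber = ds$axis[keep],
                 label = ds$label,
                 patient_id = ds$patient_id,
                 category = ds$category,
                 qf = ds$qf),
            class = "feature_matrix")
}

# L1-penalised squared-hinge linear SVM solved over a decreasing penalty path
# by FISTA with soft-thresholding, warm starts, and sequential strong-rule
# screening (the inner solve runs on the handful of candidate columns; a full
# KKT sweep per penalty level certifies the screen). The intercept is
# unpenalised. Deterministic. Returns, per feature, the index of the penalty
# level at which its weight first becomes nonzero (Inf if never), plus the
# weights at the last solved path point.
l1_svm_path <- function(x, y01, n_lambda = 50, lambda_min_ratio = 1e-3,
                        max_active = NULL, tol = 1e-6, max_iter = 1000) {
  n <- nrow(x); p <- ncol(x)
  y <- ifelse(y01, 1, -1)
  # full-matrix gradient of the mean squared-hinge loss at (w, b)
  full_grad <- function(w, b) {
    m <- y * (drop(x %*% w) + b)
    u <- y * pmax(1 - m, 0)
    list(gw = -(2 / n) * drop(crossprod(x, u)), gb = -(2 / n) * sum(u))
  }
  # FISTA on a restricted column set; returns converged (w_sub, b)
  solve_sub <- function(xs, ws, b, lam) {
    ps <- ncol(xs)
    xa <- cbind(xs, 1)
    v <- rep(1 / sqrt(ps + 1), ps + 1)
    for (i in 1:25) {
      v <- crossprod(xa, xa %*% v)
      v <- v / sqrt(sum(v^2))
    }
    step <- n / (2 * sum((xa %*% v)^2) / sum(v^2))
    w <- c(ws, b)
    z <- w
    w_prev <- w
    tk <- 1
    for (it in seq_len(max_iter)) {
      m <- y * drop(xa %*% z)
      u <- y * pmax(1 - m, 0)
      g <- -(2 / n) * drop(crossprod(xa, u))
      w_new <- z - step * g
      w_new[1:ps] <- sign(w_new[1:ps]) * pmax(abs(w_new[1:ps]) - step * lam, 0)
      tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      z <- w_new + ((tk - 1) / tk_new) * (w_new - w_prev)
      delta <- max(abs(w_new - w_prev))
      w_prev <- w_new
      tk <- tk_new
      if (delta < tol * max(1, max(abs(w_new)))) break
    }
    list(w = w_prev[1:ps], b = w_prev[ps + 1])
  }
  w <- numeric(p)
  b <- 0
  g0 <- full_grad(w, b)
  lam_max <- max(abs(g0$gw))
  lambdas <- lam_max * exp(seq(0, log(lambda_min_ratio),
                               length.out = n_lambda))
  entry <- rep(Inf, p)
  g_prev <- g0$gw
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    lam_prev <- if (li == 1) lam_max else lambdas[li - 1]
    cand <- which(abs(w) > 1e-8 | abs(g_prev) >= 2 * lam - lam_prev)
    repeat {
      if (length(cand)) {
        sub <- solve_sub(x[, cand, drop = FALSE], w[cand], b, lam)
        w[] <- 0
        w[cand] <- sub$w
        b <- sub$b
      }
      g <- full_grad(w, b)
      viol <- setdiff(which(abs(g$gw) > lam * (1 + 1e-6)), cand)
      if (!length(viol)) {
        g_prev <- g$gw
        break
      }
      cand <- sort(c(cand, viol))
    }
    newly <- which(is.infinite(entry) & abs(w) > 1e-8)
    entry[newly] <- li
    if (!is.null(max_active) && sum(is.finite(entry)) >= max_active) break
  }
  list(entry = entry, weights = w, intercept = b, lambdas = lambdas)
}

#' Rank features by an L1-regularised linear SVM path
#'
#' Fits an L1-penalised (squared-hinge) linear SVM over a decreasing penalty
#' path and ranks features by the penalty level at which their weight first
#' becomes nonzero (earlier entry = stronger feature). Ties are broken by
#' absolute weight at the final path point, then by wavenumber order.
#'
#' @param x spectra x features matrix (or a `feature_matrix`).
#' @param labels binary factor/character labels; both classes required.
#' @param positive positive class name.
#' @param n_lambda number of log-spaced penalty values on the path.
#' @param max_active optionally stop the path early once this many features
#'   have entered (sufficient when only the top `max_active` ranks are used).
#' @param ... passed to the internal path solver.
#' @return object of class `l1_ranking`: `ranking` (column indices, strongest
#'   first), `entry` (path index of first entry per feature), `weights`
#'   (final path point), `wavenumber` if available.
#' @export
l1_feature_ranking <- function(x, labels = NULL,
                               positive = "cancer_necrosis", n_lambda = 50,
                               max_active = NULL, ...) {
  wn <- NULL
  if (inherits(x, "feature_matrix")) {
    if (is.null(labels)) labels <- x$label
    wn <- x$wavenumber
    x <- x$x
  }
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("feature ranking needs both classes present")
  }
  path <- l1_svm_path(x, labels == positive, n_lambda = n_lambda,
                      max_active = max_active, ...)
  ord <- order(path$entry, -abs(path$weights), seq_len(ncol(x)))
  structure(list(ranking = ord, entry = path$entry, weights = path$weights,
                 wavenumber = wn),
            class = "l1_ranking")
}

#' Train a linear soft-margin SVM
#'
#' Plain-hinge C-regularised linear SVM (libsvm via e1071) on a reduced
#' feature set; the returned decision function is oriented so that positive
#' scores indicate the positive class.
#'
#' @param x training matrix (spectra x selected features).
#' @param labels binary labels; a single-class input is an error.
#' @param C soft-margin regularization parameter (> 0).
#' @param positive positive class name.
#' @param tolerance libsvm termination tolerance.
#' @return object of class `linear_svm`: `weights`, `intercept`, `C`,
#'   `positive`.
#' @export
train_svm <- function(x, labels, C, positive = "cancer_necrosis",
                      tolerance = 1e-7) {
  labels <- as.character(labels)
  if (C <= 0) stop("C must be > 0")
  if (length(unique(labels)) < 2) stop("single-class training set")
  y <- factor(labels)
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE, tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients its decision function toward whichever class it met first;
  # normalise so positive score = positive class
  dv <- attr(stats::predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  first <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  if (first != positive) {
    w <- -w
    b <- -b
  }
  structure(list(weights = w, intercept = b, C = C, positive = positive),
            class = "linear_svm")
}

#' Decision scores of a linear SVM
#' @param object a [train_svm()] model.
#' @param newdata matrix with the same columns the model was trained on.
#' @param ... unused.
#' @return numeric decision scores (positive = positive class).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  drop(newdata %*% object$weights) + object$intercept
}

# Per-fold L1 rankings, computed on training patients only. Folds whose
# training partition lacks a class are returned as NULL.
fold_rankings <- function(fm, max_active, n_lambda = 50) {
  patients <- sort(unique(fm$patient_id))
  out <- vector("list", length(patients))
  names(out) <- patients
  for (pt in patients) {
    tr <- fm$patient_id != pt
    if (length(unique(fm$label[tr])) < 2) next
    out[[pt]] <- l1_feature_ranking(fm$x[tr, , drop = FALSE], fm$label[tr],
                                    n_lambda = n_lambda,
                                    max_active = max_active)
  }
  out
}

#' Leave-one-patient-out cross-validation
#'
#' Each fold holds out all spectra of one patient; feature selection (L1 path
#' ranking, top `k`) and SVM training use only the remaining patients, so no
#' patient-level information leaks into its own prediction. A fold whose
#' training partition lacks a class is flagged and its spectra left unscored.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param C soft-margin parameter.
#' @param k number of selected features.
#' @param rankings optional precomputed [fold_rankings] (internal reuse by the
#'   grid search).
#' @return object of class `lopo_cv`: `scores` (one per spectrum; `NA` for
#'   flagged folds), `fold` (held-out patient per spectrum), `selected`
#'   (wavenumbers per fold), `models` (per-fold [train_svm()] fits),
#'   `flagged`, `C`, `k`.
#' @export
lopo_cv <- function(fm, C, k, rankings = NULL) {
  patients <- sort(unique(fm$patient_id))
  if (length(patients) < 2) stop("leave-one-patient-out needs >= 2 patients")
  if (k < 1) stop("k must be >= 1")
  if (is.null(rankings)) rankings <- fold_rankings(fm, max_active = k)
  scores <- rep(NA_real_, nrow(fm$x))
  selected <- list()
  models <- list()
  flagged <- character(0)
  for (pt in patients) {
    te <- fm$patient_id == pt
    rk <- rankings[[pt]]
    if (is.null(rk)) {
      flagged <- c(flagged, pt)
      next
    }
    sel <- rk$ranking[seq_len(k)]
    tr <- !te
    model <- train_svm(fm$x[tr, sel, drop = FALSE], fm$label[tr], C)
    scores[te] <- predict(model, fm$x[te, sel, drop = FALSE])
    selected[[pt]] <- fm$wavenumber[sel]
    models[[pt]] <- model
  }
  structure(list(scores = scores, fold = fm$patient_id, label = fm$label,
                 selected = selected, models = models, flagged = flagged,
                 C = C, k = k),
            class = "lopo_cv")
}

#' Grid search over (C, k) with LOPO evaluation
#'
#' Evaluates the pooled LOPO AUC for every cell of the hyperparameter grid.
#' The per-fold L1 ranking does not depend on (C, k), so it is computed once
#' per fold and the top-`k` prefix reused across cells. Ties in AUC are broken
#' toward smaller `k`, then smaller `C`.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param C_grid soft-margin grid (default spans 0.01 to 5).
#' @param k_grid feature-count grid (default 5 to 20).
#' @return object of class `grid_search`: `table` (data.frame C, k, auc),
#'   `best` (list C, k, auc), `cv` (the [lopo_cv()] predictions at the best
#'   cell).
#' @export
grid_search <- function(fm, C_grid = c(0.01, 0.05, 0.1, 0.5, 1, 2, 5),
                        k_grid = 5:20) {
  if (!length(C_grid) || !length(k_grid)) stop("empty hyperparameter grid")
  rankings <- fold_rankings(fm, max_active = max(k_grid))
  cells <- expand.grid(k = sort(k_grid), C = sort(C_grid))
  aucs <- numeric(nrow(cells))
  cvs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cv <- lopo_cv(fm, C = cells$C[i], k = cells$k[i], rankings = rankings)
    ok <- !is.na(cv$scores)
    aucs[i] <- auc_mw(cv$scores[ok], cv$label[ok])
    cvs[[i]] <- cv
  }
  tab <- data.frame(C = cells$C, k = cells$k, auc = aucs)
  # argmax AUC; ties toward smaller k then smaller C
  ord <- order(-tab$auc, tab$k, tab$C)
  best_i <- ord[1]
  structure(list(table = tab,
                 best = list(C = tab$C[best_i], k = tab$k[best_i],
                             auc = tab$auc[best_i]),
                 cv = cvs[[best_i]]),
            class = "grid_search")
}

#' Group ranked wavenumbers into contiguous bands
#'
#' Selected features on the 1 cm^-1 grid cluster within vibrational bands; for
#' band-level reporting the ranked wavenumbers are grouped: each feature joins
#' the first-ranked existing group holding a member within `gap` cm^-1 of it,
#' otherwise it opens a new band. Bands are returned in rank order of their
#' strongest member.
#'
#' @param wavenumbers ranked wavenumbers (strongest first).
#' @param gap grouping distance in cm^-1 (default 15, about one band width).
#' @return numeric vector: the leading (strongest) wavenumber of each band,
#'   in rank order.
#' @export
group_selected_bands <- function(wavenumbers, gap = 15) {
  bands <- list()
  for (w in wavenumbers) {
    placed <- FALSE
    for (i in seq_along(bands)) {
      if (min(abs(bands[[i]] - w)) <= gap) {
        bands[[i]] <- c(bands[[i]], w)
        placed <- TRUE
        break
      }
    }
    if (!placed) bands[[length(bands) + 1L]] <- w
  }
  vapply(bands, `[`, numeric(1), 1)
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("Grid search over %d cells: best AUC %.3f at C = %g, k = %d\n",
              nrow(x$table), x$best$auc, x$best$C, x$best$k))
  invisible(x)
}
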