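test_that("feature matrix drops the excluded blood band", {
  n <- 4
  ds <- fake_dataset(matrix(stats::rnorm(n * 901), n), axis = raman_axis(),
                     label = rep(c("cancer_necrosis", "normal_benign"), 2),
                     patient_id = c("P01", "P01", "P02", "P02"))
  fm <- build_feature_matrix(ds)
  expect_equal(ncol(fm$x), 901 - 41)
  expect_false(any(fm$wavenumber >= 1060 & fm$wavenumber <= 1100))
  expect_equal(ncol(build_feature_matrix(ds, NULL)$x), 901)
  expect_error(build_feature_matrix(ds[integer(0)]), "empty")
})

test_that("the L1 path ranks planted signal columns on top", {
  fm <- toy_feature_dataset(seed = 1, signal_cols = c(10, 40))
  rk <- l1_feature_ranking(fm)
  expect_true(all(c(10, 40) %in% rk$ranking[1:5]))
  expect_error(l1_feature_ranking(fm$x, rep("cancer_necrosis", nrow(fm$x))),
               "both classes")
})

test_that("duplicated columns occupy adjacent ranks by the tie rule", {
  fm <- toy_feature_dataset(seed = 2, signal_cols = c(10), p = 30)
  x2 <- cbind(fm$x, fm$x[, 10])
  rk <- l1_feature_ranking(x2, fm$label)
  pos <- match(c(10, 31), rk$ranking)
  expect_equal(sort(pos), c(1, 2))
  expect_lt(pos[1], pos[2])  # wavenumber order breaks the exact tie
  # whole ranking is reproducible
  rk2 <- l1_feature_ranking(x2, fm$label)
  expect_identical(rk$ranking, rk2$ranking)
})

test_that("rankings destabilize under label permutation", {
  fm <- toy_feature_dataset(seed = 3, signal_cols = integer(0), p = 100,
                            n_per = 10)
  set.seed(42)
  r1 <- l1_feature_ranking(fm$x, sample(fm$label))
  r2 <- l1_feature_ranking(fm$x, sample(fm$label))
  rho <- cor(order(r1$ranking), order(r2$ranking), method = "spearman")
  expect_lt(abs(rho), 0.3)
})

test_that("linear SVM training satisfies the margin contracts", {
  x <- matrix(c(-1, -1, 1, 1), 2, 2, byrow = TRUE)
  y <- c("normal_benign", "cancer_necrosis")
  m <- train_svm(x, y, C = 1)
  s <- predict(m, x)
  expect_gt(s[2], 0)
  expect_lt(s[1], 0)

  # hard-margin limit on separable data: zero training error
  fm <- toy_feature_dataset(seed = 4, signal_cols = 1:3, effect = 4, p = 10)
  mh <- train_svm(fm$x, fm$label, C = 1e6)
  pred <- predict(mh, fm$x) > 0
  expect_equal(pred, fm$label == "cancer_necrosis", ignore_attr = TRUE)

  # flipping labels negates the decision function
  flip <- ifelse(fm$label == "cancer_necrosis", "normal_benign",
                 "cancer_necrosis")
  m1 <- train_svm(fm$x, fm$label, C = 1)
  m2 <- train_svm(fm$x, flip, C = 1, positive = "normal_benign")
  expect_equal(predict(m1, fm$x), predict(m2, fm$x), tolerance = 1e-6)
  m3 <- train_svm(fm$x, flip, C = 1)
  expect_equal(predict(m1, fm$x), -predict(m3, fm$x), tolerance = 1e-4)

  expect_error(train_svm(fm$x, rep("cancer_necrosis", nrow(fm$x)), 1),
               "single-class")
  expect_error(train_svm(fm$x, fm$label, C = -1), "C must be")
})

test_that("LOPO cross-validation scores every spectrum without leakage", {
  fm <- toy_feature_dataset(seed = 5)
  cv <- lopo_cv(fm, C = 1, k = 4)
  expect_equal(length(cv$scores), nrow(fm$x))
  expect_false(any(is.na(cv$scores)))
  expect_length(cv$selected, 10)

  # per-fold selection depends only on the training patients
  pt <- "P03"
  tr <- fm$patient_id != pt
  rk_tr <- l1_feature_ranking(fm$x[tr, ], fm$label[tr], max_active = 4)
  expect_equal(sort(fm$wavenumber[rk_tr$ranking[1:4]]),
               sort(cv$selected[[pt]]))

  # no leakage: each fold's selection and weights are identical whether the
  # held-out spectra exist or are perturbed arbitrarily
  direct <- train_svm(fm$x[tr, rk_tr$ranking[1:4], drop = FALSE],
                      fm$label[tr], C = 1)
  expect_equal(cv$models[[pt]]$weights, direct$weights, tolerance = 1e-10)
  expect_equal(cv$models[[pt]]$intercept, direct$intercept,
               tolerance = 1e-10)
  fm_pert <- fm
  fm_pert$x[!tr, ] <- fm_pert$x[!tr, ] * 5 + 3
  cv_pert <- lopo_cv(fm_pert, C = 1, k = 4)
  expect_identical(cv_pert$selected[[pt]], cv$selected[[pt]])
  expect_equal(cv_pert$models[[pt]]$weights, cv$models[[pt]]$weights,
               tolerance = 1e-10)

  # degenerate two-patient, single-class-per-patient design: both folds flagged
  n <- 8
  fm3 <- structure(list(
    x = matrix(stats::rnorm(n * 5), n, 5), wavenumber = 1:5,
    label = factor(rep(c("cancer_necrosis", "normal_benign"), each = 4),
                   levels = c("cancer_necrosis", "normal_benign")),
    patient_id = rep(c("A", "B"), each = 4),
    category = rep("x", n), qf = rep(0.9, n)), class = "feature_matrix")
  cv3 <- lopo_cv(fm3, C = 1, k = 2)
  expect_setequal(cv3$flagged, c("A", "B"))
  expect_true(all(is.na(cv3$scores)))

  expect_error(lopo_cv(fm3[c("x")], C = 1, k = 2))
})

test_that("grid search evaluates every cell and breaks ties toward parsimony", {
  fm <- toy_feature_dataset(seed = 6)
  g1 <- grid_search(fm, C_grid = 1, k_grid = 4)
  expect_equal(nrow(g1$table), 1)
  expect_equal(g1$best[c("C", "k")], list(C = 1, k = 4))

  gs <- grid_search(fm, C_grid = c(0.1, 1), k_grid = c(2, 4, 8))
  expect_equal(nrow(gs$table), 6)
  gs2 <- grid_search(fm, C_grid = c(0.1, 1), k_grid = c(2, 4, 8))
  expect_identical(gs$table, gs2$table)

  # default grid cardinality: 7 C values x 16 k values
  expect_equal(length(c(0.01, 0.05, 0.1, 0.5, 1, 2, 5)) * length(5:20), 112)

  # multivariate model beats the best single feature on separated data
  uni <- max(vapply(seq_len(ncol(fm$x)), function(j) {
    ramanlung:::auc_mw(fm$x[, j], fm$label)
  }, numeric(1)))
  expect_gte(gs$best$auc, uni)

  expect_error(grid_search(fm, C_grid = numeric(0), k_grid = 5), "empty")
})

test_that("ranked wavenumbers group into contiguous bands in rank order", {
  expect_equal(group_selected_bands(c(1657, 1655, 1449, 1660, 852)),
               c(1657, 1449, 852))
  expect_equal(group_selected_bands(c(900, 1000, 916))[1:2], c(900, 1000))
  expect_equal(group_selected_bands(c(900, 910, 920, 930)), 900)
})
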