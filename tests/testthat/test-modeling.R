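test_that("Gaussian naive Bayes recovers per-class moments", {
  X <- matrix(c(0, 0.2, -0.2, 2, 2.2, 1.8), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  m <- fit_gaussian_nb(X, y)
  expect_equal(unname(m$class0$mean), 0)
  expect_equal(unname(m$class1$mean), 2)
  expect_equal(unname(m$class0$var), var(c(0, 0.2, -0.2)))

  m2 <- fit_gaussian_nb(X, y)
  expect_identical(m, m2)

  set.seed(2)
  Xr <- matrix(rnorm(60), 20, 3); yr <- rep(0:1, 10)
  mr <- fit_gaussian_nb(Xr, yr)
  expect_equal(unname(mr$class1$mean), unname(colMeans(Xr[yr == 1, ])))
  expect_equal(unname(mr$class1$var), unname(apply(Xr[yr == 1, ], 2, var)))

  expect_error(fit_gaussian_nb(Xr, rep(0, 20)), class = "tumortex_fit_error")
})

test_that("posteriors follow the closed-form Gaussian likelihood ratio", {
  X <- matrix(c(-1, 1, 1, 3), ncol = 1)   # class means 0 and 2, equal vars
  y <- c(0, 0, 1, 1)
  m <- fit_gaussian_nb(X, y)
  expect_equal(predict_posterior(m, 1), 0.5)           # symmetric midpoint
  # at x = 0: log-likelihood gap = (0 - (0-2)^2/2 + 0^2/2)/var = -2/var
  v <- var(c(-1, 1))
  expect_equal(predict_posterior(m, 0), 1 / (1 + exp(2 / v)))
  expect_equal(predict_posterior(m, 0) + predict_posterior(m, 2), 1,
               tolerance = 1e-12)                      # symmetry about 1
})

test_that("confusion metrics reproduce the clinical arithmetic", {
  expect_equal(confusion_metrics(c(.9, .8, .3, .1), c(1, 1, 0, 0))$accuracy, 1)
  expect_equal(confusion_metrics(c(.6, .4), c(0, 1))$accuracy, 0)
  # 10 of 15 positives and 19 of 20 negatives correct
  scores <- c(rep(.9, 10), rep(.1, 5), rep(.1, 19), rep(.9, 1))
  labels <- c(rep(1, 15), rep(0, 20))
  cm <- confusion_metrics(scores, labels)
  expect_equal(cm$sensitivity, 10 / 15, tolerance = 1e-12)
  expect_equal(cm$specificity, 19 / 20, tolerance = 1e-12)
  expect_equal(cm$accuracy, 29 / 35, tolerance = 1e-12)
  # ties at the threshold classify positive
  expect_equal(confusion_metrics(c(0.5, 0.4), c(1, 0))$accuracy, 1)
  expect_error(confusion_metrics(c(.5, .6), c(1, 1)),
               class = "tumortex_metric_error")
})

test_that("trapezoidal AUC equals the exhaustive rank statistic", {
  expect_equal(roc_auc(c(.9, .8, .3, .1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 17
    sc <- round(runif(n), 1)   # coarse scores force ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), oracle_rank_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("leave-one-image-out produces one nested fold per patient", {
  coh <- generate_cohort(cohort_spec(6, 5, seed = 19))
  tab <- build_cohort_table(coh)
  cv <- loo_cv(tab, family = "acm2")
  expect_equal(nrow(cv$out_of_fold), 11)
  expect_length(cv$selected, 11)
  expect_true(all(cv$out_of_fold$score >= 0 & cv$out_of_fold$score <= 1))

  # leakage check: the fold-1 selection equals selection recomputed on the
  # training rows alone
  xy <- tumortex:::.table_xy(tab, "acm2")
  refit <- tumortex:::.select_and_fit(xy$X[-1, ], xy$y[-1], 3L, NULL)
  expect_equal(cv$selected[[1]], refit$subset_names)
  # and corrupting the held-out row does not change its fold's selection
  tab2 <- tab
  tab2[1, feature_names()[feature_families() == "acm2"]] <- 1e6
  cv2 <- loo_cv(tab2, family = "acm2")
  expect_equal(cv2$selected[[1]], cv$selected[[1]])
})

test_that("repeated k-fold is seeded, stratified, and reduces to LOO at k = n", {
  coh <- generate_cohort(cohort_spec(5, 5, seed = 31))
  tab <- build_cohort_table(coh)
  a <- repeated_kfold_cv(tab, k = 3, repeats = 2, seed = 4, family = "acm2")
  b <- repeated_kfold_cv(tab, k = 3, repeats = 2, seed = 4, family = "acm2")
  expect_identical(glance(a), glance(b))
  expect_length(a$selected, 6)           # 3 folds x 2 repeats

  kn <- repeated_kfold_cv(tab, k = 10, repeats = 1, seed = 8, family = "acm2")
  lo <- loo_cv(tab, family = "acm2")
  expect_equal(kn$auc, lo$auc)
  expect_equal(kn$accuracy, lo$accuracy)
})

test_that("cross-validation results expose tidy, glance, and autoplot", {
  coh <- generate_cohort(cohort_spec(4, 4, seed = 37))
  tab <- build_cohort_table(coh)
  cv <- loo_cv(tab, family = "ih")
  td <- tidy(cv)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("patient_id", "label", "score"))
  gl <- glance(cv)
  expect_equal(gl$auc, cv$auc)
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})
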