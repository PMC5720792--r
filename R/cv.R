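# Selection nested in a training set: rank, forward-select, fit.
.select_and_fit <- function(Xtr, ytr, n_sets, k_max) {
  if (is.null(k_max)) k_max <- min(ncol(Xtr), nrow(Xtr) - 2L)
  k_max <- max(1L, min(k_max, ncol(Xtr), nrow(Xtr) - 2L))
  rk <- .fmrmr_rank_matrix(Xtr, ytr, n_sets, k_rank = k_max)
  ranking <- structure(c(rk, list(feature_names = colnames(Xtr))),
                       class = "tumortex_ranking")
  sel <- forward_select(ranking, Xtr, ytr, k_max = k_max)
  model <- fit_gaussian_nb(Xtr[, sel$subset, drop = FALSE], ytr)
  list(model = model, subset = sel$subset, subset_names = sel$subset_names,
       O = sel$O)
}

new_cv_result <- function(out_of_fold, auc, metrics, subsets, protocol,
                          family, seed = NA_integer_, extra = list()) {
  structure(
    c(list(out_of_fold = out_of_fold, auc = auc,
           accuracy = metrics$accuracy, sensitivity = metrics$sensitivity,
           specificity = metrics$specificity, selected = subsets,
           protocol = protocol, family = family, seed = seed),
      extra),
    class = "tumortex_cv"
  )
}

#' @export
print.tumortex_cv <- function(x, ...) {
  cat(sprintf(
    "<tumortex_cv> %s | family=%s\n  AUC %.3f | Ac %.1f%% | Sn %.2f | Sp %.2f\n",
    x$protocol, paste(x$family, collapse = "+"), x$auc, 100 * x$accuracy,
    x$sensitivity, x$specificity))
  invisible(x)
}

#' Leave-one-image-out cross-validation
#'
#' For every held-out patient, fuzzy-MRMR ranking, forward selection, and
#' the naive Bayes fit are recomputed on the remaining patients only; the
#' held-out patient is then scored. AUC is computed from the n out-of-fold
#' posteriors, and accuracy/sensitivity/specificity at the 0.5 threshold
#' with equal priors.
#'
#' @param table Cohort tibble from [build_cohort_table()].
#' @param family Feature family subset (`"all"`, a family name such as
#'   `"acm2"`, a vector of families, or explicit feature names).
#' @param n_sets Fuzzy sets used in selection.
#' @param k_max Cap on the forward-selection subset size; default
#'   `min(D, n_train - 2)`.
#' @return A `tumortex_cv` with out-of-fold scores, metrics, and the
#'   per-fold selected subsets.
#' @export
loo_cv <- function(table, family = "all", n_sets = 3L, k_max = NULL) {
  xy <- .table_xy(table, family)
  n <- nrow(xy$X)
  stopifnot(n >= 3)
  scores <- numeric(n)
  subsets <- vector("list", n)
  for (i in seq_len(n)) {
    ytr <- xy$y[-i]
    if (length(unique(ytr)) < 2L) {
      abort("a training fold lost one class entirely",
            class = "tumortex_fold_error")
    }
    fit <- .select_and_fit(xy$X[-i, , drop = FALSE], ytr, n_sets, k_max)
    scores[i] <- predict_posterior(fit$model,
                                   xy$X[i, fit$subset, drop = FALSE])
    subsets[[i]] <- fit$subset_names
  }
  oof <- tibble(patient_id = xy$ids, label = xy$y, score = scores)
  new_cv_result(oof, roc_auc(scores, xy$y),
                confusion_metrics(scores, xy$y), subsets,
                protocol = "leave-one-image-out", family = family)
}

# Stratified fold assignment: shuffled samples of each class are dealt
# round-robin into k folds, with the deal continuing across classes so
# every fold is populated (k = n gives one sample per fold).
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  deal <- sample(seq_len(k))
  pos <- 0L
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    fold[idx] <- deal[(pos + seq_along(idx) - 1L) %% k + 1L]
    pos <- pos + length(idx)
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Random stratified partitions per repeat (seeded); feature selection is
#' nested in each training fold. Within a repeat, every patient is scored
#' exactly once by the fold that held it out; metrics are computed on the
#' pooled out-of-fold scores of the repeat, then averaged over repeats
#' (so `k = n` reduces exactly to leave-one-image-out).
#'
#' @param table Cohort tibble.
#' @param k Number of folds.
#' @param repeats Number of repeated partitions.
#' @param seed Integer seed for the fold partitions.
#' @inheritParams loo_cv
#' @return A `tumortex_cv`; `per_repeat` holds the repeat-level metric
#'   table and `out_of_fold` the scores of every repeat.
#' @export
repeated_kfold_cv <- function(table, k = 3L, repeats = 20L, seed = 1L,
                              family = "all", n_sets = 3L, k_max = NULL) {
  stopifnot(k >= 2, repeats >= 1)
  xy <- .table_xy(table, family)
  n <- nrow(xy$X)
  oof <- list()
  per_repeat <- list()
  subsets <- list()
  for (rep_i in seq_len(repeats)) {
    fold <- .with_seed(.derive_seed(seed, rep_i), .stratified_folds(xy$y, k))
    scores <- numeric(n)
    for (f in seq_len(k)) {
      te <- which(fold == f); tr <- which(fold != f)
      if (length(unique(xy$y[tr])) < 2L) {
        abort("a training fold lost one class entirely",
              class = "tumortex_fold_error")
      }
      fit <- .select_and_fit(xy$X[tr, , drop = FALSE], xy$y[tr], n_sets, k_max)
      scores[te] <- predict_posterior(fit$model,
                                      xy$X[te, fit$subset, drop = FALSE])
      subsets[[length(subsets) + 1L]] <- fit$subset_names
    }
    cm <- confusion_metrics(scores, xy$y)
    cm$auc <- roc_auc(scores, xy$y)
    per_repeat[[rep_i]] <- cm
    oof[[rep_i]] <- tibble(repeat_id = rep_i, patient_id = xy$ids,
                           label = xy$y, score = scores)
  }
  pr <- dplyr::bind_rows(per_repeat, .id = "repeat_id")
  agg <- dplyr::summarise(pr, dplyr::across(c("accuracy", "sensitivity",
                                              "specificity", "auc"), mean))
  new_cv_result(dplyr::bind_rows(oof), agg$auc,
                agg[, c("accuracy", "sensitivity", "specificity")], subsets,
                protocol = sprintf("%d-fold x %d repeats", k, repeats),
                family = family, seed = seed,
                extra = list(per_repeat = pr, k = k, repeats = repeats))
}

#' @describeIn loo_cv Tidy the out-of-fold scores of a cross-validation
#'   result into a tibble.
#' @param x A `tumortex_cv`.
#' @param ... Unused.
#' @export
tidy.tumortex_cv <- function(x, ...) {
  x$out_of_fold
}

#' @describeIn loo_cv One-row summary of a cross-validation result.
#' @export
glance.tumortex_cv <- function(x, ...) {
  tibble(auc = x$auc, accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, protocol = x$protocol,
         family = paste(x$family, collapse = "+"))
}

#' @describeIn loo_cv ROC curve of the out-of-fold scores.
#' @param object A `tumortex_cv`.
#' @export
autoplot.tumortex_cv <- function(object, ...) {
  pts <- roc_points(object$out_of_fold$score, object$out_of_fold$label)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (%s), AUC = %.2f", object$protocol, object$auc)
    ) +
    ggplot2::theme_minimal()
}
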