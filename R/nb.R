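#' Fit a Gaussian naive Bayes classifier
#'
#' Per-class, per-feature means and variances with equal class priors by
#' default (priors are not re-estimated from fold class frequencies).
#' Variances are floored at `1e-9` times the overall feature variance
#' (plus a tiny absolute floor) to keep likelihoods defined after feature
#' selection.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Binary labels (0 = short survivor, 1 = long survivor; the
#'   positive class is survival >= 2 years).
#' @param priors Class prior pair `(P(y=0), P(y=1))`.
#' @return A `tumortex_nb` model.
#' @export
fit_gaussian_nb <- function(X, y, priors = c(0.5, 0.5)) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L || min(sum(y == 0L), sum(y == 1L)) < 2L) {
    abort("both classes need >= 2 samples", class = "tumortex_fit_error")
  }
  stopifnot(abs(sum(priors) - 1) < 1e-9)
  floor_v <- pmax(apply(X, 2L, var) * 1e-9, 1e-12)
  mk <- function(cls) {
    Xi <- X[y == cls, , drop = FALSE]
    list(mean = colMeans(Xi), var = pmax(apply(Xi, 2L, var), floor_v))
  }
  structure(
    list(class0 = mk(0L), class1 = mk(1L), priors = priors,
         features = colnames(X)),
    class = "tumortex_nb"
  )
}

#' Positive-class posterior of a Gaussian naive Bayes model
#'
#' Computed in the log domain as the product of univariate Gaussian
#' likelihoods times the priors, normalized over the two classes.
#'
#' @param model A `tumortex_nb`.
#' @param x A feature vector or matrix of rows to score (columns in model
#'   feature order).
#' @return Posterior probability of class 1 (survival >= 2 years), one
#'   value per row.
#' @export
predict_posterior <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  ll <- function(par) {
    rowSums(-0.5 * log(2 * pi * matrix(par$var, nrow(x), ncol(x), byrow = TRUE)) -
            (x - matrix(par$mean, nrow(x), ncol(x), byrow = TRUE))^2 /
            (2 * matrix(par$var, nrow(x), ncol(x), byrow = TRUE)))
  }
  l0 <- ll(model$class0) + log(model$priors[1])
  l1 <- ll(model$class1) + log(model$priors[2])
  as.vector(1 / (1 + exp(l0 - l1)))
}

#' Threshold classification metrics
#'
#' Accuracy, sensitivity, and specificity at a fixed posterior threshold.
#' The positive class is label 1 (survival >= 2 years); scores at the
#' threshold classify positive.
#'
#' @param scores Positive-class scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold (default 0.5).
#' @return One-row tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (!any(labels == 1L) || !any(labels == 0L)) {
    abort("both classes required for sensitivity/specificity",
          class = "tumortex_metric_error")
  }
  pred <- scores >= threshold
  pos <- labels == 1L
  tibble(
    accuracy = mean(pred == pos),
    sensitivity = sum(pred & pos) / sum(pos),
    specificity = sum(!pred & !pos) / sum(!pos)
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area over all score thresholds; equal to the rank statistic
#' (probability that a positive outscores a negative, ties counting one
#' half).
#'
#' @param scores Positive-class scores.
#' @param labels Binary labels (both classes present).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}

#' ROC curve points
#'
#' @param scores Positive-class scores.
#' @param labels Binary labels.
#' @return Tibble of `threshold`, `fpr`, `tpr`, ordered from (0, 0) to
#'   (1, 1).
#' @export
roc_points <- function(scores, labels) {
  if (!any(labels == 1L) || !any(labels == 0L)) {
    abort("both classes required for a ROC curve",
          class = "tumortex_metric_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- labels[ord] == 1L
  cuts <- which(!duplicated(s, fromLast = TRUE) |
                  seq_along(s) == length(s))
  tp <- cumsum(pos)[cuts]
  fp <- cumsum(!pos)[cuts]
  tibble(
    threshold = c(Inf, s[cuts]),
    fpr = c(0, fp / sum(!pos)),
    tpr = c(0, tp / sum(pos))
  )
}
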