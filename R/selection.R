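#' Fuzzify a numeric variable
#'
#' Triangular membership functions over the empirical ranks of `x`, with
#' centers at equally spaced rank quantiles (for the default `n_sets = 3`,
#' the 10th, 50th, and 90th percentiles), forming a partition of unity:
#' every row of the membership matrix sums to 1. Working on ranks makes
#' the fuzzification -- and hence the ranking built on it -- invariant to
#' strictly monotone transforms of the variable. Values at or beyond the
#' outer centers belong fully to the outer sets. Duplicate centers (heavy
#' ties, or a constant `x`) collapse, with the remaining membership
#' columns zero-filled, so a constant variable puts all mass in the first
#' set.
#'
#' @param x Finite numeric vector.
#' @param n_sets Number of fuzzy sets (>= 2).
#' @return A `tumortex_fuzzy` with fields `membership` (n x n_sets) and
#'   `set_centers` (on the rank scale).
#' @export
fuzzify <- function(x, n_sets = 3L) {
  stopifnot(n_sets >= 2, all(is.finite(x)))
  x <- rank(x, ties.method = "average")
  centers <- unname(quantile(x, seq(0.1, 0.9, length.out = n_sets)))
  uc <- unique(centers)
  K <- length(uc)
  n <- length(x)
  mem <- matrix(0, n, n_sets)
  if (K == 1L) {
    mem[, 1] <- 1
  } else {
    band <- findInterval(x, uc, all.inside = TRUE)   # interval [uc[k], uc[k+1])
    wR <- (x - uc[band]) / (uc[band + 1L] - uc[band])
    wR <- pmin(pmax(wR, 0), 1)
    for (k in seq_len(K - 1L)) {
      sel <- band == k
      mem[sel, k] <- mem[sel, k] + (1 - wR[sel])
      mem[sel, k + 1L] <- mem[sel, k + 1L] + wR[sel]
    }
  }
  structure(list(membership = mem, set_centers = centers),
            class = "tumortex_fuzzy")
}

# Crisp two-set membership for a binary class vector.
.fuzzify_class <- function(y) {
  structure(list(membership = cbind(1 - y, y), set_centers = c(0, 1)),
            class = "tumortex_fuzzy")
}

#' Fuzzy mutual information between two fuzzified variables
#'
#' Estimated from the fuzzy joint frequencies
#' `p(i, j) = mean(a[, i] * b[, j])` and their marginals, with base-2
#' logarithms; symmetric, and clipped at 0 against numerical noise.
#'
#' @param a,b `tumortex_fuzzy` objects (or plain membership matrices) over
#'   the same samples.
#' @return Nonnegative scalar (bits).
#' @export
fuzzy_mutual_information <- function(a, b) {
  ma <- if (inherits(a, "tumortex_fuzzy")) a$membership else a
  mb <- if (inherits(b, "tumortex_fuzzy")) b$membership else b
  if (nrow(ma) != nrow(mb)) {
    abort("sample counts differ", class = "tumortex_alignment_error")
  }
  joint <- crossprod(ma, mb) / nrow(ma)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  denom <- outer(pa, pb)
  pos <- joint > 0 & denom > 0
  max(0, sum(joint[pos] * log2(joint[pos] / denom[pos])))
}

# Incremental fuzzy-MRMR over a feature matrix. Ranks up to k_rank
# features by the criterion relevance - mean redundancy; remaining indices
# are appended in ascending order with NA criterion values.
.fmrmr_rank_matrix <- function(X, y, n_sets = 3L, k_rank = NULL) {
  D <- ncol(X)
  stopifnot(D >= 2, length(unique(y)) == 2L)
  if (is.null(k_rank)) k_rank <- D
  k_rank <- min(k_rank, D)
  mems <- lapply(seq_len(D), function(j) fuzzify(X[, j], n_sets)$membership)
  cls <- .fuzzify_class(y)$membership
  rel <- vapply(mems, function(m) fuzzy_mutual_information(m, cls), numeric(1))

  order_out <- integer(0)
  crit <- numeric(0)
  red_sum <- numeric(D)
  candidate <- rep(TRUE, D)
  for (m in seq_len(k_rank)) {
    J <- if (m == 1L) rel else rel - red_sum / (m - 1L)
    J[!candidate] <- -Inf
    pick <- which.max(J)                     # ties resolve to lowest index
    order_out <- c(order_out, pick)
    crit <- c(crit, J[pick])
    candidate[pick] <- FALSE
    if (m < k_rank) {
      idx <- which(candidate)
      red_sum[idx] <- red_sum[idx] + vapply(idx, function(j) {
        fuzzy_mutual_information(mems[[j]], mems[[pick]])
      }, numeric(1))
    }
  }
  rest <- setdiff(seq_len(D), order_out)
  list(order = c(order_out, rest),
       criterion = c(crit, rep(NA_real_, length(rest))),
       relevance = rel, n_ranked = k_rank)
}

#' Rank features by fuzzy minimum-redundancy maximum-relevance
#'
#' Incremental ranking: the first feature maximizes the fuzzy mutual
#' information with the class; each subsequent feature maximizes its class
#' relevance minus its mean fuzzy mutual information with the features
#' already selected. Ties break to the lowest feature index. The produced
#' prefix sets are nested by construction.
#'
#' @param table Cohort tibble with a binary `label` column and feature
#'   columns (as from [build_cohort_table()]), or a plain numeric matrix.
#' @param labels Class vector, required when `table` is a matrix.
#' @param n_sets Fuzzy sets per feature.
#' @param k_rank Rank at most this many features (the remainder is
#'   appended unranked); `NULL` ranks all.
#' @param family Feature family filter for cohort tibbles (see
#'   [feature_families()]), or `"all"`.
#' @return A `tumortex_ranking`: `order` (permutation of feature indices),
#'   `criterion` (J value per rank step), `relevance`, `feature_names`.
#' @export
fmrmr_rank <- function(table, labels = NULL, n_sets = 3L, k_rank = NULL,
                       family = "all") {
  if (is.matrix(table)) {
    X <- table
    y <- as.integer(labels)
    fn <- colnames(X)
    if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)))
  } else {
    xy <- .table_xy(table, family)
    X <- xy$X; y <- xy$y; fn <- colnames(X)
  }
  res <- .fmrmr_rank_matrix(X, y, n_sets, k_rank)
  structure(c(res, list(feature_names = fn)), class = "tumortex_ranking")
}

# Vectorized leave-one-out Gaussian naive Bayes over nested ranked feature
# prefixes: returns an n x k_max matrix of positive-class posteriors.
.nb_loo_posteriors <- function(X, y, order, k_max, priors = c(0.5, 0.5)) {
  n <- nrow(X)
  Xo <- X[, order[seq_len(k_max)], drop = FALSE]
  floor_v <- pmax(apply(Xo, 2L, var) * 1e-9, 1e-12)
  ll <- list()
  for (cls in 0:1) {
    sel <- y == cls
    n_c <- sum(sel)
    S <- colSums(Xo[sel, , drop = FALSE])
    SS <- colSums(Xo[sel, , drop = FALSE]^2)
    Mfull <- matrix(S / n_c, n, k_max, byrow = TRUE)
    Vfull <- matrix((SS - S^2 / n_c) / (n_c - 1), n, k_max, byrow = TRUE)
    M <- Mfull; V <- Vfull
    if (any(sel)) {
      Xi <- Xo[sel, , drop = FALSE]
      Sm <- matrix(S, n_c, k_max, byrow = TRUE) - Xi
      m_loo <- Sm / (n_c - 1)
      ss_loo <- matrix(SS, n_c, k_max, byrow = TRUE) - Xi^2
      v_loo <- (ss_loo - Sm^2 / (n_c - 1)) / (n_c - 2)
      M[sel, ] <- m_loo
      V[sel, ] <- v_loo
    }
    V <- pmax(V, matrix(floor_v, n, k_max, byrow = TRUE))
    ll[[cls + 1L]] <- -0.5 * log(2 * pi * V) - (Xo - M)^2 / (2 * V)
  }
  L0 <- t(apply(ll[[1]], 1L, cumsum)) + log(priors[1])
  L1 <- t(apply(ll[[2]], 1L, cumsum)) + log(priors[2])
  if (k_max == 1L) { L0 <- t(L0); L1 <- t(L1) }
  1 / (1 + exp(L0 - L1))
}

#' Forward selection of the optimal subset size
#'
#' Walks the nested ranked prefixes `S_1 ... S_k_max`, computing for each
#' the leave-one-out misclassification rate of the Gaussian naive Bayes
#' classifier (equal priors, 0.5 posterior threshold) on the data handed
#' in, and returns the smallest prefix size attaining the minimum error.
#' The caller is responsible for handing in training data only, so
#' selection never sees test samples.
#'
#' @param ranking A `tumortex_ranking`.
#' @param table Cohort tibble or feature matrix (same columns the ranking
#'   was built on).
#' @param labels Class vector when `table` is a matrix.
#' @param k_max Largest subset size to consider; default
#'   `min(n_ranked, n - 2)`.
#' @param family Family filter matching the one used for the ranking.
#' @return A `tumortex_selection`: `O` (optimal size), `subset` (first `O`
#'   ranked indices), `subset_names`, `error_trace`.
#' @export
forward_select <- function(ranking, table, labels = NULL, k_max = NULL,
                           family = "all") {
  if (is.matrix(table)) {
    X <- table; y <- as.integer(labels)
  } else {
    xy <- .table_xy(table, family)
    X <- xy$X; y <- xy$y
  }
  if (min(sum(y == 0L), sum(y == 1L)) < 3L) {
    abort("each class needs >= 3 samples for internal leave-one-out",
          class = "tumortex_cohort_error")
  }
  if (is.null(k_max)) k_max <- min(ranking$n_ranked, nrow(X) - 2L)
  k_max <- min(k_max, length(ranking$order))
  post <- .nb_loo_posteriors(X, y, ranking$order, k_max)
  pred <- post >= 0.5
  e <- unname(colMeans(pred != matrix(y == 1L, nrow(X), k_max)))
  O <- which.min(e)                          # first k attaining the minimum
  structure(
    list(O = O, subset = ranking$order[seq_len(O)],
         subset_names = ranking$feature_names[ranking$order[seq_len(O)]],
         error_trace = e),
    class = "tumortex_selection"
  )
}
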