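test_that("fuzzification forms a partition of unity with sensible extremes", {
  fz <- fuzzify(c(0, 1, 2, 3, 4, 5, 6, 10, 20), 3)
  expect_equal(rowSums(fz$membership), rep(1, 9))
  expect_true(all(fz$membership >= 0 & fz$membership <= 1))

  # constant variable: all mass in the first set
  fc <- fuzzify(rep(3.3, 6), 3)
  expect_equal(fc$membership[, 1], rep(1, 6))
  expect_equal(rowSums(fc$membership), rep(1, 6))

  # a sample sitting exactly at a set center has membership 1 there
  x <- 0:10
  fz2 <- fuzzify(x, 3)
  mid <- which(rank(x) == unname(quantile(rank(x), 0.5)))
  expect_equal(fz2$membership[mid, 2], 1)
})

test_that("fuzzy mutual information matches hand computation and axioms", {
  # crisp halves: MI(a, a) = 1 bit (entropy of a uniform binary marginal)
  a <- fuzzify(c(0, 0, 1, 1), 2)
  expect_equal(fuzzy_mutual_information(a, a), 1)

  set.seed(3); x <- rnorm(500); y <- rnorm(500)
  fa <- fuzzify(x, 3); fb <- fuzzify(y, 3)
  expect_lt(fuzzy_mutual_information(fa, fb), 0.02)  # near-independent
  expect_equal(fuzzy_mutual_information(fa, fb),
               fuzzy_mutual_information(fb, fa), tolerance = 1e-12)
  expect_gte(fuzzy_mutual_information(fa, fa), fuzzy_mutual_information(fa, fb))

  fconst <- fuzzify(rep(1, 500), 3)
  expect_equal(fuzzy_mutual_information(fconst, fa), 0)

  expect_error(fuzzy_mutual_information(fuzzify(1:4, 2), fuzzify(1:6, 2)),
               class = "tumortex_alignment_error")
})

test_that("fMRMR ranks relevance first and penalizes redundancy", {
  set.seed(7); n <- 40
  lab <- rep(0:1, each = 20)
  f1 <- lab + rnorm(n, sd = 0.3)
  f2 <- f1 + rnorm(n, sd = 0.01)   # near-copy of f1
  f3 <- rnorm(n)                   # pure noise
  X <- cbind(f1 = f1, f2 = f2, f3 = f3)
  rk <- fmrmr_rank(X, lab)
  expect_equal(rk$order[1], which.max(rk$relevance))
  expect_equal(rk$order, c(1L, 3L, 2L))  # redundancy defers the copy

  # identical features: ties break to ascending index
  Xt <- cbind(a = f1, b = f1, c = f1)
  expect_equal(fmrmr_rank(Xt, lab)$order, 1:3)
})

test_that("ranking is invariant to strictly monotone feature transforms", {
  set.seed(11); n <- 30
  lab <- rep(0:1, each = 15)
  X <- matrix(rnorm(n * 5), n, 5)
  X[, 1] <- X[, 1] + lab
  Xm <- X
  Xm[, 1] <- exp(X[, 1])
  Xm[, 3] <- X[, 3]^3
  expect_equal(fmrmr_rank(X, lab)$order, fmrmr_rank(Xm, lab)$order)
})

test_that("forward selection returns the smallest subset at minimum error", {
  set.seed(5); n <- 30
  lab <- rep(0:1, each = 15)
  sep <- lab * 10 + rnorm(n, sd = 0.1)     # perfectly separating
  X <- cbind(sep = sep, matrix(rnorm(n * 4), n, 4))
  rk <- fmrmr_rank(X, lab)
  sel <- forward_select(rk, X, lab)
  expect_equal(sel$O, 1L)
  expect_equal(sel$error_trace[1], 0)
  expect_equal(sel$subset, rk$order[1])
  expect_equal(sel$subset_names, "sep")

  # nestedness of the ranked prefixes
  expect_true(all(rk$order[seq_len(sel$O)] %in% rk$order[seq_len(sel$O + 1)]))
})

test_that("the internal LOO error matches a direct naive Bayes round", {
  set.seed(13); n <- 24
  lab <- rep(0:1, each = 12)
  X <- cbind(a = lab + rnorm(n, sd = 0.8), b = rnorm(n))
  rk <- fmrmr_rank(X, lab)
  sel <- forward_select(rk, X, lab, k_max = 2)
  # recompute e_1 by explicitly refitting on each leave-one-out split
  errs <- vapply(seq_len(n), function(i) {
    m <- fit_gaussian_nb(X[-i, rk$order[1], drop = FALSE], lab[-i])
    p <- predict_posterior(m, X[i, rk$order[1], drop = FALSE])
    (p >= 0.5) != (lab[i] == 1)
  }, logical(1))
  expect_equal(sel$error_trace[1], mean(errs))
})
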