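# Planted-signal feature table for selection-recovery checks: features 1
# and 2 are complementary halves of one signal (a shared nuisance factor z
# with opposite signs plus the class shift), so each alone misclassifies
# some samples while the pair is jointly near-perfect; the remaining
# features are pure noise.
planted_table <- function(seed, n = 40, D = 50, delta = 2,
                          z_sd = 0.8, eps_sd = 0.05) {
  set.seed(seed)
  lab <- rep(0:1, each = n / 2)
  z <- rnorm(n, sd = z_sd)
  X <- matrix(rnorm(n * D), n, D)
  X[, 1] <- z + delta * lab + rnorm(n, sd = eps_sd)
  X[, 2] <- -z + delta * lab + rnorm(n, sd = eps_sd)
  colnames(X) <- paste0("f", seq_len(D))
  list(X = X, y = lab)
}
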