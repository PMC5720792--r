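# Internal numeric helpers shared across feature families.

# log2 with the 0*log(0) = 0 convention
.xlog2 <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

.shannon_entropy <- function(p) {
  -sum(.xlog2(p))
}

# Sample skewness / excess kurtosis with a zero-variance convention of 0,
# so degenerate (constant) regions still yield finite feature vectors.
.skewness <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (n < 2 || !is.finite(s) || s == 0) return(0)
  m <- mean(x)
  mean((x - m)^3) / (sqrt(mean((x - m)^2)))^3
}

.kurtosis_excess <- function(x) {
  s <- sd(x)
  if (length(x) < 2 || !is.finite(s) || s == 0) return(0)
  m <- mean(x)
  mean((x - m)^4) / (mean((x - m)^2))^2 - 3
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Keeps generators deterministic without touching
# the global stream.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

# Deterministic per-item substream seed (kept below 2^31).
.derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807 + 12345) %% 2147483563)
}

# Gaussian blur of a vector (reflective padding).
.smooth1d <- function(v, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  vp <- c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1L]))
  as.numeric(stats::filter(vp, k, sides = 2))[(half + 1L):(half + length(v))]
}

# Separable Gaussian blur of a matrix (reflective padding).
.smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_filter <- function(v) {
    vp <- c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1L]))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1L):(half + length(v))]
  }
  m1 <- apply(m, 2L, pad_filter)
  t(apply(m1, 1L, pad_filter))
}

# Overlapping-region index pairs for an integer pixel offset (drow, dcol):
# returns row/col indices such that A[r1, c1] and A[r2, c2] are the pixel and
# its displaced partner, or NULL if there is no overlap.
.offset_overlap <- function(nr, nc, drow, dcol) {
  r1 <- max(1L, 1L - drow):min(nr, nr - drow)
  c1 <- max(1L, 1L - dcol):min(nc, nc - dcol)
  if (length(r1) < 1L || length(c1) < 1L || r1[1] > r1[length(r1)] || c1[1] > c1[length(c1)]) {
    return(NULL)
  }
  list(r1 = r1, c1 = c1, r2 = r1 + drow, c2 = c1 + dcol)
}

# Displacement (drow, dcol) for a co-occurrence direction angle (degrees,
# one of 0/45/90/135) at pixel distance d, in matrix (row-down) coordinates.
.direction_offset <- function(angle, d) {
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    abort(sprintf("unsupported co-occurrence direction: %s", angle),
          class = "tumortex_parameter_error")
  )
}

.stop_degenerate <- function(msg) {
  abort(msg, class = "tumortex_degenerate_roi_error")
}
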