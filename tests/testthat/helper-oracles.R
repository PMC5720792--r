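# Independent brute-force oracles for the texture operators. These walk
# every pixel (pair) explicitly and share no code with the package
# internals they check.

make_roi <- function(I, mask = NULL, slice_index = 1L) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(I), ncol(I))
  tumortex:::new_slice_roi(I, mask, slice_index)
}

random_roi <- function(n = 7, seed = 1, mask_frac = 1, lo = 0, hi = 100) {
  set.seed(seed)
  I <- matrix(runif(n * n, lo, hi), n, n)
  mask <- matrix(TRUE, n, n)
  if (mask_frac < 1) {
    drop <- sample(n * n, round((1 - mask_frac) * n * n))
    mask[drop] <- FALSE
  }
  make_roi(I, mask)
}

rot90_roi <- function(roi) {
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  tumortex:::new_slice_roi(rot(roi$intensities), rot(roi$mask), roi$slice_index)
}

# offsets used by the oracles, written out by hand per direction
oracle_offset <- function(angle, d) {
  list("0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
       "135" = c(-d, -d))[[as.character(angle)]]
}

# GLCM by explicit enumeration of every ordered in-mask pixel pair.
oracle_glcm <- function(levels, d, angles, N) {
  nr <- nrow(levels); nc <- ncol(levels)
  acc <- matrix(0, N, N)
  used <- 0
  for (ang in angles) {
    off <- oracle_offset(ang, d)
    M <- matrix(0, N, N)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- levels[r, c]; b <- levels[r2, c2]
      if (a > 0 && b > 0) {
        M[a, b] <- M[a, b] + 1
        M[b, a] <- M[b, a] + 1
      }
    }
    if (sum(M) > 0) {
      acc <- acc + M / sum(M)
      used <- used + 1
    }
  }
  acc / used
}

# Run-length matrix by explicit run walking.
oracle_rlm <- function(levels, direction, N, lmax) {
  nr <- nrow(levels); nc <- ncol(levels)
  step <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
               "135" = c(-1, -1))[[as.character(direction)]]
  R <- matrix(0, N, lmax)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  at <- function(r, c) if (inside(r, c)) levels[r, c] else 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- levels[r, c]
    if (v == 0L) next
    # run starts here iff the predecessor is absent or different
    if (at(r - step[1], c - step[2]) == v) next
    len <- 1
    r2 <- r + step[1]; c2 <- c + step[2]
    while (at(r2, c2) == v) {
      len <- len + 1
      r2 <- r2 + step[1]; c2 <- c2 + step[2]
    }
    R[v, len] <- R[v, len] + 1
  }
  R
}

# Sobel gradients at one pixel by direct kernel evaluation.
oracle_sobel <- function(I, r, c) {
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  ky <- rbind(c(1, 2, 1), c(0, 0, 0), c(-1, -2, -1))
  gx <- 0; gy <- 0
  for (dr in -1:1) for (dc in -1:1) {
    gx <- gx + kx[dr + 2, dc + 2] * I[r + dr, c + dc]
    gy <- gy + ky[dr + 2, dc + 2] * I[r + dr, c + dc]
  }
  c(gx = gx, gy = gy)
}

# ACM by explicit pair enumeration over valid pixels.
oracle_acm <- function(bins, valid, mag, l, angles, n_theta, weighted) {
  nr <- nrow(bins); nc <- ncol(bins)
  acc <- matrix(0, n_theta, n_theta)
  used <- 0
  for (ang in angles) {
    off <- oracle_offset(ang, l)
    M <- matrix(0, n_theta, n_theta)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!valid[r, c] || !valid[r2, c2]) next
      a <- bins[r, c]; b <- bins[r2, c2]
      w <- if (weighted) mag[r, c] + mag[r2, c2] else 1
      M[a, b] <- M[a, b] + w
      M[b, a] <- M[b, a] + w
    }
    if (sum(M) > 0) {
      acc <- acc + M / sum(M)
      used <- used + 1
    }
  }
  acc / used
}

# LBP code of one pixel by direct neighborhood enumeration.
oracle_lbp <- function(I, r, c) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  code <- 0
  for (k in 1:8) {
    nb <- I[r + offs[[k]][1], c + offs[[k]][2]]
    if (nb >= I[r, c]) code <- code + 2^(k - 1)
  }
  as.integer(code)
}

# DBC local fractal dimension of one window, independently re-derived.
oracle_dbc <- function(win, sizes = c(2, 3, 7)) {
  M <- nrow(win)
  G <- max(win) - min(win)
  xs <- c(); ys <- c()
  for (s in sizes) {
    g <- floor(M / s)
    total <- 0
    for (bi in seq_len(g)) for (bj in seq_len(g)) {
      blk <- win[((bi - 1) * s + 1):(bi * s), ((bj - 1) * s + 1):(bj * s)]
      if (G <= 0) {
        total <- total + 1
      } else {
        h <- s * G / M
        total <- total + ceiling((max(blk) - min(win)) / h - 1e-9) -
          ceiling((min(blk) - min(win)) / h - 1e-9) + 1
      }
    }
    xs <- c(xs, log(g)); ys <- c(ys, log(total))
  }
  unname(coef(lm(ys ~ xs))[2])
}

# AUC as the exhaustive pairwise rank statistic.
oracle_rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
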