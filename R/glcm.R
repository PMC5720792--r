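# Tabulate level pairs (a, b) over an integer offset, both pixels in-mask
# (codes > 0), optionally weighted; counts the pair in both directions so
# the result is symmetric.
.pair_accumulate <- function(levels, drow, dcol, N, weights = NULL) {
  ov <- .offset_overlap(nrow(levels), ncol(levels), drow, dcol)
  M <- matrix(0, N, N)
  if (is.null(ov)) return(M)
  a <- levels[ov$r1, ov$c1, drop = FALSE]
  b <- levels[ov$r2, ov$c2, drop = FALSE]
  keep <- a > 0L & b > 0L
  if (!any(keep)) return(M)
  ai <- a[keep]; bi <- b[keep]
  if (is.null(weights)) {
    w <- rep(1, length(ai))
  } else {
    wa <- weights[ov$r1, ov$c1, drop = FALSE]
    wb <- weights[ov$r2, ov$c2, drop = FALSE]
    w <- wa[keep] + wb[keep]
  }
  idx <- (bi - 1L) * N + ai
  tab <- rowsum(c(w, w), c(idx, (ai - 1L) * N + bi))
  M[as.integer(rownames(tab))] <- tab[, 1]
  M
}

#' Gray-level co-occurrence matrix
#'
#' Counts in-mask gray-level pairs at pixel distance `d` along each
#' direction, symmetrically (each pair in both orders), normalizes each
#' directional matrix to a probability matrix, and averages over the
#' direction set to obtain a rotation-invariant resultant matrix.
#'
#' @param qroi A `tumortex_qroi` from [quantize_roi()].
#' @param d Pixel distance (>= 1).
#' @param angles Direction set in degrees (subset of 0/45/90/135).
#' @return A `tumortex_comat` with fields `P` (N x N, sums to 1), `N`,
#'   `kind = "glcm"`.
#' @export
compute_glcm <- function(qroi, d = 2L, angles = c(0, 45, 90, 135)) {
  stopifnot(d >= 1)
  N <- qroi$N
  acc <- matrix(0, N, N)
  n_used <- 0L
  for (ang in angles) {
    off <- .direction_offset(ang, d)
    M <- .pair_accumulate(qroi$levels, off[1], off[2], N)
    s <- sum(M)
    if (s > 0) {
      acc <- acc + M / s
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) {
    .stop_degenerate("no valid in-mask pixel pair at any direction")
  }
  structure(list(P = acc / n_used, N = N, kind = "glcm"),
            class = "tumortex_comat")
}

#' Nineteen co-occurrence statistics
#'
#' The 14 Haralick statistics (energy, contrast, correlation, variance,
#' inverse difference moment, sum average, sum variance, sum entropy,
#' entropy, difference variance, difference entropy, the two information
#' measures of correlation, maximal correlation coefficient) followed by
#' inertia, cluster shade, cluster prominence, Renyi entropy of order `q`,
#' and Tsallis entropy of order `r`. All entropies use base-2 logarithms
#' with the `0 log 0 = 0` convention. The Tsallis value follows the form
#' `sum(P^r) / (1 - r)`; set `tsallis_conventional = TRUE` for
#' `(1 - sum(P^r)) / (r - 1)`.
#'
#' The maximal correlation coefficient is the square root of the
#' second-largest eigenvalue of the Q matrix restricted to levels with
#' positive marginal mass; when that is undefined (fewer than two occupied
#' levels, or numerical failure) it falls back to 0.
#'
#' @param M A `tumortex_comat` (normalized).
#' @param q Renyi order.
#' @param r Tsallis order.
#' @param tsallis_conventional Use the conventional Tsallis numerator.
#' @return Named numeric vector of length 19 (`s1`..`s19`).
#' @export
cooccurrence_stats19 <- function(M, q = 8, r = 2, tsallis_conventional = FALSE) {
  P <- M$P
  N <- M$N
  i <- matrix(seq_len(N), N, N)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(N) * px)
  muy <- sum(seq_len(N) * py)
  sdx <- sqrt(sum((seq_len(N) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(N) - muy)^2 * py))

  # p_{x+y}(k), k = 2..2N and p_{x-y}(k), k = 0..N-1
  psum <- vapply(2:(2 * N), function(k) sum(P[i + j == k]), numeric(1))
  ks <- 2:(2 * N)
  pdiff <- vapply(0:(N - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  kd <- 0:(N - 1)

  energy <- sum(P^2)
  contrast <- sum(kd^2 * pdiff)
  correlation <- if (sdx > 0 && sdy > 0) {
    (sum(i * j * P) - mux * muy) / (sdx * sdy)
  } else 0
  variance <- sum((i - mux)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  sum_ent <- .shannon_entropy(psum)
  entropy <- .shannon_entropy(P)
  mud <- sum(kd * pdiff)
  diff_var <- sum((kd - mud)^2 * pdiff)
  diff_ent <- .shannon_entropy(pdiff)

  hx <- .shannon_entropy(px)
  hy <- .shannon_entropy(py)
  pxy_outer <- outer(px, py)
  pos <- P > 0 & pxy_outer > 0
  hxy1 <- -sum(P[pos] * log2(pxy_outer[pos]))
  hxy2 <- .shannon_entropy(pxy_outer)
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  mcc <- 0
  sup <- which(px > 0)
  if (length(sup) >= 2L) {
    Ps <- P[sup, sup, drop = FALSE]
    pxs <- px[sup]; pys <- py[sup]
    if (all(pys > 0)) {
      Q <- (Ps / pxs) %*% t(Ps / matrix(pys, length(sup), length(sup), byrow = TRUE))
      ev <- tryCatch(sort(Re(eigen(Q, only.values = TRUE)$values),
                          decreasing = TRUE),
                     error = function(e) NULL)
      if (!is.null(ev) && length(ev) >= 2L && is.finite(ev[2]) && ev[2] >= 0) {
        mcc <- sqrt(ev[2])
      }
    }
  }

  inertia <- sum((i - j)^2 * P)
  shade <- sum((i + j - mux - muy)^3 * P)
  prominence <- sum((i + j - mux - muy)^4 * P)
  renyi <- (1 / (1 - q)) * log2(sum(P[P > 0]^q))
  tsallis <- if (tsallis_conventional) {
    (1 - sum(P[P > 0]^r)) / (r - 1)
  } else {
    (1 / (1 - r)) * sum(P[P > 0]^r)
  }

  out <- c(energy, contrast, correlation, variance, idm, sum_avg, sum_var,
           sum_ent, entropy, diff_var, diff_ent, imc1, imc2, mcc,
           inertia, shade, prominence, renyi, tsallis)
  out[!is.finite(out)] <- 0
  names(out) <- paste0("s", 1:19)
  out
}
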