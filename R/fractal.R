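# Multi-level Otsu thresholds by dynamic programming on the in-mask
# histogram: maximizes the between-class term sum(w * mu^2) over class
# partitions of the binned gray range.
.multi_otsu <- function(values, n_thresholds, n_bins = 128L) {
  rng <- range(values)
  if (diff(rng) <= 0) return(numeric(0))
  bin <- pmin(floor((values - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  h <- tabulate(bin, nbins = n_bins) / length(values)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  W <- cumsum(h); M <- cumsum(h * mids)
  seg_w <- outer(W, c(0, head(W, -1)), "-")       # seg_w[j, i] = weight of bins i..j
  seg_m <- outer(M, c(0, head(M, -1)), "-")
  cost <- ifelse(seg_w > 1e-12, seg_m^2 / pmax(seg_w, 1e-12), 0)
  cost[lower.tri(cost, diag = TRUE) == FALSE] <- -Inf  # need j >= i
  n_classes <- n_thresholds + 1L
  # dp[c, j]: best objective for first c classes covering bins 1..j
  dp <- matrix(-Inf, n_classes, n_bins)
  choice <- array(0L, dim = c(n_classes, n_bins))
  dp[1, ] <- cost[, 1]
  for (cl in 2:n_classes) {
    for (j in cl:n_bins) {
      prev <- dp[cl - 1, (cl - 1):(j - 1)] + cost[j, cl:j]
      b <- which.max(prev)
      dp[cl, j] <- prev[b]
      choice[cl, j] <- (cl - 1) + b - 1L   # last bin of previous class
    }
  }
  cuts <- integer(n_thresholds)
  j <- n_bins
  for (cl in n_classes:2) {
    cuts[cl - 1L] <- choice[cl, j]
    j <- choice[cl, j]
  }
  rng[1] + cuts * diff(rng) / n_bins   # upper edges of the cut bins
}

# Border pixels of a binary in-mask region: foreground with at least one
# in-mask background 4-neighbor. Out-of-mask neighbors are ignored.
.region_border <- function(fg, mask) {
  nr <- nrow(fg); nc <- ncol(fg)
  bg <- mask & !fg
  nb_bg <- matrix(FALSE, nr, nc)
  for (off in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    ov <- .offset_overlap(nr, nc, off[1], off[2])
    tmp <- matrix(FALSE, nr, nc)
    tmp[ov$r1, ov$c1] <- bg[ov$r2, ov$c2]
    nb_bg <- nb_bg | tmp
  }
  fg & mask & nb_bg
}

# Box-counting fractal dimension of a binary point set: slope of
# log(occupied boxes) vs log(1/size) over dyadic sizes, by least squares.
.boxcount_fd <- function(pts_rc, sizes, nr, nc) {
  if (nrow(pts_rc) == 0L) return(0)
  sizes <- sizes[sizes <= max(nr, nc)]
  if (length(sizes) < 2L) return(0)
  counts <- vapply(sizes, function(e) {
    nrow(unique(cbind((pts_rc[, 1] - 1L) %/% e, (pts_rc[, 2] - 1L) %/% e)))
  }, numeric(1))
  x <- log(1 / sizes)
  y <- log(counts)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Segmentation-based fractal texture analysis (F1 block)
#'
#' Decomposes the ROI with `n_thresholds` multi-level Otsu thresholds of
#' the in-mask histogram into 16 binary images: the band images between
#' consecutive thresholds (the last band closing at the in-mask maximum)
#' and the upper-threshold images above each threshold. Each binary image
#' contributes three values: the box-counting fractal dimension of its
#' region borders, the mean in-mask gray level of its foreground, and its
#' foreground pixel count. Empty regions contribute a (0, 0, 0) triple.
#'
#' @param roi A `tumortex_roi`.
#' @param n_thresholds Number of Otsu thresholds (default 8, giving 16
#'   binary images and 48 features).
#' @param box_sizes Box-counting grid sizes.
#' @return Named numeric vector of length `6 * n_thresholds`.
#' @export
sfta_features <- function(roi, n_thresholds = 8L, box_sizes = c(1L, 2L, 4L, 8L)) {
  v0 <- roi$intensities[roi$mask]
  if (length(v0) == 0L) .stop_degenerate("empty mask")
  # Work on the range-normalized ROI so the whole block is invariant to
  # affine intensity rescaling, consistent with ROI-relative quantization;
  # mean gray levels are therefore reported in [0, 1].
  rng0 <- range(v0)
  I <- roi$intensities
  I <- if (diff(rng0) > 0) (I - rng0[1]) / diff(rng0) else I * 0
  v <- I[roi$mask]
  th <- .multi_otsu(v, n_thresholds)
  th <- unique(th)
  if (length(th) < n_thresholds) {
    warn("degenerate gray range: fewer distinct thresholds than requested")
  }
  vmax <- max(v)
  # Band boundaries partition the in-mask gray range: every in-mask pixel
  # falls in exactly one band image.
  bounds <- c(-Inf, th[-length(th)], vmax)
  n_img <- 2L * n_thresholds
  out <- numeric(3L * n_img)
  for (k in seq_len(n_img)) {
    if (k <= n_thresholds) {
      if (k < length(bounds)) {
        fg <- roi$mask & I > bounds[k] & I <= bounds[k + 1L]
      } else {
        fg <- matrix(FALSE, nrow(I), ncol(I))
      }
    } else {
      k2 <- k - n_thresholds
      fg <- if (k2 <= length(th)) roi$mask & I > th[k2] else
        matrix(FALSE, nrow(I), ncol(I))
    }
    base <- 3L * (k - 1L)
    if (!any(fg)) {
      out[base + 1:3] <- 0
      next
    }
    border <- .region_border(fg, roi$mask)
    out[base + 1L] <- .boxcount_fd(which(border, arr.ind = TRUE), box_sizes,
                                   nrow(I), ncol(I))
    out[base + 2L] <- mean(I[fg])
    out[base + 3L] <- sum(fg)
  }
  names(out) <- paste0("F1_", seq_along(out))
  out
}

#' Differential box-counting fractal-dimension image
#'
#' Treats the intensity surface over each fully in-mask `window` x
#' `window` neighborhood as a 3-D relief and estimates a per-pixel local
#' fractal dimension: the window is partitioned into `g = floor(window /
#' s)` blocks per axis for each box size `s`, boxes of height `s * G /
#' window` (G = window gray range) are stacked, and the count
#' `ceil(max / h) - ceil(min / h) + 1` is accumulated per block. The FD is
#' the least-squares slope of `log(total boxes)` against `log(g)`, so a
#' flat surface yields exactly 2.
#'
#' @param roi A `tumortex_roi`.
#' @param window Odd window size (default 7).
#' @param sizes In-plane box sizes.
#' @return A `tumortex_fdimage` with matrix `fd` and logical `valid`.
#' @export
dbc_fd_image <- function(roi, window = 7L, sizes = c(2L, 3L, 7L)) {
  nr <- nrow(roi$intensities); nc <- ncol(roi$intensities)
  half <- (window - 1L) %/% 2L
  if (nr < window || nc < window) .stop_degenerate("ROI smaller than DBC window")
  m <- roi$mask
  inner_r <- (half + 1L):(nr - half); inner_c <- (half + 1L):(nc - half)
  supp <- matrix(TRUE, length(inner_r), length(inner_c))
  for (dr in -half:half) for (dc in -half:half) {
    supp <- supp & m[inner_r + dr, inner_c + dc]
  }
  if (!any(supp)) .stop_degenerate("no pixel has full in-mask DBC support")

  I <- roi$intensities
  shifted <- function(dr, dc) I[inner_r + dr, inner_c + dc]
  win_max <- matrix(-Inf, length(inner_r), length(inner_c))
  win_min <- matrix(Inf, length(inner_r), length(inner_c))
  for (dr in -half:half) for (dc in -half:half) {
    s <- shifted(dr, dc)
    win_max <- pmax(win_max, s); win_min <- pmin(win_min, s)
  }
  G <- win_max - win_min

  sizes <- sizes[sizes <= window]
  xs <- log(pmax(floor(window / sizes), 1L))
  ys <- matrix(0, length(inner_r) * length(inner_c), length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    g <- floor(window / s)
    h <- s * G / window
    total <- matrix(0, length(inner_r), length(inner_c))
    for (bi in seq_len(g)) for (bj in seq_len(g)) {
      bmax <- matrix(-Inf, length(inner_r), length(inner_c))
      bmin <- matrix(Inf, length(inner_r), length(inner_c))
      for (u in seq_len(s)) for (v in seq_len(s)) {
        dr <- -half + (bi - 1L) * s + (u - 1L)
        dc <- -half + (bj - 1L) * s + (v - 1L)
        sh <- shifted(dr, dc)
        bmax <- pmax(bmax, sh); bmin <- pmin(bmin, sh)
      }
      cnt <- matrix(1, length(inner_r), length(inner_c))
      posG <- G > 0
      # the 1e-9 guard keeps counts stable when floating-point jitter puts
      # a relief value exactly on a box boundary
      cnt[posG] <- ceiling((bmax[posG] - win_min[posG]) / h[posG] - 1e-9) -
        ceiling((bmin[posG] - win_min[posG]) / h[posG] - 1e-9) + 1
      total <- total + cnt
    }
    ys[, si] <- log(as.vector(total))
  }
  xbar <- mean(xs)
  slope <- as.vector(ys %*% (xs - xbar)) / sum((xs - xbar)^2)
  fd <- matrix(NA_real_, nr, nc)
  fd[inner_r, inner_c] <- matrix(slope, length(inner_r), length(inner_c))
  valid <- matrix(FALSE, nr, nc)
  valid[inner_r, inner_c] <- supp
  fd[!valid] <- NA_real_
  structure(list(fd = fd, valid = valid), class = "tumortex_fdimage")
}

#' Cross-slice FD-image features (F2_1--F2_6)
#'
#' Per slice, the mean, standard deviation, and lacunarity
#' (`E[X^2] / E[X]^2 - 1`) of the valid per-pixel fractal dimensions are
#' computed; the block reports the maximum and the average of each
#' statistic over the slices, in the order max then mean of (mean, sd,
#' lacunarity).
#'
#' @param fd_images List of `tumortex_fdimage`, one per slice.
#' @return Named numeric vector of length 6.
#' @export
fd2_features <- function(fd_images) {
  stats <- vapply(fd_images, function(im) {
    x <- im$fd[im$valid]
    if (length(x) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    mu <- mean(x)
    lac <- if (mu != 0) mean(x^2) / mu^2 - 1 else 0
    c(mu, if (length(x) > 1) sd(x) else 0, lac)
  }, numeric(3))
  if (all(is.na(stats))) {
    warn("all slices degenerate for the FD image; zero-filling F2 block")
    out <- rep(0, 6)
  } else {
    mx <- apply(stats, 1L, max, na.rm = TRUE)
    mn <- apply(stats, 1L, mean, na.rm = TRUE)
    out <- c(mx[1], mx[2], mx[3], mn[1], mn[2], mn[3])
  }
  names(out) <- paste0("F2_", 1:6)
  out
}
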