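# Neighbor offsets in circular order starting east, counter-clockwise
# (image rows grow downward, so "up" is a negative row step).
.lbp_offsets <- matrix(c(0L, 1L, -1L, 1L, -1L, 0L, -1L, -1L,
                         0L, -1L, 1L, -1L, 1L, 0L, 1L, 1L),
                       ncol = 2L, byrow = TRUE)

.lbp_rol <- function(code, s) {
  # circular left shift of an 8-bit code by s
  s <- s %% 8L
  bitwAnd(bitwOr(bitwShiftL(code, s), bitwShiftR(code, 8L - s)), 255L)
}

# Static 8-bit code tables, built once at load.
.lbp_tables <- local({
  codes <- 0:255
  bits <- sapply(0:7, function(k) bitwAnd(bitwShiftR(codes, k), 1L))
  trans <- rowSums(bits != bits[, c(2:8, 1)])
  uniform <- trans <= 2L
  min_rot <- vapply(codes, function(cd) {
    min(vapply(0:7, function(s) .lbp_rol(cd, s), integer(1)))
  }, integer(1))
  n_ones <- rowSums(bits)
  # 58 uniform codes in ascending order; bin 59 pools non-uniform codes
  u_codes <- codes[uniform]
  ulbp_bin <- rep(59L, 256)
  ulbp_bin[uniform] <- match(codes[uniform], u_codes)
  # RI-ULBP: uniform classes by number of ones (0..8 -> bins 1..9), bin 10
  # pools non-uniform codes
  riu_bin <- ifelse(uniform, n_ones + 1L, 10L)
  # RI-LBP: 36 minimal-rotation classes over all codes
  ri_classes <- sort(unique(min_rot))
  ri_bin <- match(min_rot, ri_classes)
  list(uniform = uniform, min_rot = min_rot, n_ones = n_ones,
       ulbp_bin = ulbp_bin, riu_bin = riu_bin, ri_bin = ri_bin,
       n_ri = length(ri_classes))
})

#' Local binary pattern code maps
#'
#' Thresholds the 8 neighbors of every pixel with full in-mask 3x3 support
#' against the center (`neighbor >= center` sets the bit; neighbors ordered
#' circularly starting east, counter-clockwise) and returns the raw 8-bit
#' code map together with its rotation-invariant variant (minimum over the
#' 8 circular shifts) and the rotated-LBP variant, where each code is
#' circularly shifted so the neighbor with the largest absolute intensity
#' difference from the center sits at bit position 0 (ties resolved to the
#' first such neighbor in circular order).
#'
#' @param roi A `tumortex_roi`.
#' @return A `tumortex_lbpmaps` with integer matrices `lbp`, `ri_lbp`,
#'   `rot_lbp` and logical `valid`.
#' @export
lbp_code_maps <- function(roi) {
  nr <- nrow(roi$intensities); nc <- ncol(roi$intensities)
  if (nr < 3 || nc < 3) .stop_degenerate("ROI too small for a 3x3 operator")
  I <- roi$intensities
  m <- roi$mask
  inner_r <- 2:(nr - 1); inner_c <- 2:(nc - 1)
  supp <- matrix(TRUE, length(inner_r), length(inner_c))
  for (dr in -1:1) for (dc in -1:1) {
    supp <- supp & m[inner_r + dr, inner_c + dc]
  }
  if (!any(supp)) .stop_degenerate("no pixel has full in-mask 3x3 support")

  ctr <- I[inner_r, inner_c]
  code <- matrix(0L, length(inner_r), length(inner_c))
  absdiff <- array(0, dim = c(length(inner_r), length(inner_c), 8L))
  for (k in 1:8) {
    nb <- I[inner_r + .lbp_offsets[k, 1], inner_c + .lbp_offsets[k, 2]]
    code <- code + bitwShiftL(as.integer(nb >= ctr), k - 1L)
    absdiff[, , k] <- abs(nb - ctr)
  }
  dom <- apply(absdiff, c(1, 2), which.max) - 1L   # dominant neighbor index
  # rotating the code right by `dom` brings the dominant neighbor to bit 0
  rot <- matrix(mapply(function(cd, d) {
    bitwAnd(bitwOr(bitwShiftR(cd, d), bitwShiftL(cd, 8L - d)), 255L)
  }, code, dom), nrow(code), ncol(code))

  pad <- function(x, fill) {
    full <- matrix(fill, nr, nc)
    full[inner_r, inner_c] <- x
    full
  }
  valid <- pad(supp, FALSE)
  lbp <- pad(code, NA_integer_); lbp[!valid] <- NA_integer_
  ri <- pad(matrix(.lbp_tables$min_rot[code + 1L], nrow(code)), NA_integer_)
  ri[!valid] <- NA_integer_
  rotm <- pad(rot, NA_integer_); rotm[!valid] <- NA_integer_
  structure(list(lbp = lbp, ri_lbp = ri, rot_lbp = rotm, valid = valid),
            class = "tumortex_lbpmaps")
}

.norm_hist <- function(codes, bins) {
  h <- tabulate(codes, nbins = bins)
  if (sum(h) > 0) h / sum(h) else rep(0, bins)
}

.hist_stats4 <- function(p) {
  c(sd(p), .skewness(p), .kurtosis_excess(p), .shannon_entropy(p))
}

# LBP histogram-Fourier block for P = 8: |H(n, u)| for the 7 non-constant
# uniform rows (n ones, rotations r) at u = 0..4, plus the all-zeros,
# all-ones, and pooled non-uniform bins.
.lbp_hf <- function(ulbp_p, lbp_p) {
  hf <- numeric(0)
  for (n in 1:7) {
    codes_nr <- vapply(0:7, function(r) .lbp_rol(as.integer(2^n - 1), r),
                       integer(1))
    h_nr <- lbp_p[codes_nr + 1L]
    for (u in 0:4) {
      H <- sum(h_nr * exp(-2i * pi * u * (0:7) / 8))
      hf <- c(hf, Mod(H))
    }
  }
  c(hf, lbp_p[1], lbp_p[256], 1 - sum(lbp_p[.lbp_tables$uniform]))
}

#' The 128-feature LBP block
#'
#' Concatenates the normalized 59-bin uniform-LBP histogram (L1--L59), the
#' normalized 10-bin rotation-invariant uniform-LBP histogram (L60--L69),
#' 21 histogram statistics (L70--L90), and 38 LBP histogram-Fourier
#' magnitudes (L91--L128). The 21 statistics are standard deviation,
#' skewness, excess kurtosis, and entropy of the normalized histograms of
#' the raw 256-bin LBP, ULBP, RI-ULBP, 36-bin RI-LBP, and 256-bin rotated
#' LBP (20 values) plus the entropy of the normalized histogram-Fourier
#' magnitude spectrum. The Fourier block holds `|H(n, u)|` for the seven
#' non-constant uniform rows at frequencies u = 0..4 (35 values) and the
#' three rotation-invariant singleton bins (all-zeros, all-ones, pooled
#' non-uniform mass).
#'
#' @param roi A `tumortex_roi`.
#' @return Named numeric vector of length 128.
#' @export
lbp_feature_block <- function(roi) {
  maps <- lbp_code_maps(roi)
  codes <- maps$lbp[maps$valid]
  lbp_p <- .norm_hist(codes + 1L, 256L)
  ulbp_p <- .norm_hist(.lbp_tables$ulbp_bin[codes + 1L], 59L)
  riu_p <- .norm_hist(.lbp_tables$riu_bin[codes + 1L], 10L)
  ri_p <- .norm_hist(.lbp_tables$ri_bin[codes + 1L], .lbp_tables$n_ri)
  rot_p <- .norm_hist(maps$rot_lbp[maps$valid] + 1L, 256L)

  hf <- .lbp_hf(ulbp_p, lbp_p)
  hf_p <- if (sum(hf) > 0) hf / sum(hf) else hf
  stats21 <- c(.hist_stats4(lbp_p), .hist_stats4(ulbp_p), .hist_stats4(riu_p),
               .hist_stats4(ri_p), .hist_stats4(rot_p),
               .shannon_entropy(hf_p))
  out <- c(ulbp_p, riu_p, stats21, hf)
  names(out) <- paste0("L", seq_len(128L))
  out
}

#' Intensity-histogram features (I1--I5)
#'
#' First-order statistics of the in-mask intensities: mean, standard
#' deviation, skewness, excess kurtosis, and the entropy of the normalized
#' intensity histogram over `bins` equal-width bins spanning the in-mask
#' range. Zero-variance regions yield sd 0, skewness 0, kurtosis 0, and
#' entropy 0.
#'
#' @param roi A `tumortex_roi`.
#' @param bins Histogram bin count.
#' @return Named numeric vector of length 5.
#' @export
intensity_histogram_features <- function(roi, bins = 16L) {
  v <- roi$intensities[roi$mask]
  if (length(v) == 0L) .stop_degenerate("empty mask")
  rng <- range(v)
  ent <- if (diff(rng) <= 0) 0 else {
    idx <- pmin(floor((v - rng[1]) / diff(rng) * bins) + 1L, bins)
    .shannon_entropy(.norm_hist(idx, bins))
  }
  c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
    skewness = .skewness(v), kurtosis = .kurtosis_excess(v), entropy = ent)
}
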