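#' Sobel gradient field of a slice ROI
#'
#' Applies the 3x3 Sobel operator to the ROI. Only pixels whose full 3x3
#' neighborhood lies in-mask are marked valid, so intensities outside the
#' tumor never contaminate the gradients. Angles are `atan2(gy, gx)` mapped
#' to \[0, 360) degrees with the x gradient increasing to the right (column
#' direction) and the y gradient increasing upward, so a left-to-right
#' intensity ramp has angle 0.
#'
#' @param roi A `tumortex_roi`.
#' @return A `tumortex_gradfield` with matrices `angle` (degrees),
#'   `magnitude`, and logical `valid`.
#' @export
sobel_gradients <- function(roi) {
  nr <- nrow(roi$intensities); nc <- ncol(roi$intensities)
  if (nr < 3 || nc < 3) .stop_degenerate("ROI too small for a 3x3 operator")
  I <- roi$intensities
  m <- roi$mask
  # full 3x3 in-mask support
  valid <- matrix(FALSE, nr, nc)
  inner_r <- 2:(nr - 1); inner_c <- 2:(nc - 1)
  supp <- matrix(TRUE, length(inner_r), length(inner_c))
  for (dr in -1:1) for (dc in -1:1) {
    supp <- supp & m[inner_r + dr, inner_c + dc]
  }
  valid[inner_r, inner_c] <- supp
  if (!any(valid)) .stop_degenerate("no pixel has full in-mask 3x3 support")

  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  # Sobel correlation kernels; y axis points up (negative row direction)
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  ky <- rbind(c(1, 2, 1), c(0, 0, 0), c(-1, -2, -1))
  for (dr in -1:1) for (dc in -1:1) {
    w_x <- kx[dr + 2, dc + 2]; w_y <- ky[dr + 2, dc + 2]
    if (w_x != 0) gx[inner_r, inner_c] <- gx[inner_r, inner_c] +
        w_x * I[inner_r + dr, inner_c + dc]
    if (w_y != 0) gy[inner_r, inner_c] <- gy[inner_r, inner_c] +
        w_y * I[inner_r + dr, inner_c + dc]
  }
  ang <- (atan2(gy, gx) * 180 / pi) %% 360
  mag <- sqrt(gx^2 + gy^2)
  ang[!valid] <- NA_real_
  mag[!valid] <- 0
  structure(list(angle = ang, magnitude = mag, valid = valid, gx = gx, gy = gy),
            class = "tumortex_gradfield")
}

# Quantize gradient angles into n_theta equal bins over [0, 360); bin 1 is
# [0, 360/n_theta). Zero-magnitude pixels land in bin 1 by convention.
.angle_bins <- function(field, n_theta) {
  bins <- matrix(0L, nrow(field$angle), ncol(field$angle))
  v <- field$valid
  b <- floor(field$angle[v] / (360 / n_theta)) + 1L
  b <- pmin(as.integer(b), as.integer(n_theta))
  b[field$magnitude[v] == 0] <- 1L
  bins[v] <- b
  bins
}

#' Angle co-occurrence matrix (ACM1 / ACM2)
#'
#' Joint occurrences of quantized Sobel gradient orientations for pixel
#' pairs at displacement distance `l` along each direction, restricted to
#' pairs whose two pixels are both valid (full in-mask 3x3 support). With
#' `weighted = FALSE` each pair counts once (occurrence matrix, ACM1); with
#' `weighted = TRUE` each pair contributes the sum of the two pixels'
#' gradient magnitudes (magnitude-response matrix, ACM2). Each directional
#' matrix is normalized to sum to 1 and the four are averaged.
#'
#' @param field A `tumortex_gradfield`.
#' @param l Pixel displacement distance (>= 1).
#' @param n_theta Number of orientation bins.
#' @param weighted `FALSE` for ACM1, `TRUE` for ACM2.
#' @param angles Displacement direction set (degrees).
#' @return A `tumortex_comat` with `kind` `"acm1"` or `"acm2"`.
#' @export
compute_acm <- function(field, l = 1L, n_theta = 8L, weighted = FALSE,
                        angles = c(0, 45, 90, 135)) {
  stopifnot(l >= 1)
  bins <- .angle_bins(field, n_theta)
  w <- if (weighted) field$magnitude else NULL
  acc <- matrix(0, n_theta, n_theta)
  n_used <- 0L
  for (ang in angles) {
    off <- .direction_offset(ang, l)
    M <- .pair_accumulate(bins, off[1], off[2], n_theta, weights = w)
    if (weighted && sum(M) == 0) {
      # an all-zero-magnitude field carries no weight: fall back to
      # occurrence counts, the limit of uniform pair weights
      M <- .pair_accumulate(bins, off[1], off[2], n_theta)
    }
    s <- sum(M)
    if (s > 0) {
      acc <- acc + M / s
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) .stop_degenerate("no valid pixel pair for the ACM")
  structure(list(P = acc / n_used, N = as.integer(n_theta),
                 kind = if (weighted) "acm2" else "acm1"),
            class = "tumortex_comat")
}

#' ACM feature block (A1--A19, M1--M19)
#'
#' Computes the Sobel gradient field of the ROI, forms ACM1 and ACM2, and
#' applies the same 19 co-occurrence statistics used for the GLCM to each.
#'
#' @param roi A `tumortex_roi`.
#' @param config A [tex_config()].
#' @return Named numeric vector of length 38: `acm1.*` then `acm2.*`.
#' @export
acm_feature_block <- function(roi, config = tex_config()) {
  field <- sobel_gradients(roi)
  a1 <- compute_acm(field, config$l, config$n_theta, weighted = FALSE,
                    angles = config$angles)
  a2 <- compute_acm(field, config$l, config$n_theta, weighted = TRUE,
                    angles = config$angles)
  s1 <- cooccurrence_stats19(a1, config$q, config$r, config$tsallis_conventional)
  s2 <- cooccurrence_stats19(a2, config$q, config$r, config$tsallis_conventional)
  c(setNames(s1, paste0("acm1.", names(s1))),
    setNames(s2, paste0("acm2.", names(s2))))
}
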