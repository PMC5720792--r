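# Ordered scan lines of a matrix grid along a run direction. Each line is a
# vector of linear indices traversed in order.
.scan_lines <- function(nr, nc, direction) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  switch(as.character(direction),
    "0"   = lapply(seq_len(nr), function(r) idx[r, ]),
    "90"  = lapply(seq_len(nc), function(c) idx[, c]),
    "45"  = {
      # bottom-left to top-right diagonals: constant r + c
      lapply(2:(nr + nc), function(s) {
        r <- seq(min(nr, s - 1), max(1, s - nc))
        idx[cbind(r, s - r)]
      })
    },
    "135" = {
      # top-left to bottom-right diagonals: constant r - c
      lapply((1 - nc):(nr - 1), function(dd) {
        r <- seq(max(1, 1 + dd), min(nr, nc + dd))
        idx[cbind(r, r - dd)]
      })
    },
    abort(sprintf("unsupported run direction: %s", direction),
          class = "tumortex_parameter_error")
  )
}

#' Gray-level run-length matrix
#'
#' Counts maximal constant-level pixel runs along one direction. Runs are
#' confined to in-mask pixels: a run breaks wherever the scan line leaves
#' the mask.
#'
#' @param qroi A `tumortex_qroi`.
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @return A `tumortex_rlm` with fields `R` (N x Lmax run counts),
#'   `direction`, `n_pixels` (in-mask pixels traversed).
#' @export
compute_rlm <- function(qroi, direction = 0) {
  if (!any(qroi$mask)) .stop_degenerate("empty mask")
  N <- qroi$N
  lmax <- max(nrow(qroi$levels), ncol(qroi$levels))
  R <- matrix(0, N, lmax)
  for (line in .scan_lines(nrow(qroi$levels), ncol(qroi$levels), direction)) {
    vals <- qroi$levels[line]
    rl <- rle(vals)
    keep <- rl$values > 0L
    if (!any(keep)) next
    tab <- rowsum(rep(1, sum(keep)),
                  paste(rl$values[keep], rl$lengths[keep], sep = "_"))
    parts <- strsplit(rownames(tab), "_", fixed = TRUE)
    for (k in seq_along(parts)) {
      lv <- as.integer(parts[[k]][1]); ln <- as.integer(parts[[k]][2])
      R[lv, ln] <- R[lv, ln] + tab[k, 1]
    }
  }
  structure(list(R = R, direction = direction, n_pixels = sum(qroi$mask)),
            class = "tumortex_rlm")
}

.rlm_stats11 <- function(rlm) {
  R <- rlm$R
  n_runs <- sum(R)
  if (n_runs == 0) return(rep(0, 11))
  lev <- seq_len(nrow(R))
  len <- seq_len(ncol(R))
  r_j <- colSums(R)   # runs per length
  r_i <- rowSums(R)   # runs per level
  np <- rlm$n_pixels
  c(
    sre = sum(r_j / len^2) / n_runs,
    lre = sum(r_j * len^2) / n_runs,
    gln = sum(r_i^2) / n_runs,
    rln = sum(r_j^2) / n_runs,
    rp = n_runs / np,
    lgre = sum(r_i / lev^2) / n_runs,
    hgre = sum(r_i * lev^2) / n_runs,
    srlge = sum(R / outer(lev^2, len^2)) / n_runs,
    srhge = sum(R * outer(lev^2, 1 / len^2)) / n_runs,
    lrlge = sum(R * outer(1 / lev^2, len^2)) / n_runs,
    lrhge = sum(R * outer(lev^2, len^2)) / n_runs
  )
}

#' Run-length features (R1--R11)
#'
#' The classical eleven run-length statistics -- short/long run emphasis,
#' gray-level and run-length nonuniformity, run percentage, low/high
#' gray-level run emphasis, and the four joint short/long x low/high
#' combinations -- computed per direction and averaged over 0/45/90/135
#' degrees for rotation invariance.
#'
#' @param qroi A `tumortex_qroi`.
#' @param angles Direction set (degrees).
#' @return Named numeric vector of length 11.
#' @export
rlm_features <- function(qroi, angles = c(0, 45, 90, 135)) {
  per_dir <- vapply(angles,
                    function(a) .rlm_stats11(compute_rlm(qroi, a)),
                    numeric(11))
  out <- rowMeans(per_dir)
  names(out) <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                  "srlge", "srhge", "lrlge", "lrhge")
  out
}
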