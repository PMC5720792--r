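.stat19_suffix <- c("energy", "contrast", "correlation", "variance", "idm",
                    "sum_average", "sum_variance", "sum_entropy", "entropy",
                    "diff_variance", "diff_entropy", "imc1", "imc2", "mcc",
                    "inertia", "cluster_shade", "cluster_prominence",
                    "renyi", "tsallis")
.rlm_suffix <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                 "srlge", "srhge", "lrlge", "lrhge")

.lbp_suffix <- local({
  hists <- c("lbp256", "ulbp", "riulbp", "rilbp36", "rotlbp")
  stats <- c("sd", "skew", "kurt", "entropy")
  hf <- c(paste0("hf_n", rep(1:7, each = 5), "_u", rep(0:4, times = 7)),
          "hf_zeros", "hf_ones", "hf_nonuniform")
  c(paste0("ulbp_", sprintf("%02d", 1:59)),
    paste0("riulbp_", sprintf("%02d", 1:10)),
    paste0(rep(hists, each = 4), "_", rep(stats, times = 5)), "hf_entropy",
    hf)
})

#' The ordered 255-feature registry
#'
#' Returns the fixed, versioned name order of the tumor descriptor:
#' G1--G19 (GLCM), R1--R11 (run length), L1--L128 (LBP), F1_1--F1_48
#' (SFTA), F2_1--F2_6 (DBC fractal-dimension image), I1--I5 (intensity
#' histogram), A1--A19 (ACM1), M1--M19 (ACM2). Each name encodes family,
#' registry index, and meaning, e.g. `glcm.G18_renyi` or
#' `acm2.M11_diff_entropy`. The registry is reconstructed from the
#' per-family counts and orderings of the method description; the indexing
#' resolves the reported selections (e.g. M2 contrast, M4 variance, M6 sum
#' average, M11 difference entropy, M15 inertia).
#'
#' @return Character vector of length 255.
#' @export
feature_names <- function() {
  c(paste0("glcm.G", 1:19, "_", .stat19_suffix),
    paste0("rlm.R", 1:11, "_", .rlm_suffix),
    paste0("lbp.L", 1:128, "_", .lbp_suffix),
    paste0("sfta.F1_", 1:48, "_",
           rep(c("fd", "mean", "size"), times = 16),
           rep(sprintf("_img%02d", 1:16), each = 3)),
    paste0("fd2.F2_", 1:6, "_",
           c("max_mean", "max_sd", "max_lacunarity",
             "mean_mean", "mean_sd", "mean_lacunarity")),
    paste0("ih.I", 1:5, "_", c("mean", "sd", "skewness", "kurtosis", "entropy")),
    paste0("acm1.A", 1:19, "_", .stat19_suffix),
    paste0("acm2.M", 1:19, "_", .stat19_suffix))
}

#' Feature family of each registry position
#'
#' @return Character vector of length 255 with values `glcm`, `rlm`,
#'   `lbp`, `sfta`, `fd2`, `ih`, `acm1`, `acm2`.
#' @export
feature_families <- function() {
  rep(c("glcm", "rlm", "lbp", "sfta", "fd2", "ih", "acm1", "acm2"),
      times = c(19, 11, 128, 48, 6, 5, 19, 19))
}

# All per-slice families except the FD image (aggregated separately).
.slice_features <- function(roi, config) {
  qroi <- quantize_roi(roi, config$N)
  g <- tryCatch(
    cooccurrence_stats19(compute_glcm(qroi, config$d, config$angles),
                         config$q, config$r, config$tsallis_conventional),
    tumortex_degenerate_roi_error = function(e) rep(NA_real_, 19))
  r <- tryCatch(rlm_features(qroi, config$angles),
                tumortex_degenerate_roi_error = function(e) rep(NA_real_, 11))
  l <- tryCatch(lbp_feature_block(roi),
                tumortex_degenerate_roi_error = function(e) rep(NA_real_, 128))
  f1 <- tryCatch(sfta_features(roi, config$n_thresholds, config$box_sizes),
                 tumortex_degenerate_roi_error = function(e) rep(NA_real_, 48))
  ih <- tryCatch(intensity_histogram_features(roi, config$ih_bins),
                 tumortex_degenerate_roi_error = function(e) rep(NA_real_, 5))
  am <- tryCatch(acm_feature_block(roi, config),
                 tumortex_degenerate_roi_error = function(e) rep(NA_real_, 38))
  c(g, r, l, f1, ih, am)
}

#' Extract the 255-feature tumor descriptor
#'
#' Computes every feature family on each qualifying axial slice and
#' averages over the slices (unweighted by default), except the FD-image
#' block, which is aggregated across slices by its own max/mean rule. Any
#' non-finite value is replaced by 0 with a warning so cohort tables stay
#' complete.
#'
#' @param tumor A `tumortex_volume`.
#' @param config A [tex_config()].
#' @return Named numeric vector of length 255 in [feature_names()] order,
#'   with the configuration attached as attribute `config`.
#' @export
extract_tumor_features <- function(tumor, config = tex_config()) {
  rois <- extract_slice_rois(tumor, config$min_pixels)
  per_slice <- vapply(rois, .slice_features, numeric(19 + 11 + 128 + 48 + 5 + 38),
                      config = config)
  wts <- if (config$area_weighted) {
    vapply(rois, function(r) sum(r$mask), numeric(1))
  } else rep(1, length(rois))
  agg <- apply(per_slice, 1L, function(v) {
    ok <- is.finite(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * wts[ok]) / sum(wts[ok])
  })

  fd_imgs <- lapply(rois, function(r) {
    tryCatch(dbc_fd_image(r, config$dbc_window),
             tumortex_degenerate_roi_error = function(e) {
               list(fd = matrix(NA_real_, 1, 1), valid = matrix(FALSE, 1, 1))
             })
  })
  f2 <- suppressWarnings(fd2_features(fd_imgs))
  if (all(vapply(fd_imgs, function(im) !any(im$valid), logical(1)))) {
    warn("no slice supports the DBC window; F2 block zero-filled")
  }

  out <- c(agg[1:158], agg[159:206], f2, agg[207:211], agg[212:249])
  names(out) <- feature_names()
  if (any(!is.finite(out))) {
    warn(sprintf("%d non-finite feature value(s) replaced by 0",
                 sum(!is.finite(out))))
    out[!is.finite(out)] <- 0
  }
  attr(out, "config") <- config
  out
}

#' Build the cohort feature table
#'
#' Runs [extract_tumor_features()] on every tumor and assembles a tidy
#' table: one row per patient, columns `patient_id`, `label`, and the 255
#' named features, in input order.
#'
#' @param volumes A `tumortex_cohort` or list of `tumortex_volume` with
#'   labels.
#' @param config A [tex_config()].
#' @return A tibble of `n_patients` rows by 257 columns.
#' @export
build_cohort_table <- function(volumes, config = tex_config()) {
  if (length(volumes) < 2L) {
    abort("need at least two patients", class = "tumortex_cohort_error")
  }
  labels <- vapply(volumes, function(v) v$label, integer(1))
  if (length(unique(labels)) < 2L) {
    abort("cohort must contain both classes", class = "tumortex_cohort_error")
  }
  feats <- t(vapply(volumes, extract_tumor_features, numeric(255),
                    config = config))
  dplyr::bind_cols(cohort_manifest(volumes), as_tibble(feats))
}

# Split a cohort table into (X, y, ids); `family` restricts the feature
# columns ("all" keeps every feature).
.table_xy <- function(table, family = "all") {
  fn <- feature_names()
  stopifnot(all(fn %in% names(table)))
  keep <- if (identical(family, "all")) fn else {
    if (all(family %in% c("glcm", "rlm", "lbp", "sfta", "fd2", "ih",
                          "acm1", "acm2"))) {
      fn[feature_families() %in% family]
    } else {
      stopifnot(all(family %in% fn))
      family
    }
  }
  list(X = as.matrix(table[, keep, drop = FALSE]),
       y = as.integer(table$label),
       ids = if ("patient_id" %in% names(table)) table$patient_id
             else as.character(seq_len(nrow(table))))
}
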