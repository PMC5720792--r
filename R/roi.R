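new_slice_roi <- function(intensities, mask, slice_index) {
  structure(
    list(intensities = intensities, mask = mask,
         slice_index = as.integer(slice_index)),
    class = "tumortex_roi"
  )
}

#' Extraction configuration
#'
#' Bundles every tunable of the texture pipeline with the method's
#' defaults: co-occurrence distance `d = 2` pixels over directions
#' 0/45/90/135 degrees at `N = 16` gray levels; Renyi order `q = 8` and
#' Tsallis order `r = 2`; angle co-occurrence displacement `l = 1` at
#' `n_theta = 8` orientation bins; 16 intensity-histogram bins; 8
#' multi-Otsu thresholds (16 binary images); a 7x7 differential
#' box-counting window; and a 9-pixel minimum slice size so a 3x3 operator
#' footprint fits.
#'
#' @param N Gray-level count for quantization.
#' @param d Co-occurrence pixel distance.
#' @param angles Co-occurrence direction set (degrees).
#' @param q,r Renyi and Tsallis entropy orders.
#' @param l Angle co-occurrence displacement (pixels).
#' @param n_theta Number of quantized gradient-orientation bins.
#' @param min_pixels Minimum in-mask pixel count for a slice to qualify.
#' @param ih_bins Intensity-histogram bin count.
#' @param n_thresholds Multi-Otsu threshold count (yields `2 * n_thresholds`
#'   binary images).
#' @param dbc_window Odd window size of the per-pixel differential
#'   box-counting estimator.
#' @param box_sizes Grid sizes for border box counting.
#' @param tsallis_conventional If `TRUE`, use the conventional Tsallis form
#'   `(1 - sum(p^r)) / (r - 1)` instead of the printed `sum(p^r) / (1 - r)`.
#' @param area_weighted If `TRUE`, weight slice averages by in-mask area.
#' @return A named list of class `tumortex_config`.
#' @export
tex_config <- function(N = 16L, d = 2L, angles = c(0, 45, 90, 135),
                       q = 8, r = 2, l = 1L, n_theta = 8L, min_pixels = 9L,
                       ih_bins = 16L, n_thresholds = 8L, dbc_window = 7L,
                       box_sizes = c(1L, 2L, 4L, 8L),
                       tsallis_conventional = FALSE, area_weighted = FALSE) {
  structure(
    list(N = as.integer(N), d = as.integer(d), angles = angles, q = q, r = r,
         l = as.integer(l), n_theta = as.integer(n_theta),
         min_pixels = as.integer(min_pixels), ih_bins = as.integer(ih_bins),
         n_thresholds = as.integer(n_thresholds),
         dbc_window = as.integer(dbc_window), box_sizes = as.integer(box_sizes),
         tsallis_conventional = isTRUE(tsallis_conventional),
         area_weighted = isTRUE(area_weighted)),
    class = "tumortex_config"
  )
}

#' Write a tumor volume and mask as NIfTI
#'
#' @param tumor A `tumortex_volume`.
#' @param volume_path,mask_path Output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_tumor_volume <- function(tumor, volume_path, mask_path) {
  img <- RNifti::asNifti(tumor$intensities)
  msk <- RNifti::asNifti(array(as.integer(tumor$mask), dim = dim(tumor$mask)))
  RNifti::pixdim(img) <- tumor$spacing
  RNifti::pixdim(msk) <- tumor$spacing
  RNifti::writeNifti(img, volume_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(volume_path, mask_path))
}

#' Write a cohort to disk with a manifest
#'
#' Writes each tumor as a NIfTI volume/mask pair and a CSV manifest with
#' `patient_id`, `label`, and the file paths.
#'
#' @param cohort A `tumortex_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort_manifest(cohort)
  man$volume_path <- file.path(dir, paste0(man$patient_id, "_vol.nii.gz"))
  man$mask_path <- file.path(dir, paste0(man$patient_id, "_mask.nii.gz"))
  for (i in seq_along(cohort)) {
    write_tumor_volume(cohort[[i]], man$volume_path[i], man$mask_path[i])
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Load an aligned volume + mask pair
#'
#' @param volume_path,mask_path NIfTI file paths.
#' @param label,patient_id Optional metadata attached to the result.
#' @return A `tumortex_volume`.
#' @export
load_volume_and_mask <- function(volume_path, mask_path, label = NA_integer_,
                                 patient_id = NA_character_) {
  vol <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  if (!identical(dim(vol), dim(msk))) {
    abort("volume and mask shapes differ", class = "tumortex_alignment_error")
  }
  mv <- unique(as.vector(msk))
  if (!all(mv %in% c(0, 1))) {
    abort("mask must be binary (0/1)", class = "tumortex_format_error")
  }
  spacing <- RNifti::pixdim(vol)[seq_len(3)]
  vol_arr <- array(as.numeric(vol), dim = dim(vol))
  if (any(!is.finite(vol_arr))) {
    abort("volume contains non-finite intensities", class = "tumortex_format_error")
  }
  new_tumor_volume(vol_arr, array(msk == 1, dim = dim(msk)), spacing,
                   ifelse(is.na(label), NA_integer_, as.integer(label)),
                   patient_id)
}

#' Carve per-slice tumor ROIs
#'
#' Walks the axial (third) axis and returns one region of interest per
#' slice whose in-mask pixel count reaches `min_pixels`, each cropped to
#' the bounding box of the mask on that slice.
#'
#' @param tumor A `tumortex_volume`.
#' @param min_pixels Minimum foreground pixel count per qualifying slice.
#' @return A list of `tumortex_roi` in ascending slice order.
#' @export
extract_slice_rois <- function(tumor, min_pixels = 9L) {
  stopifnot(min_pixels >= 1)
  nz <- dim(tumor$mask)[3]
  out <- list()
  for (z in seq_len(nz)) {
    m <- tumor$mask[, , z]
    if (sum(m) < min_pixels) next
    rows <- range(which(rowSums(m) > 0))
    cols <- range(which(colSums(m) > 0))
    out[[length(out) + 1L]] <- new_slice_roi(
      tumor$intensities[rows[1]:rows[2], cols[1]:cols[2], z],
      m[rows[1]:rows[2], cols[1]:cols[2]],
      z
    )
  }
  if (length(out) == 0L) {
    abort("no slice reaches min_pixels in-mask pixels",
          class = "tumortex_empty_tumor_error")
  }
  out
}

#' Quantize a slice ROI to N gray levels
#'
#' In-mask intensities are binned linearly from the per-slice in-mask
#' minimum--maximum range into `N` equal-width bins labeled 1..N (the
#' maximum maps to N); pixels outside the mask carry the sentinel 0. A
#' constant ROI maps to level 1 everywhere in-mask.
#'
#' @param roi A `tumortex_roi`.
#' @param N Number of gray levels (>= 2).
#' @return A `tumortex_qroi` with fields `levels`, `N`, `mask`.
#' @export
quantize_roi <- function(roi, N = 16L) {
  stopifnot(N >= 2)
  v <- roi$intensities[roi$mask]
  lev <- matrix(0L, nrow(roi$intensities), ncol(roi$intensities))
  rng <- range(v)
  if (diff(rng) <= 0) {
    lev[roi$mask] <- 1L
  } else {
    b <- floor((roi$intensities[roi$mask] - rng[1]) / diff(rng) * N) + 1L
    lev[roi$mask] <- pmin(as.integer(b), as.integer(N))
  }
  structure(list(levels = lev, N = as.integer(N), mask = roi$mask),
            class = "tumortex_qroi")
}
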