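#' Specify a synthetic tumor cohort
#'
#' Describes a labeled cohort of synthetic tumor volumes emulating the
#' attenuation texture continuum of pancreatic ductal adenocarcinoma on
#' portal-venous CT: short survivors (label 0, survival < 2 years) carry
#' heterogeneous, directionally structured texture with hypointense
#' necrosis-like foci, long survivors (label 1, survival >= 2 years) a
#' near-isotropic smooth texture. The default class sizes (20 short vs 15
#' long survivors) match the clinical cohort structure the method was
#' designed around.
#'
#' @param n_short_survivors,n_long_survivors Number of tumors with label 0
#'   (survival < 2 years) and label 1 (survival >= 2 years). Both must be
#'   at least 1.
#' @param volume_shape Integer triple, voxel grid of each generated volume.
#' @param slice_count_range Integer pair, range of axial slice counts the
#'   tumor may span.
#' @param texture_effect Separation between the class texture regimes, in
#'   \[0, 1\]. At 0 the two classes are drawn from the same distribution; at
#'   1 the short-survivor regime is fully expressed.
#' @param noise_sd Standard deviation of additive white intensity noise
#'   (pseudo-HU).
#' @param seed Integer seed; identical spec + seed reproduce the cohort
#'   bit-identically.
#' @return A `tumortex_cohort_spec` list.
#' @seealso [generate_cohort()], [generate_tumor()]
#' @export
cohort_spec <- function(n_short_survivors = 20L, n_long_survivors = 15L,
                        volume_shape = c(32L, 32L, 8L),
                        slice_count_range = c(3L, 5L),
                        texture_effect = 1, noise_sd = 2, seed = 1L) {
  if (n_short_survivors < 1 || n_long_survivors < 1) {
    abort("both classes need at least one tumor", class = "tumortex_parameter_error")
  }
  if (texture_effect < 0 || texture_effect > 1) {
    abort("texture_effect must lie in [0, 1]", class = "tumortex_parameter_error")
  }
  if (noise_sd < 0) {
    abort("noise_sd must be nonnegative", class = "tumortex_parameter_error")
  }
  if (length(volume_shape) != 3L || any(volume_shape < 4)) {
    abort("volume_shape must be a triple of at least 4 voxels per axis",
          class = "tumortex_parameter_error")
  }
  if (length(slice_count_range) != 2L || slice_count_range[1] < 2 ||
      slice_count_range[2] < slice_count_range[1]) {
    abort("slice_count_range must be an increasing pair with minimum >= 2",
          class = "tumortex_parameter_error")
  }
  structure(
    list(n_short_survivors = as.integer(n_short_survivors),
         n_long_survivors = as.integer(n_long_survivors),
         volume_shape = as.integer(volume_shape),
         slice_count_range = as.integer(slice_count_range),
         texture_effect = texture_effect,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "tumortex_cohort_spec"
  )
}

new_tumor_volume <- function(intensities, mask, spacing, label, patient_id) {
  structure(
    list(intensities = intensities, mask = mask, spacing = spacing,
         label = as.integer(label), patient_id = patient_id),
    class = "tumortex_volume"
  )
}

#' @export
print.tumortex_volume <- function(x, ...) {
  cat(sprintf("<tumortex_volume> %s  label=%d  %s voxels, %d in mask\n",
              x$patient_id, x$label, paste(dim(x$intensities), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' Generate one synthetic tumor volume
#'
#' Builds an ellipsoidal tumor on a voxel grid with a pseudo-HU texture in
#' the soft-tissue range (roughly 20--120). Both classes share a smooth
#' isotropic base texture; `texture_effect` scales in a label-specific
#' component: label 0 adds oriented band-limited stripes (one dominant
#' gradient direction, randomized per tumor) plus 1--3 hypointense
#' necrosis-like blobs, while label 1 adds extra isotropic low-frequency
#' structure of matched variance. At `texture_effect = 0` the labels are
#' exchangeable.
#'
#' @param label 0 (short survivor, heterogeneous regime) or 1 (long
#'   survivor, homogeneous regime).
#' @param axes_mm Positive ellipsoid diameters (x, y, z) in mm.
#' @param texture_effect Regime separation in \[0, 1\].
#' @param seed Integer seed (deterministic output).
#' @param shape Voxel grid triple.
#' @param noise_sd Additive white-noise standard deviation.
#' @param spacing Voxel spacing in mm; the default matches a typical
#'   portal-venous abdominal CT reconstruction.
#' @param patient_id Identifier stored with the volume.
#' @return A `tumortex_volume`: intensity array, binary mask, spacing,
#'   label, patient id.
#' @export
generate_tumor <- function(label, axes_mm = c(17, 15, 10), texture_effect = 1,
                           seed = 1L, shape = c(32L, 32L, 8L), noise_sd = 2,
                           spacing = c(0.7324, 0.7324, 2.5),
                           patient_id = "P000") {
  if (any(axes_mm <= 0)) {
    abort("ellipsoid axes must be positive", class = "tumortex_parameter_error")
  }
  if (texture_effect < 0 || texture_effect > 1) {
    abort("texture_effect must lie in [0, 1]", class = "tumortex_parameter_error")
  }
  label <- as.integer(label)
  stopifnot(label %in% c(0L, 1L))
  shape <- as.integer(shape)

  .with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]; nz <- shape[3]
    semi <- (axes_mm / 2) / spacing          # semi-axes in voxel units
    ctr <- (shape + 1) / 2
    rr <- (seq_len(nr) - ctr[1]) / semi[1]
    cc <- (seq_len(nc) - ctr[2]) / semi[2]
    zz <- (seq_len(nz) - ctr[3]) / semi[3]
    d2 <- outer(outer(rr^2, cc^2, "+"), zz^2, "+")
    mask <- d2 <= 1
    if (sum(apply(mask, 3L, any)) < 2L) {
      abort("tumor must span at least two axial slices; enlarge axes_mm[3]",
            class = "tumortex_parameter_error")
    }

    eff <- texture_effect
    vol <- array(70, dim = shape)
    # Patient-level attenuation variation (contrast timing, vascularity):
    # a global offset and texture-amplitude factor, independent of label,
    # so first-order intensity statistics vary across tumors of both
    # classes while directional structure stays label-specific.
    base_hu <- 70 + rnorm(1, 0, 6)
    amp <- runif(1, 0.85, 1.15)
    phi <- runif(1, 0, pi)                   # dominant gradient orientation
    xg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    yg <- matrix(seq_len(nr), nr, nc)
    u <- xg * cos(phi) + yg * sin(phi)       # coordinate along phi
    u_grid <- floor(min(u)) - 4L
    u_len <- ceiling(max(u)) - u_grid + 8L

    for (z in seq_len(nz)) {
      iso <- .smooth2d(matrix(rnorm(nr * nc), nr, nc), sigma = 2.5)
      iso <- iso / max(sd(iso), 1e-12)
      slice <- base_hu + amp * 8 * iso
      if (label == 0L) {
        # band-limited oriented noise: a smooth 1-D profile evaluated along
        # phi, constant perpendicular to it, so gradients share one
        # orientation while the intensity marginal stays Gaussian
        prof <- .smooth1d(rnorm(u_len), sigma = 1.2)
        prof <- prof / max(sd(prof), 1e-12)
        band <- matrix(stats::approx(seq_along(prof) + u_grid - 1L, prof,
                                     xout = as.vector(u))$y, nr, nc)
        rough <- .smooth2d(matrix(rnorm(nr * nc), nr, nc), sigma = 0.8)
        rough <- rough / max(sd(rough), 1e-12)
        slice <- slice + eff * amp * (sqrt(72) * band + 3 * rough)
      } else {
        extra <- .smooth2d(matrix(rnorm(nr * nc), nr, nc), sigma = 4)
        extra <- extra / max(sd(extra), 1e-12)
        slice <- slice + eff * amp * 9 * extra   # sd matched to the band+rough mix
      }
      if (noise_sd > 0) slice <- slice + rnorm(nr * nc, sd = noise_sd)
      vol[, , z] <- slice
    }

    if (label == 0L && eff > 0) {
      n_blob <- sample(1:3, 1)
      in_mask <- which(mask, arr.ind = TRUE)
      for (b in seq_len(n_blob)) {
        cpos <- in_mask[sample(nrow(in_mask), 1), ]
        rad <- runif(1, 2, 3.5)
        radz <- runif(1, 0.8, 1.5)
        depth <- 20 * eff
        for (z in seq_len(nz)) {
          dz2 <- ((z - cpos[3]) / radz)^2
          if (dz2 > 9) next
          d2b <- outer((seq_len(nr) - cpos[1])^2, (seq_len(nc) - cpos[2])^2, "+") / rad^2
          vol[, , z] <- vol[, , z] - depth * exp(-(d2b + dz2) / 2)
        }
      }
    }

    vol <- pmin(pmax(vol, 20), 120)
    new_tumor_volume(vol, mask, spacing, label, patient_id)
  })
}

#' Generate a labeled synthetic cohort
#'
#' Produces `n_short_survivors + n_long_survivors` tumor volumes with
#' per-tumor RNG streams derived deterministically from the spec seed, so a
#' cohort is bit-reproducible and individual tumors can be regenerated in
#' isolation. Tumor sizes are sampled per tumor: in-plane diameters of
#' 14--20 mm and axial extents drawn from `slice_count_range`, giving
#' volumes of roughly 1--4 cm^3.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `tumortex_volume` objects (class `tumortex_cohort`),
#'   short survivors first.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "tumortex_cohort_spec"))
  n <- spec$n_short_survivors + spec$n_long_survivors
  labels <- c(rep(0L, spec$n_short_survivors), rep(1L, spec$n_long_survivors))
  slice_mm <- 2.5
  out <- vector("list", n)
  for (i in seq_len(n)) {
    si <- .derive_seed(spec$seed, i)
    geom <- .with_seed(.derive_seed(si, 991L), {
      ns <- sample(seq(spec$slice_count_range[1], spec$slice_count_range[2]), 1)
      c(runif(2, 14, 20), ns * slice_mm * 0.95)
    })
    out[[i]] <- generate_tumor(
      label = labels[i], axes_mm = geom, texture_effect = spec$texture_effect,
      seed = si, shape = spec$volume_shape, noise_sd = spec$noise_sd,
      patient_id = sprintf("P%03d", i)
    )
  }
  structure(out, class = "tumortex_cohort", spec = spec)
}

#' Cohort manifest table
#'
#' @param cohort A `tumortex_cohort` (or plain list of `tumortex_volume`).
#' @return A tibble with `patient_id` and `label` per tumor.
#' @export
cohort_manifest <- function(cohort) {
  tibble(
    patient_id = vapply(cohort, function(v) v$patient_id, character(1)),
    label = vapply(cohort, function(v) v$label, integer(1))
  )
}

#' Deterministic micro-fixtures for texture oracles
#'
#' Tiny fully-specified 2-D regions of interest used as exact oracle targets
#' for co-occurrence, run-length, gradient, and local-binary-pattern
#' operators.
#'
#' @return A named list of `tumortex_roi` objects: `constant8` (8x8 single
#'   value), `checker` (two-level period-1 checkerboard), `rampx`
#'   (left-to-right linear ramp), `rampxy` (left half ramps in x, right half
#'   ramps in y), and `quad4` (4x4 with values 0, 5, 10, 15 by column).
#' @export
fixture_rois <- function() {
  full8 <- matrix(TRUE, 8, 8)
  checker <- outer(1:8, 1:8, function(r, c) ifelse((r + c) %% 2 == 0, 70, 30))
  rampx <- matrix(rep(10 * (1:8), each = 8), 8, 8)
  rampxy <- cbind(
    matrix(rep(10 * (1:4), each = 8), 8, 4),          # ramps along x
    matrix(rep(10 * (1:8), times = 4), 8, 4)          # ramps along y
  )
  quad4 <- matrix(rep(c(0, 5, 10, 15), each = 4), 4, 4)  # constant per column
  list(
    constant8 = new_slice_roi(matrix(50, 8, 8), full8, 1L),
    checker = new_slice_roi(checker, full8, 1L),
    rampx = new_slice_roi(rampx, full8, 1L),
    rampxy = new_slice_roi(rampxy, full8, 1L),
    quad4 = new_slice_roi(quad4, matrix(TRUE, 4, 4), 1L)
  )
}
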