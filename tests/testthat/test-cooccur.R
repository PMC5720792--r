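test_that("GLCM of degenerate and patterned fixtures matches first principles", {
  fx <- fixture_rois()
  g <- compute_glcm(quantize_roi(fx$constant8, 16), d = 2)
  expect_equal(dim(g$P), c(16L, 16L))
  expect_equal(g$P[1, 1], 1)
  expect_equal(sum(g$P), 1)

  # period-1 checkerboard at d = 2: every pair links same-colored squares
  ck <- compute_glcm(quantize_roi(fx$checker, 16), d = 2)
  expect_equal(sum(ck$P) - sum(diag(ck$P)), 0)
  expect_equal(sum(ck$P), 1, tolerance = 1e-9)
})

test_that("GLCM equals exhaustive pair enumeration on random masked ROIs", {
  for (seed in 1:4) {
    roi <- random_roi(n = 8, seed = seed, mask_frac = 0.8)
    q <- quantize_roi(roi, 6)
    g <- compute_glcm(q, d = 2)
    expect_equal(g$P, oracle_glcm(q$levels, 2, c(0, 45, 90, 135), 6),
                 tolerance = 1e-12)
    expect_equal(g$P, t(g$P), tolerance = 1e-12)   # symmetric counting
    expect_true(all(g$P >= 0))
    expect_equal(sum(g$P), 1, tolerance = 1e-9)
  }
})

test_that("co-occurrence statistics reproduce closed forms", {
  delta <- structure(list(P = diag(c(1, 0, 0, 0)), N = 4L, kind = "glcm"),
                     class = "tumortex_comat")
  s <- cooccurrence_stats19(delta, q = 8, r = 2)
  expect_equal(unname(s[c(1, 2, 9, 18)]), c(1, 0, 0, 0))  # energy, contrast, entropy, Renyi
  expect_equal(unname(s[19]), -1)  # Tsallis, r = 2: (1/(1-2)) * 1

  unif <- structure(list(P = matrix(0.25, 2, 2), N = 2L, kind = "glcm"),
                    class = "tumortex_comat")
  s2 <- cooccurrence_stats19(unif, q = 8, r = 2)
  # (1 / (1 - 8)) * log2(4 * 0.25^8) = 2 bits
  expect_equal(unname(s2[18]), 2)
})

test_that("Renyi entropy approaches Shannon entropy as the order nears 1", {
  roi <- random_roi(n = 8, seed = 9)
  g <- compute_glcm(quantize_roi(roi, 8), d = 2)
  s <- cooccurrence_stats19(g, q = 1 + 1e-6, r = 2)
  expect_equal(unname(s[18]), unname(s[9]), tolerance = 1e-3)
})

test_that("run-length matrices count maximal in-mask runs", {
  fx <- fixture_rois()
  q4 <- quantize_roi(fx$quad4, 4)
  const <- quantize_roi(make_roi(matrix(5, 4, 4)), 4)
  r0 <- compute_rlm(const, 0)
  expect_equal(r0$R[1, 4], 4)
  expect_equal(sum(r0$R) - r0$R[1, 4], 0)

  ck <- compute_rlm(quantize_roi(fx$checker, 16), 0)
  expect_true(all(ck$R[, -1] == 0))   # horizontal runs all have length 1
  # SRE of the 0-degree matrix is 1 when every run has length 1
  expect_equal(sum(ck$R[, 1]), sum(ck$R))

  # L-shaped mask: runs break at the mask boundary
  m <- matrix(TRUE, 5, 5); m[1:3, 3:5] <- FALSE
  roi <- make_roi(matrix(7, 5, 5), m)
  q <- quantize_roi(roi, 4)
  for (ang in c(0, 45, 90, 135)) {
    got <- compute_rlm(q, ang)
    expect_equal(got$R, oracle_rlm(q$levels, ang, 4, 5),
                 info = paste("direction", ang))
  }
})

test_that("run-length features average the four directions", {
  const <- quantize_roi(make_roi(matrix(5, 4, 4)), 4)
  f <- rlm_features(const)
  expect_length(f, 11)
  # run percentage: 0/90 degrees give 4 runs / 16 px, diagonals 7 / 16
  expect_equal(unname(f["rp"]), mean(c(4, 7, 4, 7) / 16))
  expect_equal(unname(f["lgre"]), 1)  # all runs at level 1
})

test_that("Sobel gradients respect the mask and match direct convolution", {
  fx <- fixture_rois()
  sg <- sobel_gradients(fx$rampx)
  expect_true(all(sg$angle[sg$valid] == 0))
  expect_equal(unique(sg$magnitude[sg$valid]), 80)

  sgc <- sobel_gradients(fx$constant8)
  expect_true(all(sgc$magnitude[sgc$valid] == 0))

  roi <- random_roi(n = 5, seed = 3)
  sg2 <- sobel_gradients(roi)
  for (r in 2:4) for (c in 2:4) {
    o <- oracle_sobel(roi$intensities, r, c)
    expect_equal(sg2$gx[r, c], unname(o["gx"]))
    expect_equal(sg2$gy[r, c], unname(o["gy"]))
  }
  # boundary pixels are never valid
  expect_false(any(sg2$valid[c(1, 5), ]) || any(sg2$valid[, c(1, 5)]))
})

test_that("angle co-occurrence matrices match exhaustive pair counting", {
  fx <- fixture_rois()
  sg <- sobel_gradients(fx$rampx)
  a1 <- compute_acm(sg, l = 1, n_theta = 8)
  expect_equal(dim(a1$P), c(8L, 8L))
  expect_equal(sum(a1$P^2), 1)            # delta matrix: energy 1
  s <- cooccurrence_stats19(a1)
  expect_equal(unname(s[9]), 0)           # entropy 0

  # uniform magnitudes: ACM2 equals ACM1 entrywise
  a2 <- compute_acm(sg, l = 1, n_theta = 8, weighted = TRUE)
  expect_equal(a1$P, a2$P, tolerance = 1e-12)

  # composite ramp: mass split between two orientation bins
  sgxy <- sobel_gradients(fx$rampxy)
  for (w in c(FALSE, TRUE)) {
    got <- compute_acm(sgxy, l = 1, n_theta = 8, weighted = w)
    bins <- tumortex:::.angle_bins(sgxy, 8)
    want <- oracle_acm(bins, sgxy$valid, sgxy$magnitude, 1,
                       c(0, 45, 90, 135), 8, w)
    expect_equal(got$P, want, tolerance = 1e-12)
    expect_equal(sum(got$P), 1, tolerance = 1e-9)
  }
})

test_that("the ACM feature block has the documented structure", {
  fx <- fixture_rois()
  blk <- acm_feature_block(fx$rampx)
  expect_length(blk, 38)
  expect_equal(unname(blk["acm1.s1"]), 1)  # energy of a delta matrix
  expect_equal(unname(blk["acm1.s9"]), 0)  # entropy
  # uniform-magnitude field: A block equals M block
  expect_equal(unname(blk[1:19]), unname(blk[20:38]), tolerance = 1e-12)
})

test_that("four-direction averaging is invariant to 90-degree rotation", {
  roi <- random_roi(n = 8, seed = 11)
  rot <- rot90_roi(roi)
  q1 <- quantize_roi(roi, 8); q2 <- quantize_roi(rot, 8)
  s1 <- cooccurrence_stats19(compute_glcm(q1, 2))
  s2 <- cooccurrence_stats19(compute_glcm(q2, 2))
  expect_equal(s1[-14], s2[-14], tolerance = 1e-9)  # mcc is the documented fallback
  expect_equal(rlm_features(q1), rlm_features(q2), tolerance = 1e-9)
  # gradient angles rotate by exactly 90 degrees = 2 orientation bins
  # (the fixture rotation is clockwise, so bins shift down by 2)
  a1 <- compute_acm(sobel_gradients(roi), 1, 8)
  a2 <- compute_acm(sobel_gradients(rot), 1, 8)
  shift <- function(i) (i + 5L) %% 8L + 1L
  expect_equal(a2$P[shift(1:8), shift(1:8)], a1$P, tolerance = 1e-9)
})
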