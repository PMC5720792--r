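test_that("tumor generation is deterministic and validated", {
  t1 <- generate_tumor(0, seed = 5)
  t2 <- generate_tumor(0, seed = 5)
  expect_identical(t1$intensities, t2$intensities)
  expect_identical(t1$mask, t2$mask)

  expect_error(generate_tumor(0, axes_mm = c(-1, 10, 10)),
               class = "tumortex_parameter_error")
  expect_error(generate_tumor(1, texture_effect = 1.5),
               class = "tumortex_parameter_error")
})

test_that("generated volumes satisfy the mask and intensity contracts", {
  for (lab in 0:1) {
    tm <- generate_tumor(lab, seed = 17 + lab)
    expect_true(all(is.finite(tm$intensities)))
    expect_true(all(tm$intensities >= 20 & tm$intensities <= 120))
    slices_with_fg <- sum(apply(tm$mask, 3, any))
    expect_gte(slices_with_fg, 2)
    expect_equal(tm$spacing, c(0.7324, 0.7324, 2.5))
  }
})

test_that("cohort generation respects the spec and is reproducible", {
  spec <- cohort_spec(n_short_survivors = 20, n_long_survivors = 15, seed = 7)
  coh <- generate_cohort(spec)
  expect_length(coh, 35)
  labs <- vapply(coh, function(v) v$label, integer(1))
  expect_equal(sum(labs == 0), 20)
  expect_equal(sum(labs == 1), 15)

  coh2 <- generate_cohort(cohort_spec(20, 15, seed = 7))
  expect_identical(lapply(coh, `[[`, "intensities"),
                   lapply(coh2, `[[`, "intensities"))

  expect_error(cohort_spec(n_short_survivors = 0),
               class = "tumortex_parameter_error")
  expect_error(cohort_spec(texture_effect = 2),
               class = "tumortex_parameter_error")
})

test_that("zero texture effect makes the classes exchangeable", {
  spec <- cohort_spec(n_short_survivors = 12, n_long_survivors = 12,
                      texture_effect = 0, seed = 29)
  coh <- generate_cohort(spec)
  m11 <- vapply(coh, function(tm) {
    rois <- extract_slice_rois(tm)
    mean(vapply(rois, function(r) acm_feature_block(r)["acm2.s11"], numeric(1)))
  }, numeric(1))
  labs <- vapply(coh, function(v) v$label, integer(1))
  p <- wilcox.test(m11[labs == 1], m11[labs == 0], exact = FALSE)$p.value
  expect_gt(p, 0.005)
})

test_that("full texture effect separates ACM2 difference entropy strongly", {
  spec <- cohort_spec(n_short_survivors = 50, n_long_survivors = 50,
                      texture_effect = 1, seed = 41)
  coh <- generate_cohort(spec)
  m11 <- vapply(coh, function(tm) {
    rois <- extract_slice_rois(tm)
    mean(vapply(rois, function(r) acm_feature_block(r)["acm2.s11"], numeric(1)))
  }, numeric(1))
  labs <- vapply(coh, function(v) v$label, integer(1))
  # oriented texture flips gradient orientation by 180 degrees across
  # ridges, pushing co-occurrence mass far off-diagonal: short survivors
  # have the higher ACM2 difference entropy
  auc <- oracle_rank_auc(m11, 1L - labs)
  expect_gt(auc, 0.9)
})

test_that("pipeline discrimination grows with the texture effect", {
  aucs <- vapply(c(0, 0.5, 1), function(eff) {
    med <- vapply(1:2, function(s) {
      spec <- cohort_spec(8, 7, texture_effect = eff, seed = 300 + s)
      loo_cv(build_cohort_table(generate_cohort(spec)), family = "acm2")$auc
    }, numeric(1))
    median(med)
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("fixture ROIs have their stated structure", {
  fx <- fixture_rois()
  expect_named(fx, c("constant8", "checker", "rampx", "rampxy", "quad4"))
  expect_equal(dim(fx$constant8$intensities), c(8L, 8L))
  expect_length(unique(as.vector(fx$constant8$intensities)), 1)
  expect_true(all(fx$constant8$mask))

  ck <- fx$checker$intensities
  expect_length(unique(as.vector(ck)), 2)
  expect_true(all(ck[, -1] != ck[, -8]))   # alternates along rows

  rx <- fx$rampx$intensities
  expect_true(all(diff(rx[1, ]) > 0))      # strictly increasing left to right
  expect_true(all(apply(rx, 2, function(col) length(unique(col)) == 1)))

  expect_equal(sort(unique(as.vector(fx$quad4$intensities))), c(0, 5, 10, 15))
})
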