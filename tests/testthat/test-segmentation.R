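spec <- small_spec()
pre_vol <- build_phantom(spec)
noise_free <- noise_model(speckle_variance = 0, blur_sigma_mm = 0)

test_that("noise-free renders segment back to the ground truth", {
  st <- render_ultrasound(pre_vol, noise_free)
  sr <- segment_stack(st)
  expect_identical(sum(sr$flags$flagged), 0L)
  agreement <- mean(sr$labels == unclass(pre_vol))
  expect_gte(agreement, 0.995)
})

test_that("default speckle keeps per-region Dice at 0.95 or better", {
  st <- render_ultrasound(pre_vol, noise_model(seed = 4L))
  sr <- segment_stack(st)
  for (lb in LBLS) {
    a <- sr$labels == lb
    b <- unclass(pre_vol) == lb
    dice <- 2 * sum(a & b) / (sum(a) + sum(b))
    expect_gte(dice, 0.95)
  }
})

test_that("degenerate inputs flag instead of erroring", {
  bright <- matrix(1, 60, 60)
  res <- segment_slice(bright, pixel_spacing_mm = 0.4)
  expect_true(res$flagged)
  expect_null(res$labels)
  expect_error(segment_stack(array(0.5, c(4, 4, 0))), "non-empty")
})

test_that("segmentation is deterministic and idempotent on its own output", {
  st <- render_ultrasound(pre_vol, noise_model(seed = 21L))
  s1 <- segment_slice(st[, , 5], pixel_spacing_mm = spec$pixel_spacing_mm)
  s2 <- segment_slice(st[, , 5], pixel_spacing_mm = spec$pixel_spacing_mm)
  expect_identical(s1$labels, s2$labels)
  # render the inferred labels noise-free and re-segment
  relab <- array(s1$labels, dim = c(dim(s1$labels), 1))
  relab <- structure(relab,
                     pixel_spacing_mm = spec$pixel_spacing_mm,
                     slice_spacing_mm = spec$slice_spacing_mm,
                     spec = spec, class = "label_volume")
  st2 <- render_ultrasound(relab, noise_free)
  s3 <- segment_slice(st2[, , 1], pixel_spacing_mm = spec$pixel_spacing_mm)
  expect_gte(mean(s3$labels == s1$labels), 0.999)
})

test_that("a breached slice yields an inferred cavity touching background", {
  sk <- skill_profile(mean_resection_radius_mm = 8, breach_probability = 1,
                      breach_depth_fraction = 1, roughness_amplitude = 0,
                      asymmetry_offset_mm = 0, seed = 13L)
  res <- simulate_resection(pre_vol, sk)
  st <- render_ultrasound(res$volume, noise_free)
  sr <- segment_stack(st)
  breach_slices <- unique(res$breaches$slice)
  expect_gt(length(breach_slices), 0L)
  touching <- vapply(breach_slices, function(k) {
    sl <- sr$labels[, , k]
    isTRUE(turpeval:::masks_touch8(sl == LBLS[["CAVITY"]],
                                   sl == LBLS[["BACKGROUND"]]))
  }, TRUE)
  expect_true(any(touching))
})

test_that("pixel accuracy does not improve as speckle grows", {
  accs <- vapply(c(0, 0.03, 0.12, 0.3), function(v) {
    st <- render_ultrasound(pre_vol,
                            noise_model(speckle_variance = v, seed = 31L))
    sr <- segment_stack(st)
    mean(sr$labels == unclass(pre_vol))
  }, 0)
  expect_true(all(diff(accs) <= 1e-3))
})

test_that("fixed-threshold strategy is honoured and recorded", {
  st <- render_ultrasound(pre_vol, noise_free)
  params <- segmentation_params(strategy = "fixed", thresholds = c(0.3, 0.7))
  res <- segment_slice(st[, , 5], params,
                       pixel_spacing_mm = spec$pixel_spacing_mm)
  expect_identical(res$thresholds, c(0.3, 0.7))
  expect_error(segmentation_params(strategy = "fixed", thresholds = c(0.7, 0.3)),
               "ordered")
})
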