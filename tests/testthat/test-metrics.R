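test_that("annulus thickness matches geometry within a pixel", {
  psp <- 0.1
  lab <- annulus_labels(5, 10, psp)
  expect_equal(min_peripheral_thickness(lab, psp), 5, tolerance = psp * 2 / 5)

  ecc <- annulus_labels(5, 10, psp, offset_mm = 2)
  th <- min_peripheral_thickness(ecc, psp)
  expect_equal(th, 3, tolerance = psp * 2 / 3)
  # brute-force all-pairs oracle agrees exactly
  expect_equal(th, oracle_min_thickness(ecc, psp), tolerance = 1e-9)
})

test_that("a cavity reaching background has zero thickness", {
  psp <- 0.2
  lab <- annulus_labels(5, 10, psp)
  # carve a channel from the cavity to the outside
  ctr <- (nrow(lab) + 1) / 2
  lab[round(ctr) + (-1:1), ] <- LBLS[["CAVITY"]]
  expect_identical(min_peripheral_thickness(lab, psp), 0)
})

test_that("closed-form circularity values are reproduced", {
  expect_equal(circularity(square_mask(60)), pi / 4, tolerance = 0.02)
  expect_equal(circularity(square_mask(12)), pi / 4, tolerance = 0.02)
  d50 <- circularity(disc_mask(50))
  expect_gte(d50, 0.98)
  expect_lte(d50, 1.02)
  # analytic disc: closed form is exactly 1
  expect_equal(4 * pi * (pi * 7^2) / (2 * pi * 7)^2, 1)
})

test_that("circularity is invariant under translation and 90-degree rotation", {
  set.seed(77)
  m <- blob_mask()
  c0 <- circularity(m)
  shifted <- matrix(FALSE, nrow(m) + 6, ncol(m) + 9)
  shifted[4 + seq_len(nrow(m)) - 1, 7 + seq_len(ncol(m)) - 1] <- m
  expect_equal(circularity(shifted), c0, tolerance = 1e-12)
  rot <- t(m)[ncol(m):1, ]
  expect_equal(circularity(rot), c0, tolerance = 0.01)
})

test_that("circularity converges under uniform scaling", {
  errs <- vapply(c(15, 30, 60), function(r) abs(circularity(disc_mask(r)) - 1), 0)
  expect_lt(errs[3], errs[1])
})

test_that("solidity is exact for convex rasters and drops with concavity", {
  expect_equal(solidity(disc_mask(40)), 1, tolerance = 1e-12)
  expect_equal(solidity(square_mask(30)), 1, tolerance = 1e-12)
  # crossed 3 x 9 bars: frozen against the independent hull oracle
  plus <- matrix(FALSE, 15, 15)
  plus[7:9, 4:12] <- TRUE
  plus[4:12, 7:9] <- TRUE
  expect_identical(sum(plus), 45L)
  expect_equal(solidity(plus), 45 / oracle_convex_count(plus),
               tolerance = 1e-12)
  expect_lt(solidity(plus), 1)
})

test_that("rougher resections are less smooth, same seed", {
  pre_vol <- build_phantom(small_spec())
  sm <- function(amp) {
    sk <- skill_profile(mean_resection_radius_mm = 8,
                        roughness_amplitude = amp,
                        asymmetry_offset_mm = 0, breach_probability = 0,
                        seed = 5L)
    cm <- evaluate_case(pre_vol, simulate_resection(pre_vol, sk)$volume)
    cm$R_smoo
  }
  expect_lt(sm(0.3), sm(0.1))
})

test_that("preservation ratio arithmetic and exclusions", {
  mk <- function(t, valid = TRUE)
    data.frame(slice = seq_along(t), T_min_peri_mm = t,
               A_uret_mm2 = 1, A_conv_mm2 = 1, P_uret_mm = 1, C = 1,
               solidity = 1, shape_valid = valid, valid = valid)
  pre <- mk(c(4, 4, 4, 4))
  post <- mk(c(4, 4, 0, 0))
  expect_equal(preservation_ratio(pre, post)$R_pres, 0.5)
  expect_equal(preservation_ratio(pre, pre)$R_pres, 1.0)
  # zero pre-thickness slices are excluded and logged
  pre0 <- mk(c(4, 0, 4, 4))
  res <- preservation_ratio(pre0, post)
  expect_identical(res$n, 3L)
  expect_true("zero pre-surgery thickness" %in% res$excluded$reason)
})

test_that("circularity ratio closed forms", {
  psp <- 1
  pre <- slice_metrics(structure(array(annulus_labels(8, 20, 0.25),
                                       c(dim(annulus_labels(8, 20, 0.25)), 1)),
                                 pixel_spacing_mm = 0.25, slice_spacing_mm = 1,
                                 class = "label_volume"))
  expect_equal(pre$C[1], 1, tolerance = 0.02)
  # disc pre, square post -> ratio pi/4
  c_disc <- circularity(disc_mask(32))
  c_sq <- circularity(square_mask(57))
  expect_equal(c_sq / c_disc, pi / 4, tolerance = 0.02)
  # geometric similarity: scaled cavity keeps circularity
  expect_equal(circularity(disc_mask(20)), circularity(disc_mask(40)),
               tolerance = 0.01)
})

test_that("evaluate_case identity and bookkeeping", {
  pre_vol <- build_phantom(small_spec())
  cm <- evaluate_case(pre_vol, pre_vol)
  expect_equal(cm$R_pres, 1.0)
  expect_equal(cm$R_circ, 1.0)
  expect_gte(cm$R_smoo, 0.99)
  expect_identical(cm$n, sum(cm$pre$valid & cm$post$valid))
  expect_error(evaluate_case(pre_vol, build_phantom(
    phantom_spec(n_slices = 4L, pixel_spacing_mm = 0.4))), "same grid")
})

test_that("ground-truth metrics match segmentation-derived metrics on noise-free renders", {
  spec <- small_spec()
  pre_vol <- build_phantom(spec)
  res <- simulate_resection(pre_vol, skill_presets(seed = 2L)$fellow)
  nf <- noise_model(speckle_variance = 0, blur_sigma_mm = 0)
  seg_pre <- segment_stack(render_ultrasound(pre_vol, nf))
  seg_post <- segment_stack(render_ultrasound(res$volume, nf))
  cm_gt <- evaluate_case(pre_vol, res$volume)
  cm_seg <- evaluate_case(seg_pre$labels, seg_post$labels,
                          seg_pre$flags, seg_post$flags)
  expect_equal(cm_seg$R_pres, cm_gt$R_pres, tolerance = 1e-3)
  expect_equal(cm_seg$R_smoo, cm_gt$R_smoo, tolerance = 1e-3)
  expect_equal(cm_seg$R_circ, cm_gt$R_circ, tolerance = 1e-3)
})

test_that("shape metrics agree with brute-force oracles on random masks", {
  set.seed(123)
  psp <- 1
  for (rep in 1:25) {
    m <- blob_mask()
    shp <- turpeval:::cavity_shape(m, psp)
    expect_equal(shp$area_mm2, sum(m))
    expect_equal(shp$solidity, sum(m) / oracle_convex_count(m),
                 tolerance = 1e-12)
    expect_equal(shp$perimeter_mm, oracle_perimeter(m), tolerance = 0.005 * shp$perimeter_mm)
    expect_equal(shp$circularity, oracle_circularity(m), tolerance = 0.01)
  }
})
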