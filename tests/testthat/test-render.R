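pre_vol <- build_phantom(small_spec())

test_that("mean intensity ordering is validated", {
  expect_error(noise_model(mean_intensity = c(BACKGROUND = 0.5,
                                              PERIPHERAL = 0.4,
                                              CENTRAL = 0.9,
                                              CAVITY = 0.1)),
               "CENTRAL > PERIPHERAL")
})

test_that("noise-free render is piecewise constant at the label means", {
  nm <- noise_model(speckle_variance = 0, blur_sigma_mm = 0)
  st <- render_ultrasound(pre_vol, nm)
  mi <- nm$mean_intensity
  for (lb in names(LBLS)) {
    px <- st[pre_vol == LBLS[[lb]]]
    if (length(px)) expect_true(all(px == mi[[lb]]))
  }
})

test_that("noise-free renders are recoverable by midpoint thresholding", {
  nm <- noise_model(speckle_variance = 0, blur_sigma_mm = 0)
  st <- render_ultrasound(pre_vol, nm)
  mi <- sort(unlist(nm$mean_intensity[names(LBLS)]))
  mids <- head(mi, -1) + diff(mi) / 2
  codes <- LBLS[names(mi)]
  rec <- array(codes[1L + findInterval(st, mids)], dim = dim(st))
  expect_true(all(rec == unclass(pre_vol)))
})

test_that("regional mean ordering survives speckle on any seed", {
  for (s in c(1L, 99L, 2024L)) {
    st <- render_ultrasound(pre_vol, noise_model(seed = s))
    m <- vapply(c("CENTRAL", "PERIPHERAL", "CAVITY"),
                function(lb) mean(st[pre_vol == LBLS[[lb]]]), 0)
    expect_gt(m[["CENTRAL"]], m[["PERIPHERAL"]])
    expect_gt(m[["PERIPHERAL"]], m[["CAVITY"]])
  }
})

test_that("rendered region mean converges to the configured mean", {
  # means chosen away from the [0,1] clip limits: the law-of-large-
  # numbers check is only meaningful where clipping cannot bias it
  nm <- noise_model(mean_intensity = c(BACKGROUND = 0.2, PERIPHERAL = 0.45,
                                       CENTRAL = 0.7, CAVITY = 0.05),
                    speckle_variance = 0.02, blur_sigma_mm = 0, seed = 7L)
  st <- render_ultrasound(pre_vol, nm)
  central <- st[pre_vol == LBLS[["CENTRAL"]]]
  expect_gt(length(central), 1e4)
  expect_equal(mean(central), nm$mean_intensity[["CENTRAL"]],
               tolerance = 0.02)
})

test_that("rendering is seeded and reproducible", {
  st1 <- render_ultrasound(pre_vol, noise_model(seed = 11L))
  st2 <- render_ultrasound(pre_vol, noise_model(seed = 11L))
  expect_identical(unclass(st1), unclass(st2))
  st3 <- render_ultrasound(pre_vol, noise_model(seed = 12L))
  expect_false(identical(as.vector(st1), as.vector(st3)))
})

test_that("co-registered case bundles share grids and reproduce across seeds", {
  spec <- small_spec()
  seeds <- c(5L, 6L, 7L)
  pres <- lapply(seeds, function(s)
    generate_case(spec, skill_presets()$fellow, noise_model(), seed = s))
  # phantoms are identical across cases; renders and resections differ
  expect_identical(unclass(pres[[1]]$pre_labels) + 0L,
                   unclass(pres[[2]]$pre_labels) + 0L)
  expect_identical(unclass(pres[[2]]$pre_labels) + 0L,
                   unclass(pres[[3]]$pre_labels) + 0L)
  expect_identical(dim(pres[[1]]$pre_stack), dim(pres[[1]]$post_stack))
  expect_false(identical(as.vector(pres[[1]]$post_labels),
                         as.vector(pres[[2]]$post_labels)))
})

test_that("stack depth follows n_slices x slice_spacing", {
  spec <- phantom_spec(n_slices = 153L, slice_spacing_mm = 0.5,
                       embedding_margin_mm = 21, pixel_spacing_mm = 0.8)
  expect_identical(spec$n_slices, 153L)
  expect_equal(spec$n_slices * spec$slice_spacing_mm, 76.5)
  vol <- build_phantom(spec)
  expect_identical(dim(vol)[3], 153L)
})
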