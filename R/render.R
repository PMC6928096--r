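#' Pseudo-ultrasound noise model
#'
#' Phenomenological B-mode renderer parameters. Each label has a mean
#' intensity; the mean intensities must be strictly ordered
#' CENTRAL > PERIPHERAL > BACKGROUND > CAVITY, mirroring the physical
#' phantom: the central zone carries the glass-microsphere ultrasound
#' contrast agent (bright), the peripheral zone is dimmer, the embedding
#' agar is darker still, and the water-filled urethra/cavity is black.
#' Speckle is multiplicative Rayleigh-derived noise (normalized to unit
#' mean and variance `speckle_variance`), followed by a Gaussian blur of
#' scale `blur_sigma_mm` standing in for the system point-spread
#' function.
#'
#' @param mean_intensity named numeric vector of per-label means in
#'   \[0,1\] with names BACKGROUND, PERIPHERAL, CENTRAL, CAVITY
#' @param speckle_variance variance of the multiplicative speckle factor
#'   (0 = noise-free)
#' @param blur_sigma_mm Gaussian blur scale in mm (0 = no blur)
#' @param seed RNG seed
#' @return object of class `noise_model`
#' @export
#' @examples
#' noise_model(speckle_variance = 0)
noise_model <- function(mean_intensity = c(BACKGROUND = 0.15,
                                           PERIPHERAL = 0.50,
                                           CENTRAL = 0.85,
                                           CAVITY = 0.02),
                        speckle_variance = 0.02,
                        blur_sigma_mm = 0.2,
                        seed = 1L) {
  nm <- structure(list(mean_intensity = mean_intensity,
                       speckle_variance = speckle_variance,
                       blur_sigma_mm = blur_sigma_mm,
                       seed = as.integer(seed)),
                  class = "noise_model")
  validate_noise_model(nm)
  nm
}

validate_noise_model <- function(nm) {
  w <- "noise_model"
  mi <- nm$mean_intensity
  need <- names(LBL)
  if (!all(need %in% names(mi)))
    stop_invalid(w, "mean_intensity must name all labels")
  if (any(mi < 0) || any(mi > 1))
    stop_invalid(w, "mean intensities must lie in [0,1]")
  if (!(mi[["CENTRAL"]] > mi[["PERIPHERAL"]] &&
        mi[["PERIPHERAL"]] > mi[["BACKGROUND"]] &&
        mi[["BACKGROUND"]] > mi[["CAVITY"]]))
    stop_invalid(w, "mean intensities must satisfy CENTRAL > PERIPHERAL > BACKGROUND > CAVITY")
  if (nm$speckle_variance < 0) stop_invalid(w, "'speckle_variance' must be >= 0")
  if (nm$blur_sigma_mm < 0) stop_invalid(w, "'blur_sigma_mm' must be >= 0")
  invisible(nm)
}

#' Render a label volume as a pseudo-ultrasound slice stack
#'
#' Each pixel takes its label's mean intensity, multiplied by a
#' unit-mean speckle factor derived from a Rayleigh variate (clamped at
#' zero), then blurred with a Gaussian kernel and clipped to \[0,1\].
#' Seeded and reproducible; with zero speckle variance and zero blur the
#' output is exactly piecewise-constant at the label means.
#'
#' @param labels a `label_volume`
#' @param noise a [noise_model()]
#' @return object of class `slice_stack`: numeric array `[x, y, slice]`
#'   in \[0,1\] with spacing and acquisition metadata attributes
#' @export
render_ultrasound <- function(labels, noise = noise_model()) {
  validate_noise_model(noise)
  mi <- noise$mean_intensity
  lut <- numeric(4)
  lut[LBL + 1L] <- mi[names(LBL)]
  d <- dim(labels)
  img <- array(lut[as.vector(unclass(labels)) + 1L], dim = d)
  psp <- attr(labels, "pixel_spacing_mm")
  v <- noise$speckle_variance
  with_seed(noise$seed, {
    for (k in seq_len(d[3])) {
      sl <- img[, , k]
      if (v > 0) {
        # Rayleigh(1) variate, standardized to mean 1, sd sqrt(v)
        ray <- sqrt(-2 * log(runif(length(sl))))
        fac <- 1 + sqrt(v) * (ray - sqrt(pi / 2)) / sqrt(2 - pi / 2)
        sl <- sl * pmax(fac, 0)
      }
      if (noise$blur_sigma_mm > 0)
        sl <- gaussian_blur(matrix(sl, d[1], d[2]), noise$blur_sigma_mm / psp)
      img[, , k] <- pmin(pmax(sl, 0), 1)
    }
  })
  structure(img,
            pixel_spacing_mm = psp,
            slice_spacing_mm = attr(labels, "slice_spacing_mm"),
            meta = list(seed = noise$seed,
                        speckle_variance = noise$speckle_variance,
                        blur_sigma_mm = noise$blur_sigma_mm,
                        mean_intensity = as.list(mi)),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<slice_stack> %d x %d px, %d slices, intensity [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

#' Generate a complete synthetic surgical case
#'
#' Builds the pre-surgery phantom, simulates a resection, and renders
#' co-registered pre- and post-surgery pseudo-ultrasound stacks (same
#' grid, same slice indices). Stage seeds are derived deterministically
#' from `seed` and recorded in the bundle; the `seed` fields of `skill`
#' and `noise` are overridden by the derived stage seeds so that a
#' single top-level seed reproduces the whole case.
#'
#' @param spec a [phantom_spec()]
#' @param skill a [skill_profile()]
#' @param noise a [noise_model()]
#' @param seed top-level case seed
#' @return object of class `case_bundle`: list with `pre_labels`,
#'   `post_labels`, `pre_stack`, `post_stack`, `breaches`, `seed`
#' @export
#' @examples
#' cb <- generate_case(phantom_spec(n_slices = 8, pixel_spacing_mm = 0.4),
#'                     skill_presets()$expert, noise_model(), seed = 7)
generate_case <- function(spec, skill = skill_presets()$expert,
                          noise = noise_model(), seed = 1L) {
  validate_phantom_spec(spec)
  skill$seed <- derive_seed(seed, 1L)
  noise_pre <- noise; noise_pre$seed <- derive_seed(seed, 2L)
  noise_post <- noise; noise_post$seed <- derive_seed(seed, 3L)
  pre <- build_phantom(spec)
  res <- simulate_resection(pre, skill)
  structure(list(pre_labels = pre,
                 post_labels = res$volume,
                 pre_stack = render_ultrasound(pre, noise_pre),
                 post_stack = render_ultrasound(res$volume, noise_post),
                 breaches = res$breaches,
                 seed = as.integer(seed)),
            class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  d <- dim(x$pre_labels)
  cat(sprintf("<case_bundle> %d slices of %d x %d px, %d breach(es), seed %d\n",
              d[3], d[1], d[2], nrow(x$breaches), x$seed))
  invisible(x)
}
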