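#' Skill profile for a simulated resection
#'
#' Operationalizes operator quality as a small set of geometric
#' parameters of the resection cavity carved around the urethra:
#'
#' * `mean_resection_radius_mm` - target cavity radius;
#' * `roughness_amplitude` - relative radial perturbation of the cavity
#'   boundary (0 = perfectly smooth cut);
#' * `roughness_harmonics` - angular frequencies of the perturbation;
#' * `asymmetry_offset_mm` - displacement of the cavity center from the
#'   urethra axis (0 = perfectly centered cut);
#' * `breach_probability` - per-slice probability that the cut locally
#'   penetrates the peripheral zone;
#' * `breach_depth_fraction` - fraction of the local peripheral-zone
#'   thickness removed at a breach.
#'
#' @param mean_resection_radius_mm target cavity radius (mm)
#' @param roughness_amplitude relative radial perturbation, >= 0
#' @param roughness_harmonics integer angular frequencies
#' @param asymmetry_offset_mm offset of cavity center from urethra axis
#' @param breach_probability per-slice breach probability in \[0,1\]
#' @param breach_depth_fraction depth of a breach as a fraction of local
#'   peripheral thickness, in \[0,1\]
#' @param breach_width_deg angular width of the raised-cosine breach bump
#' @param seed RNG seed making the simulated surgery reproducible
#' @return object of class `skill_profile`
#' @export
#' @examples
#' skill_profile(mean_resection_radius_mm = 8, roughness_amplitude = 0.1)
skill_profile <- function(mean_resection_radius_mm = 8,
                          roughness_amplitude = 0.1,
                          roughness_harmonics = 2:8,
                          asymmetry_offset_mm = 1,
                          breach_probability = 0,
                          breach_depth_fraction = 0,
                          breach_width_deg = 40,
                          seed = 1L) {
  sp <- structure(list(
    mean_resection_radius_mm = mean_resection_radius_mm,
    roughness_amplitude = roughness_amplitude,
    roughness_harmonics = as.integer(roughness_harmonics),
    asymmetry_offset_mm = asymmetry_offset_mm,
    breach_probability = breach_probability,
    breach_depth_fraction = breach_depth_fraction,
    breach_width_deg = breach_width_deg,
    seed = as.integer(seed)
  ), class = "skill_profile")
  validate_skill_profile(sp)
  sp
}

validate_skill_profile <- function(sp) {
  w <- "skill_profile"
  check_positive(sp$mean_resection_radius_mm, "mean_resection_radius_mm", w)
  if (sp$roughness_amplitude < 0)
    stop_invalid(w, "'roughness_amplitude' must be >= 0")
  if (length(sp$roughness_harmonics) < 1L || any(sp$roughness_harmonics < 1L))
    stop_invalid(w, "'roughness_harmonics' must be positive integers")
  if (sp$asymmetry_offset_mm < 0)
    stop_invalid(w, "'asymmetry_offset_mm' must be >= 0")
  check_fraction(sp$breach_probability, "breach_probability", w)
  check_fraction(sp$breach_depth_fraction, "breach_depth_fraction", w)
  check_positive(sp$breach_width_deg, "breach_width_deg", w)
  invisible(sp)
}

#' Reference skill profiles
#'
#' Three profiles mirroring the expert / medical fellow / amateur
#' operator classes of the phantom study: the expert cuts smoothly,
#' concentrically and never breaches the peripheral zone; the fellow is
#' safe but less regular; the amateur cuts roughly, eccentrically and
#' penetrates the peripheral zone on most slices. Chosen so that the
#' simulated preservation ratio is ~1 (expert/fellow, study values
#' > 0.9) and ~0.5 (amateur).
#'
#' @param seed base seed; each profile derives its own stream from it
#' @return named list of [skill_profile()] objects
#' @export
skill_presets <- function(seed = 1L) {
  list(
    expert = skill_profile(mean_resection_radius_mm = 8,
                           roughness_amplitude = 0.05,
                           asymmetry_offset_mm = 0.3,
                           breach_probability = 0,
                           breach_depth_fraction = 0,
                           seed = derive_seed(seed, 101L)),
    fellow = skill_profile(mean_resection_radius_mm = 8,
                           roughness_amplitude = 0.15,
                           asymmetry_offset_mm = 1.2,
                           breach_probability = 0.05,
                           breach_depth_fraction = 0.3,
                           seed = derive_seed(seed, 102L)),
    amateur = skill_profile(mean_resection_radius_mm = 8,
                            roughness_amplitude = 0.35,
                            asymmetry_offset_mm = 2.5,
                            breach_probability = 0.8,
                            breach_depth_fraction = 0.6,
                            seed = derive_seed(seed, 103L))
  )
}

#' Simulate a transurethral resection on a phantom volume
#'
#' Per slice, replaces tissue with CAVITY inside a closed star-shaped
#' boundary around the (offset) urethra axis. The boundary radius is
#' `mean_resection_radius_mm` modulated by random roughness harmonics,
#' clipped to the central zone except where a seeded per-slice breach
#' event extends the cut into the peripheral zone by
#' `breach_depth_fraction` of the local peripheral thickness, as a
#' raised-cosine angular bump. The urethra lumen always remains part of
#' the cavity. Slices without a central-zone cross-section are left
#' untouched.
#'
#' @param phantom a pre-surgery `label_volume` from [build_phantom()]
#' @param skill a [skill_profile()]
#' @return list with components `volume` (post-surgery `label_volume`)
#'   and `breaches` (data.frame: slice, angle_rad, depth_mm,
#'   depth_fraction) - the ground-truth breach record
#' @export
simulate_resection <- function(phantom, skill) {
  validate_skill_profile(skill)
  spec <- attr(phantom, "spec")
  if (is.null(spec)) stop("phantom must carry its phantom_spec", call. = FALSE)
  if (skill$mean_resection_radius_mm <= spec$urethra_radius_mm)
    stop("mean_resection_radius_mm must exceed the urethra radius: no resection possible",
         call. = FALSE)

  ax <- grid_axes(spec)
  z <- slice_z(spec)
  p <- spec$shape_exponent
  ao <- spec$width_mm / 2; bo <- spec$depth_mm / 2; co <- spec$height_mm / 2
  s <- spec$central_zone_scale
  nx <- length(ax$x); ny <- length(ax$y)
  X <- matrix(ax$x, nx, ny)
  Y <- matrix(ax$y, nx, ny, byrow = TRUE)
  n_theta <- 720L
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]

  out <- phantom
  breaches <- list()

  with_seed(skill$seed, {
    # one eccentricity direction per surgery, fixed along the urethra
    phi0 <- runif(1, 0, 2 * pi)
    cx <- skill$asymmetry_offset_mm * cos(phi0)
    cy <- skill$asymmetry_offset_mm * sin(phi0)
    for (k in seq_along(z)) {
      # per-slice draws happen unconditionally so that the random stream
      # (and hence every slice's geometry) is invariant to what other
      # slices did - this makes breach-depth sweeps comparable per seed
      nh <- length(skill$roughness_harmonics)
      ck <- rnorm(nh, 0, sqrt(1 / (2 * nh)))
      sk <- rnorm(nh, 0, sqrt(1 / (2 * nh)))
      breach_u <- runif(1)
      breach_angle <- runif(1, 0, 2 * pi)

      cs_in <- cross_section(z[k], ao * s[1], bo * s[2], co * s[3], p)
      if (is.null(cs_in)) next
      if (superellipse_val(cx, cy, cs_in$a, cs_in$b, p) > 1) next
      cs_out <- cross_section(z[k], ao, bo, co, p)

      g <- rep(0, n_theta)
      for (h in seq_len(nh)) {
        m <- skill$roughness_harmonics[h]
        g <- g + ck[h] * cos(m * theta) + sk[h] * sin(m * theta)
      }
      r_star <- skill$mean_resection_radius_mm * (1 + skill$roughness_amplitude * g)
      r_star <- pmax(r_star, 0)

      d_central <- superellipse_ray(cx, cy, theta, cs_in$a, cs_in$b, p)
      r_cav <- pmin(r_star, d_central)

      if (breach_u < skill$breach_probability && skill$breach_depth_fraction > 0) {
        d_outer <- superellipse_ray(cx, cy, theta, cs_out$a, cs_out$b, p)
        half_w <- skill$breach_width_deg / 2 * pi / 180
        dang <- atan2(sin(theta - breach_angle), cos(theta - breach_angle))
        bump <- ifelse(abs(dang) <= half_w,
                       (1 + cos(pi * dang / half_w)) / 2, 0)
        r_breach <- d_central +
          bump * skill$breach_depth_fraction * pmax(d_outer - d_central, 0)
        r_cav <- pmax(r_cav, ifelse(bump > 0, r_breach, 0))
        i0 <- which.min(abs(dang))
        breaches[[length(breaches) + 1L]] <- data.frame(
          slice = k, angle_rad = breach_angle,
          depth_mm = skill$breach_depth_fraction *
            max(d_outer[i0] - d_central[i0], 0),
          depth_fraction = skill$breach_depth_fraction)
      }

      th_px <- atan2(Y - cy, X - cx)
      r_px <- sqrt((X - cx)^2 + (Y - cy)^2)
      r_lim <- approx(x = c(theta, 2 * pi), y = c(r_cav, r_cav[1]),
                      xout = th_px %% (2 * pi), rule = 2)$y
      dim(r_lim) <- dim(th_px)
      sl <- out[, , k]
      cav <- (r_px <= r_lim & sl != LBL[["BACKGROUND"]]) |
        sl == LBL[["CAVITY"]]
      sl[cav] <- LBL[["CAVITY"]]
      out[, , k] <- sl
    }
  })

  breaches <- if (length(breaches)) do.call(rbind, breaches) else
    data.frame(slice = integer(), angle_rad = numeric(),
               depth_mm = numeric(), depth_fraction = numeric())
  meta <- attr(out, "meta")
  meta$skill <- unclass(skill)
  attr(out, "meta") <- meta
  list(volume = out, breaches = breaches)
}
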