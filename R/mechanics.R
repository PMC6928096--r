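#' Cyclic flat-punch indentation trace
#'
#' Wraps a time / displacement / force table with the measurement
#' geometry needed for the modulus calculation: a rigid cylindrical
#' (flat-punch) indenter of radius `a_mm` pressed into a soft sample of
#' thickness `thickness_mm`, driven sinusoidally at `frequency_hz`
#' around a pre-compression offset.
#'
#' @param t_s time (s), strictly increasing
#' @param displacement_mm indenter displacement (mm, positive into the
#'   sample)
#' @param force_n measured force (N)
#' @param a_mm indenter radius (default 3)
#' @param thickness_mm sample thickness (default 6)
#' @param nu Poisson's ratio (default 0.495, near-incompressible gel)
#' @param frequency_hz loading frequency (default 0.5)
#' @param precompression pre-compression strain (default 0.02)
#' @param strain_amplitude cyclic strain amplitude (e.g. 0.03, 0.05,
#'   0.08)
#' @return object of class `indentation_trace` (data.frame with
#'   geometry attributes)
#' @export
indentation_trace <- function(t_s, displacement_mm, force_n,
                              a_mm = 3, thickness_mm = 6, nu = 0.495,
                              frequency_hz = 0.5, precompression = 0.02,
                              strain_amplitude = 0.05) {
  if (length(t_s) != length(displacement_mm) ||
      length(t_s) != length(force_n))
    stop("t_s, displacement_mm and force_n must have equal length", call. = FALSE)
  if (any(diff(t_s) <= 0))
    stop("t_s must be strictly increasing", call. = FALSE)
  check_positive(a_mm, "a_mm", "indentation_trace")
  check_positive(thickness_mm, "thickness_mm", "indentation_trace")
  check_positive(frequency_hz, "frequency_hz", "indentation_trace")
  if (nu < 0 || nu >= 0.5)
    stop_invalid("indentation_trace", "'nu' must be in [0, 0.5)")
  structure(data.frame(t_s = t_s, displacement_mm = displacement_mm,
                       force_n = force_n),
            a_mm = a_mm, thickness_mm = thickness_mm, nu = nu,
            frequency_hz = frequency_hz, precompression = precompression,
            strain_amplitude = strain_amplitude,
            class = c("indentation_trace", "data.frame"))
}

#' Synthesize an indentation trace from a known modulus
#'
#' Inverts the flat-punch relation `E = 2 (1 - nu^2) q a / w` with
#' `q = F / (pi a^2)` to generate a sinusoidal displacement/force pair
#' for a material of modulus `E_pa`, optionally with a viscoelastic
#' phase lag of the force and additive white noise at a given SNR.
#' Used for round-trip validation and as a test fixture generator.
#'
#' @param E_pa elastic modulus (Pa)
#' @param n_cycles number of full cycles
#' @param fs_hz sampling rate (default 200)
#' @param phase_lag_deg force lag behind displacement (0 = elastic)
#' @param snr_db additive white-noise SNR on both channels in dB
#'   (Inf = noise-free)
#' @param seed RNG seed for the noise
#' @inheritParams indentation_trace
#' @return an [indentation_trace()]
#' @export
make_indentation_trace <- function(E_pa, n_cycles = 32L, fs_hz = 200,
                                   a_mm = 3, thickness_mm = 6, nu = 0.495,
                                   frequency_hz = 0.5,
                                   precompression = 0.02,
                                   strain_amplitude = 0.05,
                                   phase_lag_deg = 0, snr_db = Inf,
                                   seed = 1L) {
  t_s <- seq(0, n_cycles / frequency_hz, by = 1 / fs_hz)
  w0 <- precompression * thickness_mm
  w_amp <- strain_amplitude * thickness_mm
  disp <- w0 + w_amp * sin(2 * pi * frequency_hz * t_s)
  # F = E w pi a / (2 (1 - nu^2)); a, w in m give N
  f_of_w <- function(w_mm) E_pa * (w_mm / 1000) * pi * (a_mm / 1000) /
    (2 * (1 - nu^2))
  force <- f_of_w(w0) + f_of_w(w_amp) *
    sin(2 * pi * frequency_hz * t_s - phase_lag_deg * pi / 180)
  if (is.finite(snr_db)) {
    amp_ratio <- 10^(snr_db / 20)
    with_seed(seed, {
      disp <- disp + rnorm(length(t_s), 0, w_amp / sqrt(2) / amp_ratio)
      force <- force + rnorm(length(t_s), 0, f_of_w(w_amp) / sqrt(2) / amp_ratio)
    })
  }
  indentation_trace(t_s, disp, force, a_mm = a_mm,
                    thickness_mm = thickness_mm, nu = nu,
                    frequency_hz = frequency_hz,
                    precompression = precompression,
                    strain_amplitude = strain_amplitude)
}

trace_attrs <- function(trace) {
  attributes(trace)[c("a_mm", "thickness_mm", "nu", "frequency_hz",
                      "precompression", "strain_amplitude")]
}

#' Trim an indentation trace to its steady-state cycles
#'
#' Locates cycle boundaries from rising zero-crossings of the detrended
#' displacement and keeps the last `use_cycles` complete periods,
#' requiring at least `skip_cycles + use_cycles` periods in the trace
#' (defaults match the measurement protocol: 10 run-in cycles skipped,
#' 20 steady-state cycles used).
#'
#' @param trace an [indentation_trace()]
#' @param skip_cycles run-in cycles to discard (default 10)
#' @param use_cycles steady-state cycles to keep (default 20)
#' @return trimmed `indentation_trace` with attribute `steady = TRUE`
#' @export
steady_state_cycles <- function(trace, skip_cycles = 10L, use_cycles = 20L) {
  d <- trace$displacement_mm - mean(trace$displacement_mm)
  up <- which(d[-length(d)] < 0 & d[-1] >= 0)
  f <- attr(trace, "frequency_hz")
  spanned <- diff(range(trace$t_s)) * f
  if (spanned < skip_cycles + use_cycles - 1e-6 ||
      length(up) < use_cycles + 1L)
    stop(sprintf("trace spans only %.1f full cycles; need %d (skip %d + use %d)",
                 spanned, skip_cycles + use_cycles,
                 skip_cycles, use_cycles), call. = FALSE)
  i0 <- up[length(up) - use_cycles]
  i1 <- up[length(up)]
  out <- trace[(i0 + 1L):i1, , drop = FALSE]
  at <- trace_attrs(trace)
  out <- do.call(indentation_trace,
                 c(list(out$t_s, out$displacement_mm, out$force_n), at))
  attr(out, "steady") <- TRUE
  out
}

#' Phase shift between displacement and force
#'
#' Phase angle of the force fundamental relative to the displacement
#' fundamental, from single-frequency Fourier projection at the trace's
#' loading frequency. Near 0 for an elastic (in-phase) response;
#' positive when the force lags.
#'
#' @param trace a steady-state [indentation_trace()]
#' @return phase shift in degrees, in (-180, 180\]
#' @export
phase_shift <- function(trace) {
  f <- attr(trace, "frequency_hz")
  t <- trace$t_s
  w <- 2 * pi * f
  proj <- function(x) {
    x <- x - mean(x)
    if (all(x == 0)) stop("zero-amplitude signal", call. = FALSE)
    complex(real = sum(x * cos(w * t)), imaginary = -sum(x * sin(w * t)))
  }
  dphi <- Arg(proj(trace$displacement_mm)) - Arg(proj(trace$force_n))
  deg <- dphi * 180 / pi
  ((deg + 180) %% 360) - 180
}

#' Compressive elastic modulus from a flat-punch indentation trace
#'
#' Applies the rigid flat-punch relation `E = 2 (1 - nu^2) q a / w`
#' with `q = F_amp / (pi a^2)` the load density (mean contact pressure
#' amplitude), `a` the punch radius and `w` the displacement amplitude.
#' Amplitudes come from the Fourier fundamental at the loading frequency
#' by default (`mode = "fourier"`, robust to additive noise) or from
#' half the peak-to-peak excursion (`mode = "ptp"`). The trace is
#' trimmed with [steady_state_cycles()] unless already marked steady;
#' traces too short to trim are used as-is with a warning. A phase shift
#' beyond `phase_threshold_deg` indicates a viscoelastic response and
#' attaches a warning to the result rather than failing.
#'
#' @param trace an [indentation_trace()]
#' @param mode amplitude estimator: "fourier" or "ptp"
#' @param phase_threshold_deg elasticity check threshold (default 5)
#' @param skip_cycles,use_cycles passed to [steady_state_cycles()]
#' @return object of class `modulus_result`: `E_pa`, `q_pa`, `w_mm`,
#'   `phase_deg`, `cycles_used`, `mode`, `warnings`
#' @export
#' @examples
#' tr <- make_indentation_trace(20e3)
#' elastic_modulus(tr)
elastic_modulus <- function(trace, mode = c("fourier", "ptp"),
                            phase_threshold_deg = 5,
                            skip_cycles = 10L, use_cycles = 20L) {
  mode <- match.arg(mode)
  warns <- character()
  if (!isTRUE(attr(trace, "steady"))) {
    trimmed <- tryCatch(steady_state_cycles(trace, skip_cycles, use_cycles),
                        error = function(e) NULL)
    if (is.null(trimmed)) {
      warns <- c(warns, "trace too short to trim; using full trace")
      warning(warns[length(warns)], call. = FALSE)
    } else trace <- trimmed
  }
  a_mm <- attr(trace, "a_mm")
  nu <- attr(trace, "nu")
  f <- attr(trace, "frequency_hz")
  phi <- phase_shift(trace)
  if (abs(phi) > phase_threshold_deg) {
    warns <- c(warns, sprintf(
      "phase shift %.1f deg exceeds %.1f deg: response is not purely elastic",
      phi, phase_threshold_deg))
    warning(warns[length(warns)], call. = FALSE)
  }
  amp <- function(x) {
    if (mode == "ptp") return((max(x) - min(x)) / 2)
    x <- x - mean(x)
    t <- trace$t_s
    2 * Mod(complex(real = sum(x * cos(2 * pi * f * t)),
                    imaginary = -sum(x * sin(2 * pi * f * t)))) / length(x)
  }
  w_mm <- amp(trace$displacement_mm)
  if (w_mm <= 0) stop("zero displacement amplitude", call. = FALSE)
  f_amp <- amp(trace$force_n)
  q_pa <- f_amp / (pi * (a_mm / 1000)^2)
  E_pa <- 2 * (1 - nu^2) * q_pa * (a_mm / 1000) / (w_mm / 1000)
  structure(list(E_pa = E_pa, q_pa = q_pa, w_mm = w_mm, phase_deg = phi,
                 cycles_used = round(diff(range(trace$t_s)) * f),
                 mode = mode, nu = nu, a_mm = a_mm, warnings = warns),
            class = "modulus_result")
}

#' @export
print.modulus_result <- function(x, ...) {
  cat(sprintf("<modulus_result> E = %.4g Pa (q = %.4g Pa, w = %.4g mm, phase %.2f deg, %d cycles, %s)\n",
              x$E_pa, x$q_pa, x$w_mm, x$phase_deg, x$cycles_used, x$mode))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
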