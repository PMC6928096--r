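test_that("steady-state trimming keeps the requested cycles", {
  tr <- make_indentation_trace(20e3, n_cycles = 30L)
  st <- steady_state_cycles(tr)
  f <- attr(st, "frequency_hz")
  expect_equal(diff(range(st$t_s)) * f, 20, tolerance = 0.01)
  expect_error(steady_state_cycles(make_indentation_trace(20e3, n_cycles = 8L)),
               "cycles")
  # retained mean displacement equals the pre-compression offset
  expect_equal(mean(st$displacement_mm), 0.02 * 6, tolerance = 0.01 * 0.02 * 6)
})

test_that("phase shift recovers injected lags", {
  expect_equal(phase_shift(steady_state_cycles(make_indentation_trace(20e3))),
               0, tolerance = 0.5)
  expect_equal(phase_shift(steady_state_cycles(
    make_indentation_trace(20e3, phase_lag_deg = 10))), 10, tolerance = 0.5)
  lag_noisy <- replicate(5, {
    tr <- make_indentation_trace(20e3, snr_db = 20,
                                 seed = sample.int(1e6, 1))
    phase_shift(steady_state_cycles(tr))
  })
  expect_true(all(abs(lag_noisy) < 2))
  flat <- make_indentation_trace(20e3, strain_amplitude = 1e-12)
  flat$force_n <- rep(0, nrow(flat))
  expect_error(phase_shift(flat), "zero-amplitude")
})

test_that("the flat-punch formula evaluates its closed forms", {
  # q = 1 kPa, a = 3 mm, nu = 0.495, w = 0.1 mm
  E <- 2 * (1 - 0.495^2) * 1000 * 0.003 / (0.1 / 1000)
  expect_equal(E, 45298.5)
  # nu = 0, q a / w = 1 Pa -> E = 2 Pa
  expect_equal(2 * (1 - 0^2) * 1, 2)
  # the estimator reproduces them through a synthesized trace
  tr <- make_indentation_trace(45298.5, nu = 0.495)
  expect_equal(elastic_modulus(tr)$E_pa, 45298.5, tolerance = 1e-6)
})

test_that("round-trip recovery is within 1% noise-free and 5% at SNR 20 dB", {
  for (E in c(5e3, 20e3, 80e3)) {
    tr <- make_indentation_trace(E)
    expect_equal(elastic_modulus(tr)$E_pa, E, tolerance = 0.01)
    expect_equal(elastic_modulus(tr, mode = "ptp")$E_pa, E, tolerance = 0.01)
  }
  errs <- vapply(1:6, function(s) {
    tr <- make_indentation_trace(20e3, snr_db = 20, seed = s)
    abs(elastic_modulus(tr)$E_pa - 20e3) / 20e3
  }, 0)
  expect_true(all(errs < 0.05))
})

test_that("modulus is invariant to resampling and scales as the formula says", {
  tr1 <- make_indentation_trace(30e3, fs_hz = 200)
  tr2 <- make_indentation_trace(30e3, fs_hz = 357)
  expect_equal(elastic_modulus(tr1)$E_pa, elastic_modulus(tr2)$E_pa,
               tolerance = 1e-3)
  # linear in force amplitude, inverse in displacement amplitude
  base <- make_indentation_trace(30e3)
  doubled <- base
  doubled$force_n <- 2 * (doubled$force_n - mean(doubled$force_n)) +
    mean(doubled$force_n)
  expect_equal(elastic_modulus(doubled)$E_pa, 60e3, tolerance = 1e-3)
  halfdisp <- base
  halfdisp$displacement_mm <- 0.5 * (halfdisp$displacement_mm -
    mean(halfdisp$displacement_mm)) + mean(halfdisp$displacement_mm)
  expect_equal(elastic_modulus(halfdisp)$E_pa, 60e3, tolerance = 1e-3)
})

test_that("viscoelastic traces warn through the phase gate", {
  tr <- make_indentation_trace(20e3, phase_lag_deg = 12)
  expect_warning(res <- elastic_modulus(tr), "not purely elastic")
  expect_equal(res$phase_deg, 12, tolerance = 0.5)
  expect_true(length(res$warnings) > 0)
})
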