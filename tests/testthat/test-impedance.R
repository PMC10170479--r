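# Equivalent-circuit evaluation and fitting.

test_that("the circuit model has the right asymptotes and a hand-computed value at 12 Hz", {
  p <- circuit_params(100, 1000, 100e-9, 1e9)  # huge C_el: negligible in series
  # capacitors short at high frequency: Z -> r_sol
  expect_equal(Re(circuit_impedance(p, 1e12)), 100, tolerance = 1e-6)
  # DC limit of the parallel RC: Z -> r_sol + r_teer
  expect_equal(Re(circuit_impedance(p, 1e-9)), 1100, tolerance = 1e-6)
  # independent evaluation written out term by term
  p2 <- circuit_params(100, 1000, 100e-9, 1e-6)
  w <- 2 * pi * 12
  z_hand <- 100 + 1 / (1i * w * 1e-6) + 1000 / (1 + 1i * w * 1000 * 100e-9)
  expect_equal(circuit_impedance(p2, 12), z_hand)
  expect_error(circuit_impedance(p2, 0), "positive")
  # conjugate symmetry of the rational form, evaluated directly
  z_neg <- 100 + 1 / (1i * (-w) * 1e-6) + 1000 / (1 + 1i * (-w) * 1000 * 100e-9)
  expect_equal(z_neg, Conj(z_hand))
})

test_that("noiseless spectra are inverted to six significant digits", {
  p <- circuit_params(100, 1000, 100e-9, 1e-6)
  sp <- simulate_impedance_spectrum(p, noise_fraction = 0)
  fit <- fit_circuit(sp)
  expect_true(all(abs(unlist(fit$params) / unlist(p) - 1) < 5e-7))
  expect_lt(fit$residual, 1e-8)
})

test_that("r_teer is recovered within 5% under 2% multiplicative noise", {
  p <- circuit_params(100, 1000, 100e-9, 1e-6)
  errs <- vapply(1:30, function(s) {
    sp <- simulate_impedance_spectrum(p, noise_fraction = 0.02, seed = s)
    abs(fit_circuit(sp)$params$r_teer_ohm / 1000 - 1)
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("estimator bias vanishes as the noise goes to zero", {
  p <- circuit_params(100, 1000, 100e-9, 1e-6)
  bias <- vapply(c(0.02, 0.002), function(nf) {
    mean(vapply(1:20, function(s) {
      sp <- simulate_impedance_spectrum(p, noise_fraction = nf, seed = s)
      fit_circuit(sp)$params$r_teer_ohm / 1000 - 1
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(bias[2]), abs(bias[1]) + 1e-3)
  expect_lt(abs(bias[2]), 0.005)
})

test_that("a pure-resistor spectrum leaves the barrier element unidentifiable", {
  f <- default_freq_grid()
  sp <- impedance_spectrum(f, complex(real = rep(500, 50), imaginary = 0))
  res <- tryCatch(fit_circuit(sp), error = function(e) e)
  if (inherits(res, "circuit_fit")) {
    expect_true(res$boundary)
  } else {
    expect_s3_class(res, "error")
  }
})

test_that("fit_circuit enforces its sampling preconditions", {
  p <- circuit_params(100, 1000, 100e-9, 1e-6)
  few <- simulate_impedance_spectrum(p, freq_hz = 10^seq(5, 1, length.out = 5))
  expect_error(fit_circuit(few), "at least 8")
  narrow <- simulate_impedance_spectrum(p, freq_hz = seq(10, 100, length.out = 12))
  expect_error(fit_circuit(narrow), "decades")
})

test_that("the Bode modulus interpolates |Z| log-log at 12 Hz", {
  p <- circuit_params(100, 1000, 100e-9, 1e-6)
  sp <- simulate_impedance_spectrum(p, noise_fraction = 0)
  # grid point: exact
  f0 <- sp$freq_hz[20]
  expect_equal(bode_modulus_at(sp, f0), Mod(circuit_impedance(p, f0)))
  # off grid: close to the analytic modulus on this smooth spectrum
  expect_equal(bode_modulus_at(sp, 12), Mod(circuit_impedance(p, 12)),
               tolerance = 1e-3)
  expect_error(bode_modulus_at(sp, 1e7), "outside")
})

test_that("TEER time courses flag the maturation peak", {
  days <- 1:7
  r_teer <- c(800, 1500, 2400, 2000, 1500, 1200, 1000)  # peak at day 3
  tab <- tibble::tibble(day = days, r_teer_ohm = r_teer,
                        c_membrane_f = 100e-9)
  tc <- teer_timecourse(tab)
  expect_equal(attr(tc, "peak_day"), 3)
  expect_false(attr(tc, "peak_at_boundary"))
  expect_equal(tc$day[tc$is_peak], 3)
  mono <- teer_timecourse(tibble::tibble(day = 1:4,
                                         r_teer_ohm = c(1, 2, 3, 4) * 500,
                                         c_membrane_f = 1e-7))
  expect_true(attr(mono, "peak_at_boundary"))
  single <- teer_timecourse(tibble::tibble(day = 1, r_teer_ohm = 500,
                                           c_membrane_f = 1e-7))
  expect_true(is.na(attr(single, "peak_day")))
})

test_that("tidy and glance summarize circuit fits", {
  p <- circuit_params(100, 1000, 100e-9, 1e-6)
  fit <- fit_circuit(simulate_impedance_spectrum(p, noise_fraction = 0.01,
                                                 seed = 2))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("r_sol_ohm", "r_teer_ohm", "c_membrane_f",
                          "c_electrode_f"))
  expect_true(all(td$estimate > 0))
  expect_equal(nrow(generics::glance(fit)), 1)
})
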