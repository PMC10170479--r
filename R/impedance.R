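#' Complex impedance of the epithelial equivalent circuit
#'
#' Evaluates the equivalent circuit used for barrier monitoring: the
#' tight-junction resistance `r_teer` in parallel with the membrane
#' capacitance `c_membrane`, in series with the solution resistance `r_sol`
#' and the electrode capacitance `c_electrode`:
#' \deqn{Z(\omega) = R_{sol} + \frac{1}{j\omega C_{el}} +
#'   \frac{R_{teer}}{1 + j\omega R_{teer} C_m}, \quad \omega = 2\pi f.}
#'
#' @param params A [circuit_params()].
#' @param freq_hz Strictly positive frequencies, Hz.
#' @return Complex impedance values, ohm.
#' @examples
#' circuit_impedance(circuit_params(100, 1000, 100e-9, 1e-6), 12)
#' @export
circuit_impedance <- function(params, freq_hz) {
  stopifnot(inherits(params, "circuit_params"))
  if (!is.numeric(freq_hz) || any(!is.finite(freq_hz)) || any(freq_hz <= 0)) {
    abort("`freq_hz` must be strictly positive finite frequencies.")
  }
  w <- 2 * pi * freq_hz
  params$r_sol_ohm +
    1 / (1i * w * params$c_electrode_f) +
    params$r_teer_ohm / (1 + 1i * w * params$r_teer_ohm * params$c_membrane_f)
}

#' Build an impedance-spectrum table
#'
#' @param freq_hz Frequencies, Hz.
#' @param z Complex impedance, ohm.
#' @param day,condition Optional metadata recorded as columns.
#' @return An `impedance_spectrum` tibble with columns `freq_hz`,
#'   `z_real_ohm`, `z_imag_ohm`.
#' @export
impedance_spectrum <- function(freq_hz, z, day = NA_real_,
                               condition = NA_character_) {
  if (length(freq_hz) != length(z)) abort("freq and z lengths differ.")
  if (any(freq_hz <= 0) || any(!is.finite(freq_hz))) {
    abort("frequencies must be positive and finite.")
  }
  if (any(!is.finite(Re(z))) || any(!is.finite(Im(z)))) {
    abort("impedance values must be finite.")
  }
  out <- tibble(freq_hz = as.numeric(freq_hz),
                z_real_ohm = Re(z), z_imag_ohm = Im(z),
                day = day, condition = condition)
  class(out) <- c("impedance_spectrum", class(out))
  out
}

spectrum_z <- function(spec) complex(real = spec$z_real_ohm,
                                     imaginary = spec$z_imag_ohm)

#' Simulate a noisy impedance spectrum from known circuit parameters
#'
#' Evaluates [circuit_impedance()] on the given grid (default: 50
#' log-spaced points from 100 kHz down to 0.1 Hz, the standard acquisition
#' sweep) and perturbs each point with multiplicative complex Gaussian noise
#' of relative magnitude `noise_fraction`.
#'
#' @param params A [circuit_params()].
#' @param freq_hz Frequency grid, Hz.
#' @param noise_fraction Relative noise level (0 = exact spectrum).
#' @param seed Seed, or `NULL`.
#' @inheritParams impedance_spectrum
#' @return An `impedance_spectrum` tibble.
#' @export
simulate_impedance_spectrum <- function(params,
                                        freq_hz = default_freq_grid(),
                                        noise_fraction = 0, seed = NULL,
                                        day = NA_real_,
                                        condition = NA_character_) {
  check_number(noise_fraction, "noise_fraction", nonneg = TRUE)
  z <- circuit_impedance(params, freq_hz)
  if (noise_fraction > 0) {
    z <- with_seed(seed, {
      n <- length(z)
      z * (1 + noise_fraction *
             complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2))
    })
  }
  impedance_spectrum(freq_hz, z, day = day, condition = condition)
}

#' Default acquisition frequency grid
#'
#' 50 points, logarithmically spaced from 100 kHz down to 0.1 Hz.
#' @return Numeric vector of frequencies, Hz (descending).
#' @export
default_freq_grid <- function() 10^seq(5, -1, length.out = 50)

#' Fit the equivalent circuit to an impedance spectrum
#'
#' Nonlinear least squares on the stacked real and imaginary residuals,
#' weighted by `1/|Z|` so every frequency decade contributes comparably.
#' Positivity of all four parameters is enforced by optimizing their
#' logarithms (Levenberg-Marquardt via \pkg{minpack.lm}). Initial values are
#' taken from the spectrum's asymptotes unless supplied: `r_sol` from the
#' highest-frequency modulus, `r_teer` from the rise of the low-frequency
#' real part, and the capacitances from characteristic corner frequencies.
#'
#' @param spec An `impedance_spectrum` (or data frame with `freq_hz`,
#'   `z_real_ohm`, `z_imag_ohm`).
#' @param init A [circuit_params()] starting point, or `NULL` for auto-init.
#' @return A `circuit_fit` object: fitted [circuit_params()] values, the
#'   relative RMS residual, and the parameter covariance (log scale).
#' @export
fit_circuit <- function(spec, init = NULL) {
  spec <- as_tibble(spec)
  if (nrow(spec) < 8) abort("need at least 8 frequency points.")
  if (diff(range(log10(spec$freq_hz))) < 3) {
    abort("spectrum must span at least 3 frequency decades.")
  }
  z <- spectrum_z(spec)
  f <- spec$freq_hz
  wts <- 1 / Mod(z)

  resid_fn <- function(theta) {
    p <- circuit_params(exp(theta[1]), exp(theta[2]), exp(theta[3]),
                        exp(theta[4]))
    zm <- circuit_impedance(p, f)
    c(wts * (Re(zm) - Re(z)), wts * (Im(zm) - Im(z)))
  }
  run_lm <- function(theta0) {
    minpack.lm::nls.lm(
      par = theta0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    )
  }
  if (is.null(init)) {
    # the asymptote-based start can land in a local minimum when noise at
    # the extreme frequencies corrupts the plateaus, so try a small grid of
    # perturbed starts and keep the best converged fit
    base <- auto_init_circuit(f, z)
    theta_base <- log(unlist(base))
    starts <- list(theta_base)
    for (d_rt in c(-2, 0, 2)) {
      for (d_cm in c(-4, -2, 0, 2)) {
        if (d_rt == 0 && d_cm == 0) next
        starts <- c(starts, list(theta_base + c(0, d_rt, d_cm, 0)))
      }
    }
    fits <- lapply(starts, function(s) tryCatch(run_lm(s),
                                                error = function(e) NULL))
    fits <- Filter(function(ft) !is.null(ft) && all(is.finite(ft$par)), fits)
    if (!length(fits)) abort("circuit fit failed from every starting point.")
    dev <- vapply(fits, function(ft) sum(ft$fvec^2), numeric(1))
    fit <- fits[[which.min(dev)]]
  } else {
    theta0 <- log(unlist(init[c("r_sol_ohm", "r_teer_ohm",
                                "c_membrane_f", "c_electrode_f")]))
    fit <- run_lm(theta0)
  }
  if (fit$info %in% c(0, 9) || any(!is.finite(fit$par))) {
    abort(sprintf(
      "circuit fit did not converge (info %d); best residual %.3g with parameters %s",
      fit$info, sqrt(mean(fit$fvec^2)),
      paste(signif(exp(fit$par), 4), collapse = ", ")))
  }
  p <- exp(fit$par)
  rel_rms <- sqrt(mean(fit$fvec^2) / mean((wts * Mod(z))^2) * 2)
  cov_log <- tryCatch({
    h <- fit$hessian
    s2 <- sum(fit$fvec^2) / max(1, length(fit$fvec) - 4)
    s2 * solve(h)
  }, error = function(e) matrix(NA_real_, 4, 4))
  # flag a practically unidentifiable barrier element (e.g. pure resistor
  # spectra): the membrane corner frequency never enters the measured band
  boundary <- p[2] < 1e-6 * p[1] || !all(is.finite(diag(cov_log)))
  structure(
    list(params = circuit_params(p[1], p[2], p[3], p[4]),
         residual = rel_rms, cov_log = cov_log,
         boundary = boundary, n = nrow(spec),
         day = spec$day[1], condition = spec$condition[1]),
    class = "circuit_fit"
  )
}

# Heuristic starting values from spectral asymptotes.
auto_init_circuit <- function(f, z) {
  ord <- order(f)
  f <- f[ord]; z <- z[ord]
  r_sol <- max(Re(z)[which.max(f)], 1e-3)
  # at low frequency the real part tends to r_sol + r_teer
  r_lo <- stats::median(Re(z)[f <= stats::quantile(f, 0.1)])
  r_teer <- max(r_lo - r_sol, 0.05 * r_sol)
  # electrode capacitance from the lowest-frequency reactance
  x_lo <- -Im(z)[1]
  c_el <- 1 / (2 * pi * f[1] * max(x_lo, 1e-9))
  # membrane corner frequency f_c = 1/(2 pi R C): pick the frequency where
  # the real part is halfway between the two plateaus
  target <- r_sol + r_teer / 2
  i_c <- which.min(abs(Re(z) - target))
  c_m <- 1 / (2 * pi * f[i_c] * r_teer)
  circuit_params(r_sol, r_teer, max(c_m, 1e-15), max(c_el, 1e-15))
}

#' @export
print.circuit_fit <- function(x, ...) {
  cat("<circuit_fit>\n")
  print(x$params)
  cat(sprintf("  relative RMS residual: %.3g  (n = %d)\n", x$residual, x$n))
  if (x$boundary) cat("  warning: fit at/near a parameter boundary\n")
  invisible(x)
}

#' @rdname fit_circuit
#' @param x A `circuit_fit`.
#' @param ... Unused.
#' @method tidy circuit_fit
#' @export
tidy.circuit_fit <- function(x, ...) {
  est <- unlist(x$params)
  se_log <- sqrt(pmax(diag(x$cov_log), 0))
  tibble(
    term = c("r_sol_ohm", "r_teer_ohm", "c_membrane_f", "c_electrode_f"),
    estimate = as.numeric(est),
    std.error = as.numeric(est * se_log)  # delta method from log scale
  )
}

#' @rdname fit_circuit
#' @method glance circuit_fit
#' @export
glance.circuit_fit <- function(x, ...) {
  tibble(residual = x$residual, nobs = x$n, boundary = x$boundary)
}

#' Bode modulus interpolated at a target frequency
#'
#' `|Z|` is interpolated log-log at `f0` (default 12 Hz, the standard
#' growth-monitoring frequency). Exact at grid points.
#'
#' @param spec An `impedance_spectrum`.
#' @param f0 Target frequency, Hz (must lie inside the measured range).
#' @return Modulus in ohm.
#' @export
bode_modulus_at <- function(spec, f0 = 12) {
  spec <- as_tibble(spec)
  check_number(f0, "f0", positive = TRUE)
  f <- spec$freq_hz
  if (f0 < min(f) || f0 > max(f)) {
    abort(sprintf("f0 = %g Hz is outside the measured range [%g, %g] Hz.",
                  f0, min(f), max(f)))
  }
  modz <- Mod(spectrum_z(spec))
  ord <- order(f)
  10^approx(log10(f[ord]), log10(modz[ord]), xout = log10(f0))$y
}

#' TEER and capacitance time course from per-day circuit fits
#'
#' Orders the fits by day, tabulates `r_teer` and `c_membrane`, and flags
#' the day at which `r_teer` peaks (barrier maturation). A peak on the first
#' or last day is flagged as a boundary peak; with a single time point no
#' peak is reported.
#'
#' @param fits A list of `circuit_fit` objects (each carrying a `day`), or a
#'   data frame with columns `day`, `r_teer_ohm`, `c_membrane_f`.
#' @return A tibble (class `teer_timecourse`) with columns `day`,
#'   `r_teer_ohm`, `c_membrane_nf`, `is_peak`, and attributes `peak_day`,
#'   `peak_at_boundary`.
#' @export
teer_timecourse <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- as_tibble(fits)
  } else {
    tab <- purrr::map_dfr(fits, function(ft) {
      stopifnot(inherits(ft, "circuit_fit"))
      tibble(day = ft$day, r_teer_ohm = ft$params$r_teer_ohm,
             c_membrane_f = ft$params$c_membrane_f)
    })
  }
  if (nrow(tab) < 2) {
    out <- mutate(tab, c_membrane_nf = .data$c_membrane_f * 1e9,
                  is_peak = FALSE)
    attr(out, "peak_day") <- NA_real_
    attr(out, "peak_at_boundary") <- NA
    class(out) <- c("teer_timecourse", class(out))
    return(out)
  }
  tab <- arrange(tab, .data$day)
  i <- which.max(tab$r_teer_ohm)
  out <- tab |>
    mutate(c_membrane_nf = .data$c_membrane_f * 1e9,
           is_peak = row_number() == i) |>
    select("day", "r_teer_ohm", "c_membrane_nf", "is_peak")
  attr(out, "peak_day") <- tab$day[i]
  attr(out, "peak_at_boundary") <- i %in% c(1L, nrow(tab))
  class(out) <- c("teer_timecourse", class(out))
  out
}

#' Plot an impedance spectrum as a Bode modulus diagram
#'
#' @param object An `impedance_spectrum`.
#' @param fit Optional `circuit_fit` overlaid as a line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot impedance_spectrum
#' @export
autoplot.impedance_spectrum <- function(object, fit = NULL, ...) {
  df <- as_tibble(object) |> mutate(mod = Mod(spectrum_z(object)))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$mod)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "|Z| (ohm)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    fgrid <- 10^seq(log10(min(df$freq_hz)), log10(max(df$freq_hz)),
                    length.out = 200)
    line <- tibble(freq_hz = fgrid,
                   mod = Mod(circuit_impedance(fit$params, fgrid)))
    p <- p + ggplot2::geom_line(data = line, colour = "red3")
  }
  p
}

#' Plot a TEER/capacitance time course
#'
#' @param object A `teer_timecourse`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot teer_timecourse
#' @export
autoplot.teer_timecourse <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("r_teer_ohm", "c_membrane_nf"),
                            names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_peak),
                        show.legend = FALSE) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL) +
    ggplot2::theme_minimal()
}

#' Read and write impedance-spectrum CSV files
#'
#' Plain CSV with columns `freq_hz`, `z_real_ohm`, `z_imag_ohm` (and any
#' metadata columns present).
#'
#' @param spec An `impedance_spectrum`.
#' @param path CSV path.
#' @export
write_spectrum <- function(spec, path) {
  readr::write_csv(as_tibble(spec), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  impedance_spectrum(df$freq_hz,
                     complex(real = df$z_real_ohm, imaginary = df$z_imag_ohm),
                     day = df$day %||% NA_real_,
                     condition = df$condition %||% NA_character_)
}
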