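#' Viscosity from an MSD curve, purely viscous branch
#'
#' For free diffusion in two dimensions `MSD = 4 D tau`; `D` is obtained by
#' a through-origin least-squares fit over the chosen lags and converted to
#' viscosity with the Stokes-Einstein relation
#' `eta = kB T / (6 pi D a)`.
#'
#' @param msd An `msd_curve` for a single region.
#' @param radius_m Tracer radius, metres.
#' @param temperature_k Absolute temperature, kelvin.
#' @param fit_range Integer lag indices used in the fit (default: all).
#' @return A `rheology_result`: `regime`, `diffusion_um2_s`,
#'   `viscosity_cp`, `fit_range`, `region`.
#' @export
viscosity_viscous <- function(msd, radius_m, temperature_k = 298.15,
                              fit_range = NULL) {
  msd <- one_region(msd)
  check_number(radius_m, "radius_m", positive = TRUE)
  check_number(temperature_k, "temperature_k", positive = TRUE)
  fit_range <- fit_range %||% seq_len(nrow(msd))
  sub <- msd[fit_range, ]
  D_um2 <- sum(sub$lag_s * sub$msd_um2) / (4 * sum(sub$lag_s^2))
  if (!is.finite(D_um2) || D_um2 <= 0) {
    abort(sprintf("fitted diffusivity is non-positive (%.3g um^2/s).", D_um2))
  }
  eta_pas <- .kB * temperature_k / (6 * pi * (D_um2 * 1e-12) * radius_m)
  new_rheology_result(
    regime = "viscous", region = msd$region[1],
    diffusion_um2_s = D_um2, viscosity_cp = pas_to_cp(eta_pas),
    elastic_modulus_pa = NA_real_, fit_range = fit_range
  )
}

#' Viscosity and elastic modulus from an MSD curve, viscoelastic branch
#'
#' The MSD is converted to the creep compliance through the generalized
#' Stokes-Einstein relation, `J(t) = (3 pi a / (2 kB T)) MSD(t)`, and the
#' Maxwell model `J(t) = 1/G + t/eta` is fitted by ordinary least squares:
#' the intercept gives the elastic modulus, the inverse slope the viscosity.
#'
#' When the static localization error of the tracking stage is known, its
#' MSD offset (`2 n sigma^2` with `n = 2` dimensions) can be subtracted
#' before conversion via `localization_sd_m`; this is the standard static
#' error correction of particle-tracking microrheology and matters mostly
#' for the plateau (elastic) term.
#'
#' @inheritParams viscosity_viscous
#' @param localization_sd_m Known per-axis localization error (m), or `NULL`
#'   for no correction.
#' @return A `rheology_result` with `viscosity_cp` and
#'   `elastic_modulus_pa`.
#' @export
viscosity_viscoelastic <- function(msd, radius_m, temperature_k = 298.15,
                                   fit_range = NULL,
                                   localization_sd_m = NULL) {
  msd <- one_region(msd)
  check_number(radius_m, "radius_m", positive = TRUE)
  check_number(temperature_k, "temperature_k", positive = TRUE)
  fit_range <- fit_range %||% seq_len(nrow(msd))
  sub <- msd[fit_range, ]
  msd_m2 <- sub$msd_um2 * 1e-12
  if (!is.null(localization_sd_m)) {
    check_number(localization_sd_m, "localization_sd_m", nonneg = TRUE)
    msd_m2 <- msd_m2 - 4 * localization_sd_m^2
  }
  J <- (3 * pi * radius_m / (2 * .kB * temperature_k)) * msd_m2  # 1/Pa
  # inverse-variance weights: the time-averaged MSD has relative variance
  # growing linearly with the lag index (fewer, more correlated pairs), so
  # long lags must not dominate the extrapolated intercept
  k_idx <- seq_along(J)
  wls <- 1 / (pmax(J, .Machine$double.eps)^2 * k_idx)
  fit <- lm(J ~ sub$lag_s, weights = wls)
  intercept <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  if (slope <= 0) {
    abort(sprintf("creep-compliance slope is non-positive (%.3g); the medium does not flow over the observed lags.", slope))
  }
  if (intercept <= 0) {
    abort(sprintf("creep-compliance intercept is non-positive (%.3g 1/Pa); no elastic plateau is resolvable. Consider the viscous branch.", intercept))
  }
  new_rheology_result(
    regime = "viscoelastic", region = msd$region[1],
    diffusion_um2_s = NA_real_,
    viscosity_cp = pas_to_cp(1 / slope),
    elastic_modulus_pa = 1 / intercept,
    fit_range = fit_range
  )
}

new_rheology_result <- function(regime, region, diffusion_um2_s,
                                viscosity_cp, elastic_modulus_pa,
                                fit_range, alpha = NA_real_) {
  structure(
    list(regime = regime, region = region, alpha = alpha,
         diffusion_um2_s = diffusion_um2_s, viscosity_cp = viscosity_cp,
         elastic_modulus_pa = elastic_modulus_pa, fit_range = fit_range),
    class = "rheology_result"
  )
}

#' @export
print.rheology_result <- function(x, ...) {
  cat(sprintf("<rheology_result> region %s, %s", x$region, x$regime))
  if (is.finite(x$alpha)) cat(sprintf(" (alpha = %.3f)", x$alpha))
  cat("\n")
  cat(sprintf("  viscosity: %.4g cP", x$viscosity_cp))
  if (is.finite(x$elastic_modulus_pa)) {
    cat(sprintf(", G: %.4g Pa", x$elastic_modulus_pa))
  }
  if (is.finite(x$diffusion_um2_s)) {
    cat(sprintf(", D: %.4g um^2/s", x$diffusion_um2_s))
  }
  cat("\n")
  invisible(x)
}

#' @rdname fit_rheology
#' @param x A `rheology_result`.
#' @param ... Unused.
#' @method tidy rheology_result
#' @export
tidy.rheology_result <- function(x, ...) {
  tibble(region = x$region, regime = x$regime, alpha = x$alpha,
         diffusion_um2_s = x$diffusion_um2_s,
         viscosity_cp = x$viscosity_cp,
         elastic_modulus_pa = x$elastic_modulus_pa)
}

#' Full microrheology analysis of an MSD curve
#'
#' For every region: fit the power-law exponent, classify the regime
#' (threshold 0.95 on `alpha`), and run the corresponding branch —
#' Stokes-Einstein for a viscous medium, Maxwell creep-compliance fit for a
#' viscoelastic one. Falls back to the viscous branch if the viscoelastic
#' fit finds no positive elastic plateau.
#'
#' @param msd An `msd_curve` (any number of regions) or a
#'   [trajectory_set()] (MSD computed with defaults first).
#' @inheritParams viscosity_viscoelastic
#' @param alpha_threshold Regime classification threshold.
#' @return A tibble with one row per region: `region`, `alpha`, `regime`,
#'   `diffusion_um2_s`, `viscosity_cp`, `elastic_modulus_pa`.
#' @examples
#' gt <- rheo_ground_truth(1e-3, n_particles = 50, n_frames = 100, seed = 1)
#' msd <- compute_msd(simulate_brownian_trajectories(gt))
#' fit_rheology(msd, radius_m = 100e-9)
#' @export
fit_rheology <- function(msd, radius_m, temperature_k = 298.15,
                         fit_range = NULL, alpha_threshold = 0.95,
                         localization_sd_m = NULL) {
  if (inherits(msd, "trajectory_set")) msd <- compute_msd(msd)
  msd <- as_tibble(msd)
  purrr::map_dfr(split(msd, msd$region), function(m) {
    pl <- fit_power_law(m, fit_range)
    regime <- classify_regime(pl$alpha, alpha_threshold)
    res <- if (regime == "viscous") {
      viscosity_viscous(m, radius_m, temperature_k, fit_range)
    } else {
      tryCatch(
        viscosity_viscoelastic(m, radius_m, temperature_k, fit_range,
                               localization_sd_m),
        error = function(e) viscosity_viscous(m, radius_m, temperature_k,
                                              fit_range)
      )
    }
    res$alpha <- pl$alpha
    tidy(res)
  })
}
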