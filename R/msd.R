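#' Time-averaged mean squared displacement per region
#'
#' For every particle the MSD at lag `tau = k / frame_rate` is the time
#' average over all ordered frame pairs `(t, t + tau)` within its trajectory;
#' region curves are the unweighted mean of the per-particle curves over all
#' particles imaged in that region. Lags are limited to `max_lag_fraction`
#' of each trajectory's length, because long-lag estimates average very few
#' pairs and are noise-dominated.
#'
#' @param traj A [trajectory_set()].
#' @param max_lag_fraction Largest lag as a fraction of trajectory length.
#' @param min_length Trajectories shorter than this many frames are
#'   excluded.
#' @return An `msd_curve` tibble: `region`, `lag_s`, `msd_um2`,
#'   `n_contributing`; attribute `frame_rate`.
#' @examples
#' gt <- rheo_ground_truth(1e-3, n_particles = 20, n_frames = 50, seed = 1)
#' msd <- compute_msd(simulate_brownian_trajectories(gt))
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25, min_length = 10L) {
  stopifnot(inherits(traj, "trajectory_set"))
  fr <- frame_rate_of(traj)
  df <- as_tibble(traj) |>
    group_by(.data$region, .data$particle) |>
    filter(n() >= min_length) |>
    ungroup()
  if (!nrow(df)) {
    abort(sprintf("no trajectory with at least %d frames; cannot compute an MSD.",
                  min_length))
  }
  per_particle <- df |>
    group_by(.data$region, .data$particle) |>
    summarise(msd = list(msd_single(.data$x_um, .data$y_um,
                                    max_lag_fraction)),
              .groups = "drop") |>
    tidyr::unnest("msd")
  out <- per_particle |>
    group_by(.data$region, .data$lag) |>
    summarise(msd_um2 = mean(.data$msd_um2),
              n_contributing = n(), .groups = "drop") |>
    mutate(lag_s = .data$lag / fr) |>
    select("region", "lag_s", "msd_um2", "n_contributing") |>
    arrange(.data$region, .data$lag_s)
  attr(out, "frame_rate") <- fr
  class(out) <- c("msd_curve", class(out))
  out
}

# All-ordered-pairs time-averaged MSD of one track; returns a tibble of
# integer lag and msd.
msd_single <- function(x, y, max_lag_fraction) {
  L <- length(x)
  kmax <- max(1L, floor(max_lag_fraction * L))
  purrr::map_dfr(seq_len(kmax), function(k) {
    dx <- x[(1 + k):L] - x[1:(L - k)]
    dy <- y[(1 + k):L] - y[1:(L - k)]
    tibble(lag = k, msd_um2 = mean(dx^2 + dy^2))
  })
}

#' Plot MSD curves on log-log axes
#'
#' @param object An `msd_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag_s, .data$msd_um2,
                                       colour = factor(.data$region))) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"),
                  y = expression(MSD ~ (mu * m^2)), colour = "region") +
    ggplot2::theme_minimal()
}

#' Power-law exponent of an MSD curve
#'
#' Least-squares line in log(tau) vs log(MSD); the slope is the anomalous
#' exponent `alpha` (1 for free diffusion, < 1 for subdiffusion in a
#' viscoelastic medium, 2 for ballistic motion).
#'
#' @param msd An `msd_curve` covering a single region.
#' @param fit_range Integer indices of the lags used (default: all).
#' @return A list with `alpha`, `prefactor` (MSD at 1 s under the power
#'   law), and `fit_range`.
#' @export
fit_power_law <- function(msd, fit_range = NULL) {
  msd <- one_region(msd)
  fit_range <- fit_range %||% seq_len(nrow(msd))
  sub <- msd[fit_range, ]
  if (nrow(sub) < 3) abort("need at least 3 lags in the fit range.")
  if (any(sub$msd_um2 <= 0)) {
    abort("MSD values in the fit range must be positive (log-log fit).")
  }
  fit <- lm(log(msd_um2) ~ log(lag_s), data = sub)
  list(alpha = unname(coef(fit)[2]),
       prefactor = unname(exp(coef(fit)[1])),
       fit_range = fit_range)
}

one_region <- function(msd) {
  msd <- as_tibble(msd)
  regs <- unique(msd$region)
  if (length(regs) > 1) {
    abort("this operation expects an MSD curve from a single region; filter or map over regions (see fit_rheology()).")
  }
  msd
}

#' Classify the rheological regime from the MSD exponent
#'
#' The medium is treated as purely viscous when `alpha` strictly exceeds
#' the threshold (default 0.95) and as viscoelastic otherwise; exactly at
#' the threshold counts as viscoelastic.
#'
#' @param alpha Anomalous exponent.
#' @param threshold Classification threshold.
#' @return `"viscous"` or `"viscoelastic"`.
#' @export
classify_regime <- function(alpha, threshold = 0.95) {
  check_number(alpha, "alpha")
  if (alpha > threshold) "viscous" else "viscoelastic"
}
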