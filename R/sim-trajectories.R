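#' Simulate Brownian tracer trajectories in a purely viscous fluid
#'
#' Per-axis displacement increments are independent Gaussians with variance
#' `2 D dt`, where the diffusivity follows the Stokes-Einstein relation
#' `D = kB T / (6 pi eta a)`. Optional localization noise is added to the
#' reported positions (not to the underlying physical path), emulating the
#' static error of centroid tracking.
#'
#' @param truth A [rheo_ground_truth()] without an elastic modulus.
#' @param n_regions Number of imaging regions; particles are split evenly
#'   across regions (a typical mucus MPT run images >= 8 regions).
#' @param start_box_um Side of the square (µm) over which initial positions
#'   are scattered uniformly.
#' @param start_positions_um Optional `n_particles x 2` matrix of starting
#'   positions (µm), overriding the random scatter (useful for rendering
#'   well-separated spots).
#' @return A [trajectory_set()] with attribute `ground_truth` (the input) and
#'   `diffusivity_um2_s` (the Stokes-Einstein D in µm²/s).
#' @examples
#' gt <- rheo_ground_truth(1e-3, n_particles = 5, n_frames = 50, seed = 1)
#' traj <- simulate_brownian_trajectories(gt)
#' @export
simulate_brownian_trajectories <- function(truth, n_regions = 1L,
                                           start_box_um = 50,
                                           start_positions_um = NULL) {
  stopifnot(inherits(truth, "rheo_ground_truth"))
  if (!is.null(truth$elastic_modulus_pa)) {
    abort("truth has an elastic modulus; use simulate_viscoelastic_trajectories().")
  }
  n_regions <- check_count(n_regions, "n_regions")
  D_m2 <- stokes_einstein_D(truth$viscosity_pas, truth$particle_radius_m,
                            truth$temperature_k)
  D_um2 <- D_m2 * 1e12
  dt <- 1 / truth$frame_rate
  step_sd_um <- sqrt(2 * D_um2 * dt)
  loc_sd_um <- truth$localization_noise_sd_m * 1e6

  traj <- with_seed(truth$seed, {
    purrr::map_dfr(seq_len(truth$n_particles), function(p) {
      x0 <- if (is.null(start_positions_um)) {
        stats::runif(2, 0, start_box_um)
      } else {
        start_positions_um[p, ]
      }
      dxy <- matrix(rnorm(2 * (truth$n_frames - 1L), sd = step_sd_um),
                    ncol = 2)
      pos <- rbind(x0, sweep(apply(dxy, 2, cumsum), 2, x0, "+"))
      dimnames(pos) <- NULL
      obs <- pos
      if (loc_sd_um > 0) {
        obs <- obs + matrix(rnorm(2 * truth$n_frames, sd = loc_sd_um), ncol = 2)
      }
      tibble(particle = p, frame = seq_len(truth$n_frames),
             x_um = obs[, 1], y_um = obs[, 2],
             region = ((p - 1L) %% n_regions) + 1L)
    })
  })
  out <- trajectory_set(traj, frame_rate = truth$frame_rate)
  attr(out, "ground_truth") <- truth
  attr(out, "diffusivity_um2_s") <- D_um2
  out
}

# Per-axis target MSD (µm^2) of a Maxwell medium observed by a bead of radius
# `a`: total 2D MSD(t) = (2 kB T / (3 pi a)) (1/G + t/eta); each axis carries
# half of it.
maxwell_msd_axis_um2 <- function(t_s, truth) {
  pref <- .kB * truth$temperature_k / (3 * pi * truth$particle_radius_m)
  (pref * (1 / truth$elastic_modulus_pa + t_s / truth$viscosity_pas)) * 1e12
}

#' Simulate tracer trajectories in a Maxwell viscoelastic fluid
#'
#' Positions are drawn from a zero-mean Gaussian process whose structure
#' function reproduces the Maxwell target
#' `MSD(t) = (2 kB T / (3 pi a)) (1/G + t/eta)` at every observable lag.
#' The covariance is built as `C(t, s) = (m(t) + m(s) - m(|t - s|)) / 2` from
#' the per-axis target `m` (with `m(0) = 0`), Cholesky-factorized once and
#' shared by all particles; if the factorization fails numerically, a small
#' diagonal jitter is added and reported via a message.
#'
#' @inheritParams simulate_brownian_trajectories
#' @return A [trajectory_set()] with the ground truth attached.
#' @examples
#' gt <- rheo_ground_truth(20e-3, elastic_modulus_pa = 1,
#'                         n_particles = 10, n_frames = 50, seed = 1)
#' traj <- simulate_viscoelastic_trajectories(gt)
#' @export
simulate_viscoelastic_trajectories <- function(truth, n_regions = 1L,
                                               start_box_um = 50,
                                               start_positions_um = NULL) {
  stopifnot(inherits(truth, "rheo_ground_truth"))
  if (is.null(truth$elastic_modulus_pa)) {
    abort("truth lacks an elastic modulus; use simulate_brownian_trajectories().")
  }
  n_regions <- check_count(n_regions, "n_regions")
  nf <- truth$n_frames
  dt <- 1 / truth$frame_rate
  t_s <- (seq_len(nf) - 1L) * dt
  m <- maxwell_msd_axis_um2(t_s, truth)
  m[1] <- 0  # structure function convention: m(0) = 0 so X(0) is pinned
  C <- outer(seq_len(nf), seq_len(nf), function(i, j) {
    (m[i] + m[j] - m[abs(i - j) + 1L]) / 2
  })
  L <- tryCatch(chol(C[-1L, -1L, drop = FALSE]), error = function(e) NULL)
  if (is.null(L)) {
    jitter <- 1e-12 * max(diag(C))
    message(sprintf("covariance regularized with diagonal jitter %.3g um^2",
                    jitter))
    L <- tryCatch(chol(C[-1L, -1L] + diag(jitter, nf - 1L)),
                  error = function(e) {
                    abort("target covariance is not positive definite even after regularization.")
                  })
  }
  loc_sd_um <- truth$localization_noise_sd_m * 1e6

  traj <- with_seed(truth$seed, {
    purrr::map_dfr(seq_len(truth$n_particles), function(p) {
      x0 <- if (is.null(start_positions_um)) {
        stats::runif(2, 0, start_box_um)
      } else {
        start_positions_um[p, ]
      }
      z <- matrix(rnorm(2 * (nf - 1L)), ncol = 2)
      pos <- rbind(c(0, 0), crossprod(L, z))  # t(L) %*% z gives cov C
      pos <- sweep(pos, 2, x0, "+")
      if (loc_sd_um > 0) {
        pos <- pos + matrix(rnorm(2 * nf, sd = loc_sd_um), ncol = 2)
      }
      tibble(particle = p, frame = seq_len(nf),
             x_um = pos[, 1], y_um = pos[, 2],
             region = ((p - 1L) %% n_regions) + 1L)
    })
  })
  out <- trajectory_set(traj, frame_rate = truth$frame_rate)
  attr(out, "ground_truth") <- truth
  out
}

#' Analytic target MSD of a simulated medium
#'
#' Returns the two-dimensional ensemble MSD the generator aims at:
#' `4 D t` for a viscous medium, `(2 kB T / (3 pi a)) (1/G + t/eta)` for a
#' Maxwell medium. Useful as the reference curve in recovery tests.
#'
#' @param truth A [rheo_ground_truth()].
#' @param lag_s Lag times in seconds.
#' @return Numeric vector of MSD values in µm².
#' @export
target_msd_um2 <- function(truth, lag_s) {
  stopifnot(inherits(truth, "rheo_ground_truth"))
  if (is.null(truth$elastic_modulus_pa)) {
    D_um2 <- stokes_einstein_D(truth$viscosity_pas, truth$particle_radius_m,
                               truth$temperature_k) * 1e12
    4 * D_um2 * lag_s
  } else {
    2 * maxwell_msd_axis_um2(lag_s, truth)
  }
}
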