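# MSD estimation and viscosity/elastic-modulus extraction.

test_that("compute_msd equals the brute-force all-pairs oracle exactly", {
  gt <- rheo_ground_truth(18e-3, n_particles = 3, n_frames = 20, seed = 13)
  traj <- simulate_brownian_trajectories(gt)
  msd <- compute_msd(traj, min_length = 10)
  expect_equal(msd$msd_um2, brute_force_msd(traj))
  expect_equal(msd$lag_s[1], 1 / 20)  # first lag = 1/frame_rate
  expect_equal(msd$n_contributing, rep(3L, nrow(msd)))
})

test_that("degenerate motion gives the expected MSD laws", {
  fr <- 20
  # stationary particle: MSD identically zero
  still <- trajectory_set(
    tibble::tibble(particle = 1L, frame = 1:40, x_um = 3, y_um = 4),
    frame_rate = fr)
  msd0 <- compute_msd(still)
  expect_true(all(msd0$msd_um2 == 0))
  expect_error(fit_power_law(msd0), "positive")
  # ballistic motion x = v t: MSD = v^2 tau^2, alpha exactly 2
  v <- 1.5
  ball <- trajectory_set(
    tibble::tibble(particle = 1L, frame = 1:40,
                   x_um = v * (1:40) / fr, y_um = 0),
    frame_rate = fr)
  msd2 <- compute_msd(ball)
  expect_equal(msd2$msd_um2, v^2 * msd2$lag_s^2)
  expect_equal(fit_power_law(msd2)$alpha, 2, tolerance = 1e-10)
})

test_that("MSD is additive over duplicated particle sets and errors when no track qualifies", {
  gt <- rheo_ground_truth(18e-3, n_particles = 4, n_frames = 30, seed = 3)
  traj <- simulate_brownian_trajectories(gt)
  doubled <- dplyr::mutate(tibble::as_tibble(traj),
                           particle = particle + 100L)
  both <- trajectory_set(dplyr::bind_rows(tibble::as_tibble(traj), doubled),
                         frame_rate = 20)
  expect_equal(compute_msd(both)$msd_um2, compute_msd(traj)$msd_um2)
  short <- trajectory_set(
    tibble::tibble(particle = 1L, frame = 1:5, x_um = 1:5, y_um = 0),
    frame_rate = 20)
  expect_error(compute_msd(short), "at least")
})

test_that("the regime threshold is strict at alpha = 0.95", {
  expect_equal(classify_regime(1.0), "viscous")
  expect_equal(classify_regime(0.5), "viscoelastic")
  expect_equal(classify_regime(0.95), "viscoelastic")
})

test_that("the viscous branch inverts Stokes-Einstein exactly on an ideal MSD", {
  # construct MSD = 4 D tau with D for eta = 2 cP, and demand eta back
  D <- 1.380649e-23 * 298.15 / (6 * pi * 2e-3 * 100e-9) * 1e12
  lags <- (1:20) / 20
  msd <- structure(
    tibble::tibble(region = 1L, lag_s = lags, msd_um2 = 4 * D * lags,
                   n_contributing = 100L),
    frame_rate = 20, class = c("msd_curve", class(tibble::tibble())))
  res <- viscosity_viscous(msd, radius_m = 100e-9)
  expect_equal(res$viscosity_cp, 2, tolerance = 1e-12)
  expect_equal(res$diffusion_um2_s, D, tolerance = 1e-12)
  # eta scales linearly with T at fixed D
  res_hot <- viscosity_viscous(msd, radius_m = 100e-9,
                               temperature_k = 2 * 298.15)
  expect_equal(res_hot$viscosity_cp, 4, tolerance = 1e-12)
})

test_that("viscosity is recovered within 10% across the mucus range", {
  for (eta_cp in c(1, 18)) {
    gt <- rheo_ground_truth(eta_cp * 1e-3, n_particles = 300,
                            n_frames = 100, seed = 40 + eta_cp)
    msd <- compute_msd(simulate_brownian_trajectories(gt))
    fit <- fit_rheology(msd, radius_m = gt$particle_radius_m,
                        localization_sd_m = gt$localization_noise_sd_m)
    expect_equal(fit$viscosity_cp, eta_cp, tolerance = 0.1)
  }
})

test_that("alpha is near 1 for Brownian motion and below 0.95 for a strong Maxwell plateau", {
  gt <- rheo_ground_truth(1e-3, n_particles = 300, n_frames = 100,
                          localization_noise_sd_m = 0, seed = 8)
  msd <- compute_msd(simulate_brownian_trajectories(gt))
  expect_equal(fit_power_law(msd)$alpha, 1, tolerance = 0.05)
  gtm <- rheo_ground_truth(20e-3, elastic_modulus_pa = 0.5,
                           n_particles = 300, n_frames = 100,
                           localization_noise_sd_m = 0, seed = 9)
  msdm <- compute_msd(simulate_viscoelastic_trajectories(gtm))
  expect_lt(fit_power_law(msdm)$alpha, 0.95)
})

test_that("the Maxwell branch recovers both moduli and J(0) = 1/G", {
  gt <- rheo_ground_truth(20e-3, elastic_modulus_pa = 1, n_particles = 400,
                          n_frames = 100, seed = 17)
  msd <- compute_msd(simulate_viscoelastic_trajectories(gt))
  res <- viscosity_viscoelastic(msd, radius_m = gt$particle_radius_m,
                                localization_sd_m = gt$localization_noise_sd_m)
  expect_equal(res$viscosity_cp, 20, tolerance = 0.15)
  expect_equal(res$elastic_modulus_pa, 1, tolerance = 0.15)
})

test_that("both branches agree on viscosity for nearly-viscous data", {
  gt <- rheo_ground_truth(5e-3, n_particles = 400, n_frames = 100,
                          seed = 23)  # localization noise gives J a small positive intercept
  msd <- compute_msd(simulate_brownian_trajectories(gt))
  eta_v <- viscosity_viscous(msd, 100e-9)$viscosity_cp
  eta_ve <- viscosity_viscoelastic(msd, 100e-9)$viscosity_cp
  expect_equal(eta_ve / eta_v, 1, tolerance = 0.1)
})

test_that("units round-trip between Pa.s and cP", {
  expect_equal(mucochip:::pas_to_cp(18e-3), 18)
  expect_equal(mucochip:::cp_to_pas(33), 33e-3)
})
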