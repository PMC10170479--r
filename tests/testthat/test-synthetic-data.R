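# Generators: Brownian and Maxwell trajectories, spectra, traces, z-stacks.

test_that("Stokes-Einstein diffusivity matches the closed form", {
  # kB T / (6 pi eta a) at 1 cP, a = 100 nm, T = 298.15 K
  D_expected <- 1.380649e-23 * 298.15 / (6 * pi * 1e-3 * 100e-9)  # m^2/s
  expect_equal(D_expected * 1e12, 2.18381, tolerance = 1e-5)
  gt <- rheo_ground_truth(1e-3, seed = 1)
  traj <- simulate_brownian_trajectories(gt)
  expect_equal(attr(traj, "diffusivity_um2_s"), D_expected * 1e12)
})

test_that("Brownian increments have the Stokes-Einstein variance and the ensemble MSD follows 4 D tau", {
  gt <- rheo_ground_truth(1e-3, n_particles = 300, n_frames = 100,
                          localization_noise_sd_m = 0, seed = 7)
  traj <- simulate_brownian_trajectories(gt)
  D <- attr(traj, "diffusivity_um2_s")
  msd <- compute_msd(traj)
  expect_true(all(abs(msd$msd_um2 / (4 * D * msd$lag_s) - 1) < 0.05))
})

test_that("a near-infinite viscosity freezes the particles", {
  gt <- rheo_ground_truth(1e6, n_particles = 5, n_frames = 50,
                          localization_noise_sd_m = 0, seed = 1)
  traj <- simulate_brownian_trajectories(gt)
  disp <- do.call(rbind, lapply(split(traj, traj$particle), function(d) {
    cbind(diff(d$x_um), diff(d$y_um))
  }))
  expect_lt(max(abs(disp)), 1e-3)
})

test_that("generators are bit-identical under a fixed seed", {
  gt <- rheo_ground_truth(18e-3, n_particles = 20, n_frames = 30, seed = 99)
  expect_identical(simulate_brownian_trajectories(gt),
                   simulate_brownian_trajectories(gt))
  gtv <- rheo_ground_truth(20e-3, elastic_modulus_pa = 1, n_particles = 10,
                           n_frames = 30, seed = 99)
  expect_identical(simulate_viscoelastic_trajectories(gtv),
                   simulate_viscoelastic_trajectories(gtv))
  expect_identical(simulate_cilia_trace(8, 100, 2, noise_sd = 0.3, seed = 5),
                   simulate_cilia_trace(8, 100, 2, noise_sd = 0.3, seed = 5))
})

test_that("parameter validation rejects unphysical ground truths", {
  expect_error(rheo_ground_truth(-1), "positive")
  expect_error(rheo_ground_truth(1e-3, particle_radius_m = 0), "positive")
  expect_error(rheo_ground_truth(1e-3, n_frames = 1), "integer")
  expect_error(circuit_params(0, 1, 1, 1), "positive")
})

test_that("Maxwell generator reproduces the analytic creep MSD", {
  gt <- rheo_ground_truth(20e-3, elastic_modulus_pa = 1, n_particles = 500,
                          n_frames = 100, localization_noise_sd_m = 0,
                          seed = 11)
  traj <- simulate_viscoelastic_trajectories(gt)
  msd <- compute_msd(traj)
  target <- target_msd_um2(gt, msd$lag_s)
  sub <- msd$lag_s <= 1
  expect_true(all(abs(msd$msd_um2[sub] / target[sub] - 1) < 0.05))
})

test_that("the Maxwell target has the 1/G plateau at t = 0 and the viscous limit at large G", {
  gt <- rheo_ground_truth(20e-3, elastic_modulus_pa = 1)
  plateau <- 2 * 1.380649e-23 * 298.15 / (3 * pi * 100e-9 * 1) * 1e12
  expect_equal(target_msd_um2(gt, 0), plateau)
  # G -> infinity: target collapses onto the purely viscous 4 D t line
  gt_stiff <- rheo_ground_truth(20e-3, elastic_modulus_pa = 1e9)
  gt_visc <- rheo_ground_truth(20e-3)
  lags <- seq(0.05, 2, by = 0.05)
  expect_equal(target_msd_um2(gt_stiff, lags), target_msd_um2(gt_visc, lags),
               tolerance = 1e-6)
})

test_that("noiseless simulated spectra equal the circuit model on the standard 50-point sweep", {
  p <- circuit_params(100, 1000, 100e-9, 1e-6)
  grid <- default_freq_grid()
  expect_length(grid, 50)
  expect_equal(range(grid), c(0.1, 1e5))
  sp <- simulate_impedance_spectrum(p, grid, noise_fraction = 0)
  z <- circuit_impedance(p, grid)
  expect_equal(sp$z_real_ohm, Re(z))
  expect_equal(sp$z_imag_ohm, Im(z))
})

test_that("a vanishing barrier resistance makes |Z| insensitive to the membrane capacitance", {
  f <- default_freq_grid()
  z1 <- circuit_impedance(circuit_params(100, 1e-9, 1e-9, 1e-6), f)
  z2 <- circuit_impedance(circuit_params(100, 1e-9, 1e-5, 1e-6), f)
  expect_equal(Mod(z1), Mod(z2), tolerance = 1e-9)
})

test_that("cilia traces carry the requested number of oscillations and honour Nyquist", {
  tr <- simulate_cilia_trace(8, frame_rate = 100, duration_s = 2)
  peaks <- mucochip:::find_peaks(tr$intensity, 0.1)
  expect_length(peaks, 16)
  flat <- simulate_cilia_trace(0, 100, 1)
  expect_equal(var(flat$intensity), 0)
  expect_error(simulate_cilia_trace(8, frame_rate = 10, duration_s = 1),
               "Nyquist")
})

test_that("two-layer z-stacks store the realized gap and round off-grid gaps with a warning", {
  zs <- simulate_two_layer_zstack(30, 1, seed = 1)
  expect_equal(attr(zs, "truth")$gap_um, 30)
  expect_equal(attr(zs, "truth")$bead_bottom_edge_um -
                 attr(zs, "truth")$cell_top_edge_um, 30)
  expect_warning(zs2 <- simulate_two_layer_zstack(9.75, 1, seed = 1),
                 "rounded")
  expect_equal(attr(zs2, "truth")$gap_um, 10)
  zs0 <- simulate_two_layer_zstack(0, 1, seed = 1)
  expect_equal(attr(zs0, "truth")$gap_um, 0)
})

test_that("rendered videos put the brightness where the particles are", {
  traj <- trajectory_set(
    tibble::tibble(particle = 1L, frame = 1:3, x_um = 12.3, y_um = 20.7),
    frame_rate = 20)
  vid <- render_spot_video(traj, c(40, 40), pixel_size_um = 1, snr = Inf)
  for (f in 1:3) {
    peak <- which(vid[, , f] == max(vid[, , f]), arr.ind = TRUE)
    expect_equal(unname(peak[1, ]), c(21, 12))  # row = y, col = x
  }
  # off-field positions are rejected with the offending frames named
  far <- trajectory_set(
    tibble::tibble(particle = 1L, frame = 1:2, x_um = c(5, 99), y_um = 5),
    frame_rate = 20)
  expect_error(render_spot_video(far, c(40, 40), 1), "frame")
  # empty trajectory set renders pure noise
  none <- trajectory_set(
    tibble::tibble(particle = integer(0), frame = integer(0),
                   x_um = numeric(0), y_um = numeric(0)), frame_rate = 20)
  noise <- render_spot_video(none, c(16, 16), 1, snr = 5, n_frames = 4,
                             seed = 2)
  expect_equal(dim(noise), c(16, 16, 4))
  expect_gt(sd(noise), 0)
})
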