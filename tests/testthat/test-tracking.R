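# Spot detection and proximity-principle linking.

test_that("centroid detection is sub-pixel accurate on a clean Gaussian spot", {
  traj <- trajectory_set(
    tibble::tibble(particle = 1L, frame = 1L, x_um = 10.3, y_um = 20.7),
    frame_rate = 20)
  vid <- render_spot_video(traj, c(40, 40), pixel_size_um = 1,
                           psf_sigma_px = 1.5, snr = Inf)
  det <- detect_spots(vid[, , 1], intensity_threshold = 1)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - 10.3), 0.1)
  expect_lt(abs(det$y_px - 20.7), 0.1)
})

test_that("detection handles empty, saturated, and two-spot frames", {
  expect_equal(nrow(detect_spots(matrix(0, 20, 20), 0.5)), 0)
  expect_error(detect_spots(matrix(2, 20, 20), 0.5), "saturated")
  two <- trajectory_set(
    tibble::tibble(particle = 1:2, frame = 1L, x_um = c(10, 25),
                   y_um = c(10, 25)), frame_rate = 20)
  vid <- render_spot_video(two, c(40, 40), 1, psf_sigma_px = 1.5, snr = Inf)
  expect_equal(nrow(detect_spots(vid[, , 1], 1)), 2)
})

test_that("noiseless fixtures are recovered below 0.1 px RMS", {
  gt <- rheo_ground_truth(10e-3, n_particles = 9, n_frames = 30,
                          localization_noise_sd_m = 0, seed = 21)
  traj <- simulate_brownian_trajectories(gt,
                                         start_positions_um = grid_starts(9))
  vid <- render_spot_video(traj, c(90, 90), pixel_size_um = 0.5, snr = Inf)
  truth <- attr(vid, "truth")
  err <- unlist(lapply(seq_len(dim(vid)[3]), function(f) {
    det <- detect_spots(vid[, , f], 1)
    tt <- truth[truth$frame == f, ]
    vapply(seq_len(nrow(tt)), function(i) {
      min(sqrt((det$x_px - tt$x_px[i])^2 + (det$y_px - tt$y_px[i])^2))
    }, numeric(1))
  }))
  expect_lt(sqrt(mean(err^2)), 0.1)
})

test_that("a single detection per frame links into one full-length trajectory", {
  det <- tibble::tibble(frame = 1:20, x_um = cumsum(rep(0.1, 20)), y_um = 0)
  tr <- link_trajectories(det, max_displacement_um = 1, frame_rate = 20,
                          min_length = 2)
  expect_equal(length(unique(tr$particle)), 1)
  expect_equal(tr$frame, 1:20)
})

test_that("linking matches the generator's particles when steps are much smaller than separations", {
  gt <- rheo_ground_truth(10e-3, n_particles = 10, n_frames = 40,
                          localization_noise_sd_m = 0, seed = 5)
  traj <- simulate_brownian_trajectories(
    gt, start_positions_um = grid_starts(10, spacing_um = 15))
  det <- dplyr::select(tibble::as_tibble(traj), "frame", "x_um", "y_um",
                       true_particle = "particle")
  tr <- link_trajectories(det, max_displacement_um = 3, frame_rate = 20)
  # a correct linking reproduces 10 tracks covering every frame
  expect_equal(length(unique(tr$particle)), 10)
  # and every recovered track follows a single true particle
  joined <- dplyr::inner_join(tibble::as_tibble(tr), det,
                              by = c("frame", "x_um", "y_um"))
  purity <- vapply(split(joined$true_particle, joined$particle),
                   function(tp) mean(tp == tp[1]), numeric(1))
  expect_gte(mean(purity), 0.95)
})

test_that("linking is invariant to a rigid translation of the field", {
  det <- tibble::tibble(frame = rep(1:10, each = 2),
                        x_um = rep(c(5, 15), 10) + rep(1:10, each = 2) * 0.1,
                        y_um = rep(c(5, 15), 10))
  tr1 <- link_trajectories(det, 2, frame_rate = 20, min_length = 2)
  det2 <- dplyr::mutate(det, x_um = x_um + 50, y_um = y_um + 30)
  tr2 <- link_trajectories(det2, 2, frame_rate = 20, min_length = 2)
  expect_equal(tr1$particle, tr2$particle)
  expect_equal(tr1$x_um + 50, tr2$x_um)
})

test_that("ties are broken deterministically and misses terminate tracks", {
  # one new detection equidistant from two previous ones: the earlier track
  # (lower index) wins
  det <- tibble::tibble(frame = c(1L, 1L, 2L),
                        x_um = c(0, 10, 5), y_um = 0)
  tr <- link_trajectories(det, max_displacement_um = 6, frame_rate = 20,
                          min_length = 1)
  ext <- dplyr::filter(tibble::as_tibble(tr), frame == 2)
  first_track <- tr$particle[tr$frame == 1 & tr$x_um == 0]
  expect_equal(ext$particle, first_track)
  # a skipped frame starts a fresh track (no gap closing)
  det2 <- tibble::tibble(frame = c(1L, 2L, 4L, 5L), x_um = 0, y_um = 0)
  tr2 <- link_trajectories(det2, 1, frame_rate = 20, min_length = 1)
  expect_equal(length(unique(tr2$particle)), 2)
  expect_error(link_trajectories(det2, -1, 20), "positive")
})

test_that("track counts never exceed detections plus restarts", {
  gt <- rheo_ground_truth(5e-3, n_particles = 6, n_frames = 25,
                          localization_noise_sd_m = 0, seed = 31)
  traj <- simulate_brownian_trajectories(gt,
                                         start_positions_um = grid_starts(6))
  vid <- render_spot_video(traj, c(80, 80), 0.5, snr = 10, seed = 1)
  tr <- track_video(vid, intensity_threshold = 20, max_displacement_um = 3,
                    min_length = 2)
  n_det <- sum(vapply(seq_len(dim(vid)[3]), function(f) {
    nrow(detect_spots(vid[, , f], 20))
  }, numeric(1)))
  expect_lte(nrow(tr), n_det)
})
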