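# Shared fixtures built in code. Expensive field solutions are cached per
# session so several tests can interrogate the same solve.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

default_chip_solution <- function() {
  cached("chip_default", {
    sol <- solve_flow(chip_geometry(), transport_params(), resolution = 16)
    solve_oxygen(sol)
  })
}

straight_channel_solution <- function() {
  cached("channel_fine", {
    solve_flow(chip_geometry(include_pool = FALSE), transport_params(),
               resolution = 24)
  })
}

# starting positions on a grid, guaranteeing separated rendered spots
grid_starts <- function(n, spacing_um = 12, margin_um = 10) {
  k <- ceiling(sqrt(n))
  g <- expand.grid(x = margin_um + (seq_len(k) - 1) * spacing_um,
                   y = margin_um + (seq_len(k) - 1) * spacing_um)
  as.matrix(g[seq_len(n), ])
}

# filled-disc label image, for shape-metric fixtures
disc_label <- function(side, centre, radius, value = 1L) {
  xs <- matrix(rep(seq_len(side), each = side), side, side)
  ys <- t(xs)
  lab <- matrix(0L, side, side)
  lab[(xs - centre[1])^2 + (ys - centre[2])^2 <= radius^2] <- value
  lab
}

# independent brute-force MSD oracle: plain double loop over all ordered
# frame pairs, per particle, then unweighted mean across particles
brute_force_msd <- function(traj, max_lag_fraction = 0.25) {
  df <- as.data.frame(traj)
  fr <- attr(traj, "frame_rate")
  parts <- split(df, df$particle)
  kmax <- min(vapply(parts, function(d) {
    as.integer(max(1L, floor(max_lag_fraction * nrow(d))))
  }, integer(1)))
  sapply(seq_len(kmax), function(k) {
    mean(vapply(parts, function(d) {
      tot <- 0; cnt <- 0
      for (i in seq_len(nrow(d) - k)) {
        tot <- tot + (d$x_um[i + k] - d$x_um[i])^2 +
          (d$y_um[i + k] - d$y_um[i])^2
        cnt <- cnt + 1
      }
      tot / cnt
    }, numeric(1)))
  })
}
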