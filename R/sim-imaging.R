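#' Render trajectories into a synthetic fluorescence video
#'
#' Each particle becomes a Gaussian intensity spot (an idealized point-spread
#' function) at its sub-pixel position; optional Gaussian shot-like noise is
#' added per pixel. The ground-truth pixel positions are attached as the
#' `truth` attribute so detection and linking can be scored exactly.
#'
#' Pixel centers sit at integer coordinates, origin top-left, x rightward
#' (columns), y downward (rows).
#'
#' @param traj A [trajectory_set()] with positions in µm.
#' @param image_shape `c(n_rows, n_cols)` of the rendered frames.
#' @param pixel_size_um Pixel size in µm.
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param snr Peak amplitude over noise standard deviation; `Inf` disables
#'   noise.
#' @param amplitude Peak spot intensity (arbitrary units).
#' @param background Constant background level.
#' @param n_frames Number of frames to render; defaults to the last frame
#'   present in `traj` (required when `traj` is empty, which yields a
#'   pure-noise video).
#' @param seed Seed for the noise, or `NULL`.
#' @param offscreen `"error"` (default) rejects positions outside the field
#'   of view, listing the offending frames; `"skip"` silently omits them
#'   (they go undetected, as off-field beads would).
#' @return A [video_stack()] with attribute `truth`: a tibble of
#'   (particle, frame, x_px, y_px) for the rendered positions.
#' @export
render_spot_video <- function(traj, image_shape, pixel_size_um,
                              psf_sigma_px = 1.5, snr = Inf,
                              amplitude = 100, background = 0,
                              n_frames = NULL, seed = NULL,
                              offscreen = c("error", "skip")) {
  stopifnot(inherits(traj, "trajectory_set"))
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_number(psf_sigma_px, "psf_sigma_px", positive = TRUE)
  nr <- image_shape[1]; nc <- image_shape[2]
  df <- as_tibble(traj) |>
    mutate(x_px = .data$x_um / pixel_size_um, y_px = .data$y_um / pixel_size_um)
  margin <- 0.5
  off <- df$x_px < margin | df$x_px > nc + margin |
    df$y_px < margin | df$y_px > nr + margin
  offscreen <- match.arg(offscreen)
  if (any(off)) {
    if (offscreen == "error") {
      abort(paste0("positions fall outside the field of view in frame(s): ",
                   paste(sort(unique(df$frame[off])), collapse = ", ")))
    }
    df <- df[!off, , drop = FALSE]
  }
  nframes <- n_frames %||% if (nrow(df)) max(df$frame) else
    abort("an empty trajectory set needs an explicit `n_frames`.")
  arr <- array(background, dim = c(nr, nc, nframes))
  win <- ceiling(4 * psf_sigma_px)
  for (k in seq_len(nrow(df))) {
    x <- df$x_px[k]; y <- df$y_px[k]; f <- df$frame[k]
    cs <- max(1L, floor(x - win)):min(nc, ceiling(x + win))
    rs <- max(1L, floor(y - win)):min(nr, ceiling(y + win))
    spot <- amplitude *
      exp(-(outer((rs - y)^2, (cs - x)^2, "+")) / (2 * psf_sigma_px^2))
    arr[rs, cs, f] <- arr[rs, cs, f] + spot
  }
  if (is.finite(snr)) {
    check_number(snr, "snr", positive = TRUE)
    arr <- with_seed(seed, {
      arr + array(rnorm(length(arr), sd = amplitude / snr), dim = dim(arr))
    })
    arr[arr < 0] <- 0
  }
  out <- video_stack(arr, frame_rate = frame_rate_of(traj),
                     pixel_size_um = pixel_size_um)
  attr(out, "truth") <- select(df, "particle", "frame", "x_px", "y_px")
  out
}

#' Simulate a two-channel confocal z-stack of beads above a cell layer
#'
#' Emulates the aerosolized-bead assay used to measure mucus thickness: the
#' blue channel is bright in a bottom slab (nuclei of the epithelium) and the
#' red channel carries bright bead spots in a top slab whose lower edge sits
#' `gap_um` above the top of the blue slab. The realized (grid-rounded) gap is
#' recorded in the `truth` attribute; if `gap_um` is not an exact multiple of
#' `z_spacing_um` the value is rounded with a warning.
#'
#' @param gap_um Empty space between the two layers, µm (>= 0).
#' @param z_spacing_um Axial step, µm.
#' @param xy_shape `c(n_rows, n_cols)` of each slice.
#' @param cell_slab_um Thickness of the blue (cell) slab, µm.
#' @param bead_slab_um Thickness of the red (bead) slab, µm.
#' @param n_beads_per_slice Bright red spots rendered per bead slice.
#' @param noise_sd Gaussian noise standard deviation added to both channels.
#' @param seed Seed, or `NULL`.
#' @return A [z_stack()] with channels `c("red", "blue")` and a `truth`
#'   attribute holding the realized gap and layer edges (µm).
#' @export
simulate_two_layer_zstack <- function(gap_um, z_spacing_um = 1,
                                      xy_shape = c(64, 64),
                                      cell_slab_um = 10, bead_slab_um = 3,
                                      n_beads_per_slice = 30,
                                      noise_sd = 0.02, seed = NULL) {
  check_number(gap_um, "gap_um", nonneg = TRUE)
  check_number(z_spacing_um, "z_spacing_um", positive = TRUE)
  n_gap <- gap_um / z_spacing_um
  if (abs(n_gap - round(n_gap)) > 1e-9) {
    warn(sprintf("gap %.4g um is not a multiple of the z step %.4g um; rounded to %.4g um",
                 gap_um, z_spacing_um, round(n_gap) * z_spacing_um))
  }
  n_gap <- as.integer(round(n_gap))
  n_cell <- max(1L, as.integer(round(cell_slab_um / z_spacing_um)))
  n_bead <- max(1L, as.integer(round(bead_slab_um / z_spacing_um)))
  n_z <- n_cell + n_gap + n_bead + 2L  # one dark slice at each end
  nr <- xy_shape[1]; nc <- xy_shape[2]
  arr <- array(0, dim = c(nr, nc, n_z, 2L))
  cell_slices <- 1L + seq_len(n_cell)
  bead_slices <- 1L + n_cell + n_gap + seq_len(n_bead)

  with_seed(seed, {
    # blue: dense nuclei texture filling the bottom slab
    for (z in cell_slices) {
      arr[, , z, 2L] <- 0.6 + matrix(stats::runif(nr * nc, 0, 0.4), nr, nc)
    }
    # red: discrete bead spots in the top slab
    for (z in bead_slices) {
      rows <- sample.int(nr, n_beads_per_slice, replace = TRUE)
      cols <- sample.int(nc, n_beads_per_slice, replace = TRUE)
      sl <- matrix(0, nr, nc)
      sl[cbind(rows, cols)] <- 1
      # small dilation so beads cover a few pixels
      sl <- sl + rbind(sl[-1, ], 0) + rbind(0, sl[-nr, ]) +
        cbind(sl[, -1], 0) + cbind(0, sl[, -nc])
      arr[, , z, 1L] <- pmin(sl, 1)
    }
    if (noise_sd > 0) {
      arr <- arr + array(abs(rnorm(length(arr), sd = noise_sd)), dim = dim(arr))
    }
  })
  out <- z_stack(arr, z_spacing_um = z_spacing_um,
                 channels = c("red", "blue"))
  # slice k spans z in [(k-1) dz, k dz]; edges of the slabs in µm:
  attr(out, "truth") <- list(
    gap_um = n_gap * z_spacing_um,
    cell_top_edge_um = max(cell_slices) * z_spacing_um,
    bead_bottom_edge_um = (min(bead_slices) - 1L) * z_spacing_um
  )
  out
}
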