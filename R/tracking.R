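#' Detect bright spots in a single frame
#'
#' Thresholds the image, labels connected regions (8-connectivity),
#' size-filters them, and returns the intensity-weighted centroid of every
#' surviving region at sub-pixel precision. Pixel centers sit at integer
#' coordinates, origin top-left, x rightward (columns), y downward (rows).
#'
#' @param frame_image Numeric matrix, non-negative, single channel.
#' @param intensity_threshold Pixels strictly above this value are
#'   foreground.
#' @param min_size,max_size Region size bounds in pixels.
#' @param pixel_size_um Pixel size in µm (positions are reported in both px
#'   and µm).
#' @return A tibble of detections: `x_px`, `y_px`, `x_um`, `y_um`,
#'   `intensity` (summed), `area_px`. Zero rows when nothing is found.
#' @export
detect_spots <- function(frame_image, intensity_threshold,
                         min_size = 3, max_size = Inf, pixel_size_um = 1) {
  if (!is.matrix(frame_image) || !is.numeric(frame_image)) {
    abort("`frame_image` must be a numeric matrix.")
  }
  if (any(frame_image < 0)) abort("`frame_image` must be non-negative.")
  mask <- frame_image > intensity_threshold
  if (all(mask)) {
    abort("every pixel is above threshold (saturated image?).")
  }
  empty <- tibble(x_px = numeric(0), y_px = numeric(0),
                  x_um = numeric(0), y_um = numeric(0),
                  intensity = numeric(0), area_px = integer(0))
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  lab <- as.matrix(lab)
  idx <- which(lab > 0)
  if (!length(idx)) return(empty)
  labs <- lab[idx]
  wts <- frame_image[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L  # y
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L # x
  tot <- tapply(wts, labs, sum)
  area <- tapply(labs, labs, length)
  cx <- tapply(wts * cols, labs, sum) / tot
  cy <- tapply(wts * rows, labs, sum) / tot
  out <- tibble(x_px = as.numeric(cx), y_px = as.numeric(cy),
                x_um = as.numeric(cx) * pixel_size_um,
                y_um = as.numeric(cy) * pixel_size_um,
                intensity = as.numeric(tot), area_px = as.integer(area))
  filter(out, .data$area_px >= min_size, .data$area_px <= max_size)
}

#' Link per-frame detections into trajectories by the proximity principle
#'
#' Detections in successive frames are paired greedily by ascending distance
#' (the nearest candidates are matched first), subject to a maximum
#' displacement gate. Unmatched detections start new tracks; a track with no
#' match in the next frame terminates (no gap closing). Equal distances are
#' broken deterministically by (track index, detection index).
#'
#' @param detections A data frame with columns `frame`, `x_um`, `y_um`
#'   (typically detections from [detect_spots()] stacked over frames).
#' @param max_displacement_um Gate on the frame-to-frame displacement, µm.
#' @param frame_rate Frames per second, attached to the output.
#' @param min_length Minimum trajectory length (frames) to keep; shorter
#'   tracks are dropped. Default 10, the usual floor for time-averaged MSD
#'   estimation.
#' @param pixel_size_m Pixel size in metres, attached to the output.
#' @return A [trajectory_set()].
#' @export
link_trajectories <- function(detections, max_displacement_um,
                              frame_rate, min_length = 10L,
                              pixel_size_m = NA_real_) {
  check_number(max_displacement_um, "max_displacement_um", positive = TRUE)
  det <- as_tibble(detections) |> arrange(.data$frame)
  if (!nrow(det)) {
    return(trajectory_set(tibble(particle = integer(0), frame = integer(0),
                                 x_um = numeric(0), y_um = numeric(0)),
                          frame_rate = frame_rate,
                          pixel_size_m = pixel_size_m))
  }
  frames <- sort(unique(det$frame))
  by_frame <- split(det, det$frame)

  next_id <- 0L
  new_track <- function(row, f) {
    next_id <<- next_id + 1L
    list(id = next_id, rows = list(c(row$x_um, row$y_um)), start = f)
  }
  f1 <- by_frame[[as.character(frames[1])]]
  active <- purrr::map(seq_len(nrow(f1)), ~ new_track(f1[.x, ], frames[1]))
  done <- list()

  for (k in seq_along(frames)[-1]) {
    f_prev <- frames[k - 1]; f_cur <- frames[k]
    cur <- by_frame[[as.character(f_cur)]]
    if (f_cur != f_prev + 1L || length(active) == 0L) {
      # a skipped frame terminates every active track
      done <- c(done, active)
      active <- purrr::map(seq_len(nrow(cur)), ~ new_track(cur[.x, ], f_cur))
      next
    }
    heads <- do.call(rbind, purrr::map(active, ~ .x$rows[[length(.x$rows)]]))
    dmat <- sqrt(outer(heads[, 1], cur$x_um, "-")^2 +
                   outer(heads[, 2], cur$y_um, "-")^2)
    cand <- which(dmat <= max_displacement_um, arr.ind = TRUE)
    assigned_t <- logical(length(active))
    assigned_d <- logical(nrow(cur))
    if (nrow(cand)) {
      ord <- order(dmat[cand], cand[, 1], cand[, 2])
      for (ci in ord) {
        ti <- cand[ci, 1]; di <- cand[ci, 2]
        if (!assigned_t[ti] && !assigned_d[di]) {
          assigned_t[ti] <- TRUE
          assigned_d[di] <- TRUE
          active[[ti]]$rows <- c(active[[ti]]$rows,
                                 list(c(cur$x_um[di], cur$y_um[di])))
        }
      }
    }
    done <- c(done, active[!assigned_t])
    active <- active[assigned_t]
    if (any(!assigned_d)) {
      starts <- purrr::map(which(!assigned_d), ~ new_track(cur[.x, ], f_cur))
      active <- c(active, starts)
    }
  }
  done <- c(done, active)

  traj <- purrr::map_dfr(done, function(tr) {
    pos <- do.call(rbind, tr$rows)
    tibble(particle = tr$id,
           frame = tr$start + seq_len(nrow(pos)) - 1L,
           x_um = pos[, 1], y_um = pos[, 2])
  })
  traj <- traj |>
    group_by(.data$particle) |>
    filter(n() >= min_length) |>
    ungroup()
  # renumber surviving tracks consecutively for tidiness
  traj$particle <- match(traj$particle, sort(unique(traj$particle)))
  trajectory_set(traj, frame_rate = frame_rate, pixel_size_m = pixel_size_m)
}

#' Track beads through a video: detect in every frame, then link
#'
#' Convenience wrapper running [detect_spots()] on each frame of a video and
#' [link_trajectories()] on the stacked detections.
#'
#' @param video A [video_stack()].
#' @param intensity_threshold Detection threshold (see [detect_spots()]).
#' @param max_displacement_um Linking gate, µm.
#' @inheritParams detect_spots
#' @inheritParams link_trajectories
#' @return A [trajectory_set()] in µm.
#' @export
track_video <- function(video, intensity_threshold, max_displacement_um,
                        min_size = 3, max_size = Inf, min_length = 10L) {
  stopifnot(inherits(video, "video_stack"))
  px <- attr(video, "pixel_size_um")
  det <- purrr::map_dfr(seq_len(dim(video)[3]), function(f) {
    d <- detect_spots(video[, , f], intensity_threshold,
                      min_size = min_size, max_size = max_size,
                      pixel_size_um = px)
    mutate(d, frame = f)
  })
  link_trajectories(det, max_displacement_um,
                    frame_rate = attr(video, "frame_rate"),
                    min_length = min_length, pixel_size_m = px * 1e-6)
}
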