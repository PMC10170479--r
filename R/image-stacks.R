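#' Video and z-stack containers
#'
#' `video_stack()` wraps a numeric 3D array `[row, col, frame]` with a frame
#' rate and pixel size; `z_stack()` wraps a 4D array `[row, col, slice,
#' channel]` with a z spacing and pixel size. Both are plain arrays with
#' attributes, so base subsetting keeps working.
#'
#' @param data Numeric array (3D for video, 4D for z-stacks).
#' @param frame_rate Frames per second.
#' @param pixel_size_um Pixel size in µm.
#' @return A `video_stack` / `z_stack` object.
#' @export
video_stack <- function(data, frame_rate, pixel_size_um = 1) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  check_number(frame_rate, "frame_rate", positive = TRUE)
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(data, frame_rate = frame_rate, pixel_size_um = pixel_size_um,
            class = c("video_stack", "array"))
}

#' @param z_spacing_um Axial step between slices, µm.
#' @param channels Character vector of channel names (4th dimension).
#' @rdname video_stack
#' @export
z_stack <- function(data, z_spacing_um, pixel_size_um = 1,
                    channels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  check_number(z_spacing_um, "z_spacing_um", positive = TRUE)
  channels <- channels %||% paste0("ch", seq_len(dim(data)[4]))
  stopifnot(length(channels) == dim(data)[4])
  structure(data, z_spacing_um = z_spacing_um, pixel_size_um = pixel_size_um,
            channels = channels, class = c("z_stack", "array"))
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<video_stack> %d x %d px, %d frames at %g fps (%g um/px)\n",
              d[1], d[2], d[3], attr(x, "frame_rate"),
              attr(x, "pixel_size_um")))
  invisible(x)
}

#' @export
print.z_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<z_stack> %d x %d px, %d slices x %d channels, dz = %g um\n",
              d[1], d[2], d[3], d[4], attr(x, "z_spacing_um")))
  invisible(x)
}

#' Read and write image stacks as multi-page TIFF with a JSON sidecar
#'
#' Frames (or slice/channel pages, channel-fastest) are stored as 32-bit
#' float TIFF pages; calibration metadata (`frame_rate`, `pixel_size_um`,
#' `z_spacing_um`, `channels`) is stored in `<file>.json`.
#'
#' @param stack A `video_stack` or `z_stack`.
#' @param path TIFF path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   the reconstructed object.
#' @export
write_stack <- function(stack, path) {
  if (inherits(stack, "video_stack")) {
    pages <- purrr::map(seq_len(dim(stack)[3]), ~ stack[, , .x])
    meta <- list(kind = "video", frame_rate = attr(stack, "frame_rate"),
                 pixel_size_um = attr(stack, "pixel_size_um"))
  } else if (inherits(stack, "z_stack")) {
    d <- dim(stack)
    pages <- purrr::flatten(purrr::map(seq_len(d[3]), function(z) {
      purrr::map(seq_len(d[4]), ~ stack[, , z, .x])
    }))
    meta <- list(kind = "zstack", z_spacing_um = attr(stack, "z_spacing_um"),
                 pixel_size_um = attr(stack, "pixel_size_um"),
                 channels = attr(stack, "channels"),
                 n_slices = d[3])
  } else {
    abort("write_stack() expects a video_stack or z_stack.")
  }
  # scale into [0, 1] for TIFF storage; record the scale to invert on read
  mx <- max(unlist(lapply(pages, max)), 1e-12)
  meta$intensity_scale <- mx
  tiff::writeTIFF(purrr::map(pages, ~ pmin(pmax(.x / mx, 0), 1)), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- purrr::map(pages, ~ .x * meta$intensity_scale)
  if (identical(meta$kind, "video")) {
    arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    video_stack(arr, frame_rate = meta$frame_rate,
                pixel_size_um = meta$pixel_size_um)
  } else {
    n_ch <- length(meta$channels)
    n_z <- meta$n_slices
    arr <- array(0, dim = c(dim(pages[[1]]), n_z, n_ch))
    k <- 1L
    for (z in seq_len(n_z)) {
      for (ch in seq_len(n_ch)) {
        arr[, , z, ch] <- pages[[k]]
        k <- k + 1L
      }
    }
    z_stack(arr, z_spacing_um = meta$z_spacing_um,
            pixel_size_um = meta$pixel_size_um, channels = meta$channels)
  }
}
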