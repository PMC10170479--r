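#' Trajectory tables
#'
#' A `trajectory_set` is a tibble of particle positions over frames with the
#' acquisition metadata attached as attributes. Columns:
#' \describe{
#'   \item{particle}{integer particle id}
#'   \item{frame}{integer frame index (1-based, strictly increasing with no
#'     gaps within a particle)}
#'   \item{x_um, y_um}{position in micrometres}
#'   \item{region}{imaging region id}
#' }
#'
#' @param data A data frame with at least `particle`, `frame`, `x_um`, `y_um`.
#' @param frame_rate Frames per second.
#' @param pixel_size_m Pixel size in metres (NA when positions did not come
#'   from an image).
#' @return A `trajectory_set` tibble.
#' @export
trajectory_set <- function(data, frame_rate, pixel_size_m = NA_real_) {
  check_number(frame_rate, "frame_rate", positive = TRUE)
  data <- as_tibble(data)
  needed <- c("particle", "frame", "x_um", "y_um")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("trajectory data lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"region" %in% names(data)) data$region <- 1L
  data <- arrange(data, .data$region, .data$particle, .data$frame)
  bad <- data |>
    group_by(.data$region, .data$particle) |>
    summarise(ok = all(diff(.data$frame) == 1L) || n() == 1L,
              .groups = "drop")
  if (!all(bad$ok)) {
    abort("each trajectory must cover strictly consecutive frames (no gaps).")
  }
  structure(data,
            frame_rate = frame_rate,
            pixel_size_m = pixel_size_m,
            class = c("trajectory_set", class(data)))
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d particles, %d rows, %g fps\n",
              dplyr::n_distinct(paste(x$region, x$particle)), nrow(x),
              attr(x, "frame_rate")))
  NextMethod()
}

frame_rate_of <- function(traj) {
  fr <- attr(traj, "frame_rate")
  if (is.null(fr)) abort("object has no frame_rate attribute.")
  fr
}

#' Plot trajectories in the imaging plane
#'
#' @param object A [trajectory_set()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trajectory_set
#' @export
autoplot.trajectory_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x_um, .data$y_um,
                                       group = interaction(.data$region, .data$particle),
                                       colour = factor(.data$particle))) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Read and write trajectory CSV files
#'
#' The on-disk format is a plain CSV with columns `particle`, `frame`,
#' `x_um`, `y_um` (and optionally `region`); acquisition metadata travels in
#' a JSON sidecar `<file>.json` holding `frame_rate` and `pixel_size_m`.
#'
#' @param traj A [trajectory_set()].
#' @param path CSV path.
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` returns a [trajectory_set()].
#' @export
write_trajectories <- function(traj, path) {
  readr::write_csv(as_tibble(traj), path)
  meta <- list(frame_rate = frame_rate_of(traj),
               pixel_size_m = attr(traj, "pixel_size_m"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param frame_rate Override for the frame rate when no sidecar exists.
#' @rdname write_trajectories
#' @export
read_trajectories <- function(path, frame_rate = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  pixel_size_m <- NA_real_
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    frame_rate <- frame_rate %||% meta$frame_rate
    pixel_size_m <- suppressWarnings(as.numeric(meta$pixel_size_m %||% NA_real_))
  }
  if (is.null(frame_rate)) {
    abort("no frame_rate given and no sidecar JSON found.")
  }
  trajectory_set(data, frame_rate = frame_rate, pixel_size_m = pixel_size_m)
}
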