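#' Simulate a ciliary-beat intensity trace
#'
#' A sinusoid with `cbf_hz` cycles per second sampled at `frame_rate`, plus
#' additive Gaussian noise. The sampling must satisfy Nyquist
#' (`frame_rate > 2 * cbf_hz`); high-frame-rate cilia video is typically
#' acquired at 100 frames/s.
#'
#' @param cbf_hz Beat frequency, Hz (0 gives a constant trace).
#' @param frame_rate Sampling rate, frames per second.
#' @param duration_s Trace duration, seconds.
#' @param amplitude Oscillation amplitude (arbitrary units).
#' @param baseline Constant offset.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Seed, or `NULL`.
#' @return A tibble with columns `time_s`, `intensity` and attribute
#'   `frame_rate`.
#' @examples
#' tr <- simulate_cilia_trace(8, frame_rate = 100, duration_s = 2)
#' @export
simulate_cilia_trace <- function(cbf_hz, frame_rate = 100, duration_s = 2,
                                 amplitude = 1, baseline = 10,
                                 noise_sd = 0, seed = NULL) {
  check_number(cbf_hz, "cbf_hz", nonneg = TRUE)
  check_number(frame_rate, "frame_rate", positive = TRUE)
  check_number(duration_s, "duration_s", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (cbf_hz > 0 && frame_rate <= 2 * cbf_hz) {
    abort(sprintf(
      "frame_rate (%g fps) violates the Nyquist criterion for a %g Hz beat; need > %g fps.",
      frame_rate, cbf_hz, 2 * cbf_hz))
  }
  n <- as.integer(round(duration_s * frame_rate))
  t_s <- (seq_len(n) - 1L) / frame_rate
  y <- baseline + amplitude * sin(2 * pi * cbf_hz * t_s)
  if (noise_sd > 0) {
    y <- with_seed(seed, y + rnorm(n, sd = noise_sd))
  }
  out <- tibble(time_s = t_s, intensity = y)
  attr(out, "frame_rate") <- frame_rate
  out
}

#' Mean-intensity trace of a rectangular ROI over a video
#'
#' Reproduces the manual kymograph workflow: a region of interest on the
#' cilia is cropped and its mean intensity recorded per frame. With
#' `mode = "line"` a one-pixel-wide line kymograph row is returned per frame
#' instead of a scalar mean.
#'
#' @param video A [video_stack()] (single channel; colour videos should be
#'   converted to grayscale before this step).
#' @param roi `c(x, y, w, h)` in pixels (top-left corner, 1-based).
#' @param mode `"mean"` (default) or `"line"` (kymograph of row `y`).
#' @return For `"mean"`, a tibble `time_s`, `intensity` with attribute
#'   `frame_rate`; for `"line"`, a matrix `[frame, x]`.
#' @export
roi_trace <- function(video, roi, mode = c("mean", "line")) {
  stopifnot(inherits(video, "video_stack"))
  mode <- match.arg(mode)
  d <- dim(video)
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  if (x < 1 || y < 1 || x + w - 1 > d[2] || y + h - 1 > d[1]) {
    abort(sprintf("ROI [%d, %d, %d, %d] falls outside the %d x %d frame.",
                  x, y, w, h, d[2], d[1]))
  }
  fr <- attr(video, "frame_rate")
  if (mode == "line") {
    return(t(vapply(seq_len(d[3]),
                    function(f) video[y, x:(x + w - 1), f],
                    numeric(w))))
  }
  vals <- vapply(seq_len(d[3]),
                 function(f) mean(video[y:(y + h - 1), x:(x + w - 1), f]),
                 numeric(1))
  out <- tibble(time_s = (seq_len(d[3]) - 1L) / fr, intensity = vals)
  attr(out, "frame_rate") <- fr
  out
}

# Local maxima of a 1D signal with topographic prominence. Returns indices
# of peaks whose prominence exceeds `min_prominence`. Plateau maxima count
# once (left edge). Endpoints are not peaks.
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  dx <- diff(x)
  # candidate: last rise before a fall (handles flat tops)
  sign_dx <- sign(dx)
  # propagate the sign of the previous non-zero difference through plateaus
  for (i in seq_along(sign_dx)) {
    if (sign_dx[i] == 0 && i > 1) sign_dx[i] <- sign_dx[i - 1]
  }
  cand <- which(head(sign_dx, -1) > 0 & tail(sign_dx, -1) < 0) + 1L
  if (!length(cand)) return(integer(0))
  keep <- vapply(cand, function(i) {
    left_min <- min(x[1:i])
    right_min <- min(x[i:n])
    # prominence: height above the higher of the two key saddles, using the
    # lowest point between this peak and the nearest higher terrain
    higher_left <- which(x[1:(i - 1)] > x[i])
    lo_l <- if (length(higher_left)) min(x[(max(higher_left) + 1):i]) else left_min
    higher_right <- which(x[(i + 1):n] > x[i]) + i
    lo_r <- if (length(higher_right)) min(x[i:(min(higher_right) - 1)]) else right_min
    (x[i] - max(lo_l, lo_r)) >= min_prominence
  }, logical(1))
  cand[keep]
}

#' Ciliary beat frequency by peak counting
#'
#' Counts local intensity maxima whose prominence exceeds a threshold and
#' normalizes by the trace duration: `cbf = n_peaks / duration`. The estimate
#' is cross-checked against the dominant discrete-Fourier frequency of the
#' detrended trace; a discrepancy above 20% raises the `flag` field.
#'
#' @param trace A tibble from [simulate_cilia_trace()] / [roi_trace()], or a
#'   numeric vector of intensities.
#' @param frame_rate Sampling rate, frames per second (taken from the trace
#'   attribute when available).
#' @param min_prominence Peak prominence threshold; default half the trace
#'   standard deviation.
#' @return A `cbf_result` list: `cbf_hz`, `n_peaks`, `duration_s`,
#'   `spectral_cbf_hz`, `flag`.
#' @examples
#' tr <- simulate_cilia_trace(8, 100, 2)
#' count_peaks_cbf(tr)$cbf_hz
#' @export
count_peaks_cbf <- function(trace, frame_rate = NULL, min_prominence = NULL) {
  if (is.data.frame(trace)) {
    frame_rate <- frame_rate %||% attr(trace, "frame_rate")
    x <- trace$intensity
  } else {
    x <- as.numeric(trace)
  }
  if (is.null(frame_rate)) abort("frame_rate is required.")
  check_number(frame_rate, "frame_rate", positive = TRUE)
  n <- length(x)
  duration <- n / frame_rate
  min_prominence <- min_prominence %||% (0.5 * sd(x))
  if (!is.finite(min_prominence)) min_prominence <- 0
  peaks <- find_peaks(x, min_prominence)
  cbf <- length(peaks) / duration

  # spectral cross-check on the mean-removed trace
  spec_cbf <- NA_real_
  if (n >= 8) {
    amp <- Mod(fft(x - mean(x)))[2:floor(n / 2)]
    if (length(amp) && max(amp) > 0) {
      spec_cbf <- (which.max(amp)) * frame_rate / n
    }
  }
  flag <- if (length(peaks) == 0) {
    "no_peaks"
  } else if (is.finite(spec_cbf) && spec_cbf > 0 &&
             abs(cbf - spec_cbf) / spec_cbf > 0.2) {
    "spectral_mismatch"
  } else {
    NA_character_
  }
  structure(
    list(cbf_hz = cbf, n_peaks = length(peaks), duration_s = duration,
         peak_index = peaks, spectral_cbf_hz = spec_cbf, flag = flag,
         frame_rate = frame_rate),
    class = "cbf_result"
  )
}

#' @export
print.cbf_result <- function(x, ...) {
  cat(sprintf("<cbf_result> %.3g Hz (%d peaks / %.3g s)", x$cbf_hz,
              x$n_peaks, x$duration_s))
  if (!is.na(x$flag)) cat(sprintf("  [flag: %s]", x$flag))
  cat("\n")
  invisible(x)
}

#' @rdname count_peaks_cbf
#' @param x A `cbf_result`.
#' @param ... Unused.
#' @method tidy cbf_result
#' @export
tidy.cbf_result <- function(x, ...) {
  tibble(cbf_hz = x$cbf_hz, n_peaks = x$n_peaks, duration_s = x$duration_s,
         spectral_cbf_hz = x$spectral_cbf_hz, flag = x$flag)
}
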