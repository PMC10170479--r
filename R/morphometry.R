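#' Count nuclei in a single-channel image
#'
#' Thresholds the nuclei channel, labels connected components
#' (8-connectivity), discards regions below `min_area`, and optionally
#' splits touching nuclei by a distance-transform watershed.
#'
#' @param nuclei_img Numeric matrix.
#' @param threshold Foreground threshold; `NULL` uses Otsu's method.
#' @param min_area Minimum region area in pixels.
#' @param split_touching Apply watershed splitting (off by default, as for
#'   well-separated stained nuclei).
#' @return Integer nucleus count, with the label matrix as attribute
#'   `labels`.
#' @export
count_nuclei <- function(nuclei_img, threshold = NULL, min_area = 5,
                         split_touching = FALSE) {
  stopifnot(is.matrix(nuclei_img), is.numeric(nuclei_img))
  threshold <- threshold %||% otsu_threshold(nuclei_img)
  mask <- nuclei_img > threshold
  if (!any(mask)) {
    return(structure(0L, labels = matrix(0L, nrow(nuclei_img),
                                         ncol(nuclei_img))))
  }
  if (split_touching) {
    dmap <- EBImage::distmap(EBImage::Image(mask * 1))
    lab <- as.matrix(EBImage::watershed(dmap))
  } else {
    lab <- as.matrix(EBImage::bwlabel(mask))
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  lab[!(lab %in% keep)] <- 0L
  lab <- matrix(match(lab, c(0L, keep)) - 1L, nrow(lab), ncol(lab))
  structure(length(keep), labels = lab)
}

# Otsu's threshold on a numeric matrix (256-bin histogram).
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (img - rng[1]) / diff(rng)
  as.numeric(EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))) *
    diff(rng) + rng[1]
}

#' Marker area per nucleus
#'
#' Thresholds the marker channel, measures its total area in µm², and
#' divides by the nucleus count obtained from the co-registered nuclei
#' channel — the standard "stained area per cell" quantification.
#'
#' @param marker_img,nuclei_img Numeric matrices of the same field.
#' @param marker_threshold Threshold for the marker channel; `NULL` uses
#'   Otsu's method.
#' @param pixel_size_um Pixel size, µm.
#' @param ... Passed to [count_nuclei()].
#' @return A tibble: `marker_area_um2`, `n_nuclei`,
#'   `marker_area_per_nucleus_um2`.
#' @export
marker_area_per_cell <- function(marker_img, nuclei_img,
                                 marker_threshold = NULL, pixel_size_um = 1,
                                 ...) {
  if (!all(dim(marker_img) == dim(nuclei_img))) {
    abort("marker and nuclei images must share dimensions (same field).")
  }
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  marker_threshold <- marker_threshold %||% otsu_threshold(marker_img)
  area_um2 <- sum(marker_img > marker_threshold) * pixel_size_um^2
  n <- as.integer(count_nuclei(nuclei_img, ...))
  if (n < 1) abort("no nuclei found; cannot normalize the marker area.")
  tibble(marker_area_um2 = area_um2, n_nuclei = n,
         marker_area_per_nucleus_um2 = area_um2 / n)
}

#' Per-cell shape metrics from a label image
#'
#' Computes area, aspect ratio, and circularity for every labelled region.
#' Labels normally come from a manual or external segmentation (the
#' surrogate for wand-tool cell selection). Aspect ratio is the major/minor
#' axis ratio of the intensity-moment ellipse; circularity is
#' `4 pi area / perimeter^2` with the perimeter measured on the traced
#' polygon contour and capped at 1 (discrete contours of small discs can
#' slightly overshoot).
#'
#' @param label_img Integer matrix; 0 is background, equal positive values
#'   form one cell.
#' @param pixel_size_um Pixel size, µm.
#' @return A tibble with one row per cell: `cell`, `area_um2`,
#'   `aspect_ratio`, `circularity`. Degenerate (< 4 px) regions are skipped
#'   with a warning.
#' @export
cell_shape_metrics <- function(label_img, pixel_size_um = 1) {
  stopifnot(is.matrix(label_img))
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  labs <- sort(unique(as.integer(label_img[label_img > 0])))
  if (!length(labs)) {
    return(tibble(cell = integer(0), area_um2 = numeric(0),
                  aspect_ratio = numeric(0), circularity = numeric(0)))
  }
  res <- purrr::map_dfr(labs, function(l) {
    idx <- which(label_img == l)
    if (length(idx) < 4) {
      warn(sprintf("region %d has fewer than 4 pixels; skipped.", l))
      return(NULL)
    }
    rows <- ((idx - 1L) %% nrow(label_img)) + 1L
    cols <- ((idx - 1L) %/% nrow(label_img)) + 1L
    # second central moments -> equivalent-ellipse axes
    mu_rr <- var(rows) * (length(idx) - 1) / length(idx) + 1 / 12
    mu_cc <- var(cols) * (length(idx) - 1) / length(idx) + 1 / 12
    mu_rc <- stats::cov(rows, cols) * (length(idx) - 1) / length(idx)
    tr2 <- (mu_rr + mu_cc) / 2
    det_d <- sqrt(((mu_rr - mu_cc) / 2)^2 + mu_rc^2)
    lam <- c(tr2 + det_d, tr2 - det_d)
    aspect <- sqrt(lam[1] / max(lam[2], .Machine$double.eps))
    perim_px <- region_perimeter(label_img == l)
    area_px <- length(idx)
    circ <- min(1, 4 * pi * area_px / perim_px^2)
    tibble(cell = l, area_um2 = area_px * pixel_size_um^2,
           aspect_ratio = aspect, circularity = circ)
  })
  res
}

# Contour perimeter (px) of a logical mask via EBImage::ocontour, using the
# Freeman chain-code estimator (0.948 per axial step, 1.340 per diagonal
# step) which corrects the staircase bias of raw 8-connected chains on
# smooth outlines.
region_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  sum(vapply(oc, function(pts) {
    if (nrow(pts) < 2) return(4)  # single pixel: unit square
    d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
    sum(ifelse(abs(d - sqrt(2)) < 1e-9, 1.340,
               ifelse(abs(d - 1) < 1e-9, 0.948, d)))
  }, numeric(1)))
}

#' Mucus-layer thickness from a two-channel z-stack
#'
#' Locates the top of the cell (blue) layer as the highest slice whose
#' in-plane coverage exceeds `coverage_fraction`, and the bottom of the
#' aerosolized-bead (red) layer as the lowest such slice above it; the
#' thickness is the empty axial space between the two layer edges (floored
#' at 0). Coverage is computed on thresholded slices, which makes the
#' measurement invariant to global intensity scaling.
#'
#' @param zstack A [z_stack()] with channels `"red"` and `"blue"`.
#' @param red_threshold,blue_threshold Intensity thresholds; `NULL` uses
#'   half the channel maximum.
#' @param coverage_fraction Minimum fraction of in-plane pixels above
#'   threshold for a slice to count as part of a layer.
#' @return A `thickness_result`: `thickness_um`, `particle_layer_z_um`
#'   (lower edge of the bead layer), `cell_layer_top_z_um` (upper edge of
#'   the cell layer).
#' @examples
#' zs <- simulate_two_layer_zstack(gap_um = 10, seed = 1)
#' mucus_thickness(zs)$thickness_um
#' @export
mucus_thickness <- function(zstack, red_threshold = NULL,
                            blue_threshold = NULL,
                            coverage_fraction = 0.01) {
  stopifnot(inherits(zstack, "z_stack"))
  chans <- attr(zstack, "channels")
  i_red <- match("red", chans)
  i_blue <- match("blue", chans)
  if (is.na(i_red) || is.na(i_blue)) {
    abort("z-stack must carry 'red' and 'blue' channels.")
  }
  dz <- attr(zstack, "z_spacing_um")
  n_z <- dim(zstack)[3]
  coverage <- function(ch, thr) {
    thr <- thr %||% (0.5 * max(zstack[, , , ch]))
    vapply(seq_len(n_z),
           function(z) mean(zstack[, , z, ch] > thr), numeric(1))
  }
  cov_red <- coverage(i_red, red_threshold)
  cov_blue <- coverage(i_blue, blue_threshold)
  blue_slices <- which(cov_blue > coverage_fraction)
  if (!length(blue_slices)) {
    abort("blue (cell) channel never exceeds the coverage threshold.")
  }
  i_cell_top <- max(blue_slices)
  red_slices <- which(cov_red > coverage_fraction)
  red_slices <- red_slices[red_slices > i_cell_top]
  if (!length(red_slices)) {
    abort("red (bead) channel never exceeds the coverage threshold above the cell layer.")
  }
  i_bead_bottom <- min(red_slices)
  # slice k spans [(k-1) dz, k dz]: layer edges sit on slice boundaries
  cell_top_um <- i_cell_top * dz
  bead_bottom_um <- (i_bead_bottom - 1) * dz
  structure(
    list(thickness_um = max(bead_bottom_um - cell_top_um, 0),
         particle_layer_z_um = bead_bottom_um,
         cell_layer_top_z_um = cell_top_um),
    class = "thickness_result"
  )
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("<thickness_result> %.3g um (cell top %.3g um, bead layer %.3g um)\n",
              x$thickness_um, x$cell_layer_top_z_um, x$particle_layer_z_um))
  invisible(x)
}

#' @rdname mucus_thickness
#' @param x A `thickness_result`.
#' @param ... Unused.
#' @method tidy thickness_result
#' @export
tidy.thickness_result <- function(x, ...) {
  tibble(thickness_um = x$thickness_um,
         particle_layer_z_um = x$particle_layer_z_um,
         cell_layer_top_z_um = x$cell_layer_top_z_um)
}
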