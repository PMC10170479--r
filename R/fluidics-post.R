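#' Wall shear stress along the tissue-liquid interface
#'
#' Evaluates `tau(x) = mu * du/dn` on the top (membrane) or bottom wall by
#' a one-sided second-order difference that is exact for parabolic
#' profiles. `surface = "membrane"` restricts the profile to the insert
#' footprint on the top wall.
#'
#' @param sol A `field_solution` from [solve_flow()].
#' @param surface `"membrane"` (top wall over the insert footprint),
#'   `"pool"` (top wall across the whole pool, the tissue-liquid interface
#'   plotted in geometry comparisons), `"top"`, or `"bottom"`.
#' @return A tibble `x_mm`, `shear_pa`, `shear_dyn_cm2`.
#' @export
wall_shear_profile <- function(sol, surface = c("membrane", "pool", "top",
                                                "bottom")) {
  stopifnot(inherits(sol, "field_solution"))
  surface <- match.arg(surface)
  mu <- sol$params$viscosity_pas
  nz <- sol$nz
  uc <- (sol$u[-1, , drop = FALSE] + sol$u[-(sol$nx + 1L), , drop = FALSE]) / 2
  if (surface == "bottom") {
    grad <- (9 * uc[, 1] - uc[, 2]) / (3 * sol$dz_m)
  } else {
    grad <- (9 * uc[, nz] - uc[, nz - 1]) / (3 * sol$dz_m)
  }
  out <- tibble(x_mm = sol$x_c_mm, shear_pa = abs(mu * grad)) |>
    mutate(shear_dyn_cm2 = pa_to_dyn_cm2(.data$shear_pa))
  if (surface == "membrane") {
    fp <- footprint_mm(sol$geom)
    out <- filter(out, .data$x_mm >= fp[1], .data$x_mm <= fp[2])
    if (!nrow(out)) abort("no grid cells under the insert footprint; refine the mesh.")
  } else if (surface == "pool") {
    g <- sol$geom
    if (!g$include_pool) abort("the straight-channel geometry has no pool.")
    out <- filter(out, .data$x_mm >= g$channel_length_mm,
                  .data$x_mm <= g$channel_length_mm + g$pool_length_mm)
  }
  out
}

#' Uniformity of a wall-shear profile
#'
#' Coefficient of variation (sd/mean) of the shear over the profile, the
#' summary used to compare chip geometries: a wide channel feeds the pool
#' evenly (small CV), a narrow one produces a heterogeneous interface.
#'
#' @param profile A tibble from [wall_shear_profile()] (column `shear_pa`).
#' @return A single CV value.
#' @export
shear_uniformity <- function(profile) {
  s <- profile$shear_pa %||% abort("profile lacks a shear_pa column.")
  m <- mean(s)
  if (!is.finite(m) || m == 0) abort("mean shear is zero; CV undefined.")
  sd(s) / m
}

#' Representative flow speed under the porous membrane
#'
#' Mean tangential speed sampled 50-150 µm below the membrane across the
#' insert footprint (linear interpolation of the staggered solution in z).
#'
#' @param sol A `field_solution`.
#' @param depth_range_um Sampling band below the membrane, µm.
#' @param n_depths Number of sampling depths across the band.
#' @return Mean speed, m/s.
#' @export
membrane_velocity <- function(sol, depth_range_um = c(50, 150),
                              n_depths = 5) {
  stopifnot(inherits(sol, "field_solution"))
  fp <- footprint_mm(sol$geom)
  cols <- which(sol$x_c_mm >= fp[1] & sol$x_c_mm <= fp[2])
  if (!length(cols)) abort("no grid cells under the insert footprint.")
  uc <- (sol$u[-1, , drop = FALSE] + sol$u[-(sol$nx + 1L), , drop = FALSE]) / 2
  h <- sol$height_m
  z_grid <- c(0, sol$z_c_mm * 1e-3, h)           # wall-anchored z nodes
  depths <- seq(depth_range_um[1], depth_range_um[2],
                length.out = n_depths) * 1e-6
  z_samp <- h - depths
  speeds <- vapply(cols, function(i) {
    prof <- c(0, uc[i, ], 0)                      # no-slip anchors
    mean(abs(approx(z_grid, prof, xout = z_samp)$y))
  }, numeric(1))
  mean(speeds)
}
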