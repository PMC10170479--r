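#' Chip geometry for the reduced-order fluidics model
#'
#' The culture chip is an inlet channel, a central hexagonal pool housing
#' the porous insert, and an outlet channel. The solver works on a 2D
#' vertical mid-plane slice (x along the flow, z across the liquid depth)
#' with a segment-wise effective width: the channel width in the channels,
#' and `pool_surface / pool_length` in the pool so that the pool's plan
#' area is preserved. The pool depth is derived as `volume / surface`.
#'
#' @param channel_length_mm,channel_width_mm,channel_height_mm Channel
#'   dimensions (defaults 15 x 4 x 1.5 mm).
#' @param pool_surface_cm2 Plan area of the hexagonal pool (default 2.08).
#' @param pool_volume_cm3 Pool volume (default 0.312).
#' @param insert_diameter_mm Porous-insert diameter (default 6.5).
#' @param include_pool `FALSE` gives a straight channel only (useful for
#'   analytic Poiseuille checks).
#' @return A `chip_geometry` list with derived fields `pool_depth_mm`,
#'   `pool_length_mm` (long diagonal of the equal-area regular hexagon),
#'   `pool_eff_width_mm`, `domain_length_mm`.
#' @examples
#' chip_geometry()
#' chip_geometry(channel_width_mm = 1)  # the narrow-channel comparison case
#' @export
chip_geometry <- function(channel_length_mm = 15, channel_width_mm = 4,
                          channel_height_mm = 1.5,
                          pool_surface_cm2 = 2.08, pool_volume_cm3 = 0.312,
                          insert_diameter_mm = 6.5, include_pool = TRUE) {
  for (nm in c("channel_length_mm", "channel_width_mm", "channel_height_mm",
               "pool_surface_cm2", "pool_volume_cm3", "insert_diameter_mm")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  pool_depth_mm <- pool_volume_cm3 / pool_surface_cm2 * 10
  area_mm2 <- pool_surface_cm2 * 100
  # regular hexagon of equal area; flow crosses it along the long diagonal
  side_mm <- sqrt(2 * area_mm2 / (3 * sqrt(3)))
  pool_length_mm <- 2 * side_mm
  pool_eff_width_mm <- area_mm2 / pool_length_mm
  if (include_pool && abs(pool_depth_mm - channel_height_mm) > 0.2) {
    warn(sprintf(
      "pool depth (%.2f mm) differs from channel height (%.2f mm); the slice uses the channel height.",
      pool_depth_mm, channel_height_mm))
  }
  domain_length_mm <- if (include_pool) {
    2 * channel_length_mm + pool_length_mm
  } else {
    channel_length_mm
  }
  structure(
    list(channel_length_mm = channel_length_mm,
         channel_width_mm = channel_width_mm,
         channel_height_mm = channel_height_mm,
         pool_surface_cm2 = pool_surface_cm2,
         pool_volume_cm3 = pool_volume_cm3,
         insert_diameter_mm = insert_diameter_mm,
         include_pool = include_pool,
         pool_depth_mm = pool_depth_mm,
         pool_length_mm = if (include_pool) pool_length_mm else 0,
         pool_eff_width_mm = pool_eff_width_mm,
         domain_length_mm = domain_length_mm),
    class = "chip_geometry"
  )
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat("<chip_geometry>\n")
  cat(sprintf("  channel: %g x %g x %g mm\n", x$channel_length_mm,
              x$channel_width_mm, x$channel_height_mm))
  if (x$include_pool) {
    cat(sprintf("  pool: %.3g cm^2 x %.3g mm deep; effective %.3g x %.3g mm in the slice\n",
                x$pool_surface_cm2, x$pool_depth_mm, x$pool_length_mm,
                x$pool_eff_width_mm))
    cat(sprintf("  insert: %g mm diameter\n", x$insert_diameter_mm))
  } else {
    cat("  straight channel (no pool)\n")
  }
  invisible(x)
}

# Effective width (mm) at positions x (mm along the flow axis).
geom_width_mm <- function(geom, x_mm) {
  if (!geom$include_pool) {
    return(rep(geom$channel_width_mm, length(x_mm)))
  }
  in_pool <- x_mm > geom$channel_length_mm &
    x_mm < geom$channel_length_mm + geom$pool_length_mm
  ifelse(in_pool, geom$pool_eff_width_mm, geom$channel_width_mm)
}

# x-interval (mm) of the insert footprint on the top wall.
footprint_mm <- function(geom) {
  if (!geom$include_pool) abort("the straight-channel geometry has no insert footprint.")
  centre <- geom$channel_length_mm + geom$pool_length_mm / 2
  c(centre - geom$insert_diameter_mm / 2, centre + geom$insert_diameter_mm / 2)
}

#' Transport and perfusion parameters for the chip model
#'
#' Defaults are the standard simulation constants for airway-epithelium
#' culture medium at 37 degC: inlet oxygen 0.22 mol/m^3, oxygen diffusivity
#' 3e-9 m^2/s, cell density 7.5e13 cell/m^3, maximum per-cell oxygen
#' consumption 3.42e-16 mol/(cell s), Michaelis constant 0.214 mol/m^3,
#' water-like viscosity and density, and a 40 uL/min perfusion rate.
#'
#' @param inlet_o2_mol_m3 Inlet oxygen concentration.
#' @param diffusivity_m2_s Oxygen diffusion coefficient.
#' @param cell_density_m3 Volumetric cell density of the tissue layer.
#' @param v_max_mol_cell_s Maximum oxygen consumption rate per cell.
#' @param k_m_mol_m3 Oxygen concentration at half-maximal consumption.
#' @param viscosity_pas Medium dynamic viscosity.
#' @param density_kg_m3 Medium density.
#' @param flow_ul_min Perfusion flow rate, µL/min.
#' @param tissue_thickness_um Thickness of the consuming tissue layer under
#'   the membrane (layer model).
#' @param n_cells Total seeded cell count (alternative `"cells"` sink
#'   model).
#' @return A `transport_params` list.
#' @export
transport_params <- function(inlet_o2_mol_m3 = 0.22,
                             diffusivity_m2_s = 3e-9,
                             cell_density_m3 = 7.5e13,
                             v_max_mol_cell_s = 3.42e-16,
                             k_m_mol_m3 = 2.14e-1,
                             viscosity_pas = 1e-3,
                             density_kg_m3 = 1000,
                             flow_ul_min = 40,
                             tissue_thickness_um = 20,
                             n_cells = 250000) {
  for (nm in c("inlet_o2_mol_m3", "diffusivity_m2_s", "cell_density_m3",
               "v_max_mol_cell_s", "k_m_mol_m3", "viscosity_pas",
               "density_kg_m3", "tissue_thickness_um", "n_cells")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  check_number(flow_ul_min, "flow_ul_min", nonneg = TRUE)
  structure(
    list(inlet_o2_mol_m3 = inlet_o2_mol_m3,
         diffusivity_m2_s = diffusivity_m2_s,
         cell_density_m3 = cell_density_m3,
         v_max_mol_cell_s = v_max_mol_cell_s,
         k_m_mol_m3 = k_m_mol_m3,
         viscosity_pas = viscosity_pas,
         density_kg_m3 = density_kg_m3,
         flow_ul_min = flow_ul_min,
         tissue_thickness_um = tissue_thickness_um,
         n_cells = n_cells),
    class = "transport_params"
  )
}

#' @export
print.transport_params <- function(x, ...) {
  cat("<transport_params>\n")
  cat(sprintf("  flow: %g uL/min, mu = %g Pa.s, rho = %g kg/m^3\n",
              x$flow_ul_min, x$viscosity_pas, x$density_kg_m3))
  cat(sprintf("  O2: inlet %g mol/m^3, D = %g m^2/s, Vmax = %g mol/(cell.s), Km = %g mol/m^3\n",
              x$inlet_o2_mol_m3, x$diffusivity_m2_s, x$v_max_mol_cell_s,
              x$k_m_mol_m3))
  invisible(x)
}
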