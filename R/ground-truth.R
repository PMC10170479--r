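#' Ground-truth parameters for simulated tracer-bead experiments
#'
#' Bundles the physical and acquisition parameters that define a simulated
#' multiple-particle-tracking (MPT) experiment: medium rheology (viscosity,
#' optionally an elastic modulus for a Maxwell fluid), tracer radius,
#' temperature, and the camera settings. Defaults mirror a typical mucus MPT
#' acquisition: 200 nm beads (radius 100 nm), room temperature, 5 s of video
#' at 20 frames per second.
#'
#' @param viscosity_pas Medium viscosity in Pa·s (1 cP = 1e-3 Pa·s).
#' @param elastic_modulus_pa Elastic modulus G in Pa for a Maxwell
#'   (viscoelastic) medium, or `NULL` for a purely viscous fluid.
#' @param particle_radius_m Tracer bead radius in metres.
#' @param temperature_k Absolute temperature in kelvin.
#' @param frame_rate Acquisition rate in frames per second.
#' @param n_particles Number of beads to simulate.
#' @param n_frames Number of frames per trajectory (>= 2).
#' @param localization_noise_sd_m Standard deviation of additive Gaussian
#'   localization error applied per frame and per axis, in metres. The paper
#'   trail of real MPT data always carries some static tracking error; 20 nm
#'   is a typical value for bright sub-micron beads. Set to 0 to disable.
#' @param seed Integer seed making the simulation reproducible, or `NULL`.
#'
#' @return An object of class `rheo_ground_truth` (a named list).
#' @examples
#' rheo_ground_truth(viscosity_pas = 1e-3)
#' rheo_ground_truth(viscosity_pas = 20e-3, elastic_modulus_pa = 1)
#' @export
rheo_ground_truth <- function(viscosity_pas,
                              elastic_modulus_pa = NULL,
                              particle_radius_m = 100e-9,
                              temperature_k = 298.15,
                              frame_rate = 20,
                              n_particles = 100L,
                              n_frames = 100L,
                              localization_noise_sd_m = 20e-9,
                              seed = NULL) {
  check_number(viscosity_pas, "viscosity_pas", positive = TRUE)
  if (!is.null(elastic_modulus_pa)) {
    check_number(elastic_modulus_pa, "elastic_modulus_pa", positive = TRUE)
  }
  check_number(particle_radius_m, "particle_radius_m", positive = TRUE)
  check_number(temperature_k, "temperature_k", positive = TRUE)
  check_number(frame_rate, "frame_rate", positive = TRUE)
  n_particles <- check_count(n_particles, "n_particles")
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  check_number(localization_noise_sd_m, "localization_noise_sd_m", nonneg = TRUE)
  structure(
    list(
      viscosity_pas = viscosity_pas,
      elastic_modulus_pa = elastic_modulus_pa,
      particle_radius_m = particle_radius_m,
      temperature_k = temperature_k,
      frame_rate = frame_rate,
      n_particles = n_particles,
      n_frames = n_frames,
      localization_noise_sd_m = localization_noise_sd_m,
      seed = seed
    ),
    class = "rheo_ground_truth"
  )
}

#' @export
print.rheo_ground_truth <- function(x, ...) {
  regime <- if (is.null(x$elastic_modulus_pa)) "viscous" else "viscoelastic (Maxwell)"
  cat("<rheo_ground_truth>", regime, "\n")
  cat(sprintf("  viscosity: %g cP", pas_to_cp(x$viscosity_pas)))
  if (!is.null(x$elastic_modulus_pa)) {
    cat(sprintf(", G: %g Pa", x$elastic_modulus_pa))
  }
  cat("\n")
  cat(sprintf("  bead radius: %g nm, T: %g K\n", x$particle_radius_m * 1e9,
              x$temperature_k))
  cat(sprintf("  %d particles x %d frames at %g fps, localization sd %g nm\n",
              x$n_particles, x$n_frames, x$frame_rate,
              x$localization_noise_sd_m * 1e9))
  invisible(x)
}

#' Equivalent-circuit parameters of the epithelial impedance model
#'
#' The epithelium and measurement chain are modelled as the tight-junction
#' resistance (TEER) in parallel with the membrane capacitance, in series
#' with the solution resistance and the electrode capacitance.
#'
#' @param r_sol_ohm Solution (medium) resistance, ohm.
#' @param r_teer_ohm Transepithelial resistance, ohm.
#' @param c_membrane_f Membrane capacitance, farad.
#' @param c_electrode_f Electrode capacitance, farad.
#' @return An object of class `circuit_params`.
#' @examples
#' circuit_params(100, 1000, 100e-9, 1e-6)
#' @export
circuit_params <- function(r_sol_ohm, r_teer_ohm, c_membrane_f, c_electrode_f) {
  check_number(r_sol_ohm, "r_sol_ohm", positive = TRUE)
  check_number(r_teer_ohm, "r_teer_ohm", positive = TRUE)
  check_number(c_membrane_f, "c_membrane_f", positive = TRUE)
  check_number(c_electrode_f, "c_electrode_f", positive = TRUE)
  structure(
    list(r_sol_ohm = r_sol_ohm, r_teer_ohm = r_teer_ohm,
         c_membrane_f = c_membrane_f, c_electrode_f = c_electrode_f),
    class = "circuit_params"
  )
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  cat(sprintf("  R_sol = %g ohm, R_teer = %g ohm\n", x$r_sol_ohm, x$r_teer_ohm))
  cat(sprintf("  C_membrane = %g nF, C_electrode = %g nF\n",
              x$c_membrane_f * 1e9, x$c_electrode_f * 1e9))
  invisible(x)
}
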