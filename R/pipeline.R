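#' Run a configured end-to-end analysis
#'
#' Executes the selected stages on simulated inputs with known ground
#' truth, in dependency order, and returns a machine-readable report. Every
#' stage draws its random numbers from a seed derived deterministically
#' from `config$seed`, so a fixed configuration reproduces its report (and
#' any written files) bit-identically.
#'
#' The configuration is a named list (or a YAML file path) with an optional
#' `seed`, `output_dir`, and a `stages` character vector choosing among:
#' \describe{
#'   \item{rheology}{simulate tracer trajectories (optionally render to
#'     video and re-track them), compute MSDs, and fit viscosity/elastic
#'     modulus. Parameters under `rheology`: `viscosity_cp`,
#'     `elastic_modulus_pa` (NULL for viscous), `n_particles`, `n_frames`,
#'     `frame_rate`, `radius_nm`, `temperature_k`, `n_regions`,
#'     `from_video` (logical), `localization_noise_nm`.}
#'   \item{impedance}{simulate a spectrum from `r_sol_ohm`, `r_teer_ohm`,
#'     `c_membrane_nf`, `c_electrode_nf`, `noise_fraction` and fit the
#'     equivalent circuit; reports the Bode modulus at 12 Hz too.}
#'   \item{fluidics}{solve flow + oxygen at `flow_ul_min`,
#'     `channel_width_mm`, `resolution`; reports membrane shear, velocity
#'     and minimum oxygen.}
#'   \item{cbf}{simulate a beat trace (`cbf_hz`, `frame_rate`,
#'     `duration_s`, `noise_sd`) and estimate the beat frequency.}
#'   \item{thickness}{simulate a two-layer z-stack (`gap_um`,
#'     `z_spacing_um`) and measure the mucus thickness.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return A `pipeline_report`: `stages` (per-stage outputs), `metrics`
#'   (tidy tibble of scalar summaries), `config`, `log`.
#' @examples
#' rep <- run_pipeline(list(seed = 1, stages = "cbf",
#'                          cbf = list(cbf_hz = 8)))
#' rep$metrics
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  stages <- config$stages %||% character(0)
  known <- c("rheology", "impedance", "fluidics", "cbf", "thickness")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  log_lines <- c(sprintf("pipeline seed: %d", as.integer(seed)),
                 sprintf("stages: %s",
                         if (length(stages)) paste(stages, collapse = ", ")
                         else "(none)"))
  results <- list()
  metrics <- tibble(metric = character(0), value = numeric(0))
  add_metric <- function(name, value) {
    metrics <<- bind_rows(metrics, tibble(metric = name,
                                          value = as.numeric(value)))
  }
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    log_lines <<- c(log_lines, sprintf("stage %s: done", name))
    results[[name]] <<- res
  }

  if ("rheology" %in% stages) run_stage("rheology", function() {
    p <- config$rheology %||% list()
    truth <- rheo_ground_truth(
      viscosity_pas = cp_to_pas(p$viscosity_cp %||% 18),
      elastic_modulus_pa = p$elastic_modulus_pa,
      particle_radius_m = (p$radius_nm %||% 100) * 1e-9,
      temperature_k = p$temperature_k %||% 298.15,
      frame_rate = p$frame_rate %||% 20,
      n_particles = p$n_particles %||% 200L,
      n_frames = p$n_frames %||% 100L,
      localization_noise_sd_m = (p$localization_noise_nm %||% 20) * 1e-9,
      seed = derive_seed(seed, 1L)
    )
    starts <- NULL
    if (isTRUE(p$from_video)) {
      # spots must stay well separated for faithful detection: start the
      # beads on a grid and size the field of view to hold them
      k <- ceiling(sqrt(truth$n_particles))
      spacing <- 12; margin <- 20
      grid <- expand.grid(x = margin + (seq_len(k) - 1) * spacing,
                          y = margin + (seq_len(k) - 1) * spacing)
      starts <- as.matrix(grid[seq_len(truth$n_particles), ])
    }
    traj <- if (is.null(truth$elastic_modulus_pa)) {
      simulate_brownian_trajectories(truth, n_regions = p$n_regions %||% 8L,
                                     start_positions_um = starts)
    } else {
      simulate_viscoelastic_trajectories(truth,
                                         n_regions = p$n_regions %||% 8L,
                                         start_positions_um = starts)
    }
    if (isTRUE(p$from_video)) {
      px <- 0.65
      extent <- 2 * 20 + (ceiling(sqrt(truth$n_particles)) - 1) * 12
      shape <- rep(ceiling(extent / px), 2)
      video <- render_spot_video(traj, image_shape = shape,
                                 pixel_size_um = px, snr = 20,
                                 seed = derive_seed(seed, 2L),
                                 offscreen = "skip")
      thr <- 0.2 * max(video)
      traj <- track_video(video, intensity_threshold = thr,
                          max_displacement_um = 5)
    }
    msd <- compute_msd(traj)
    fits <- fit_rheology(msd, radius_m = truth$particle_radius_m,
                         temperature_k = truth$temperature_k,
                         localization_sd_m = truth$localization_noise_sd_m)
    add_metric("viscosity_cp_mean", mean(fits$viscosity_cp))
    add_metric("viscosity_cp_sd", sd(fits$viscosity_cp))
    if (any(is.finite(fits$elastic_modulus_pa))) {
      add_metric("elastic_modulus_pa_mean",
                 mean(fits$elastic_modulus_pa, na.rm = TRUE))
    }
    list(truth = truth, msd = msd, fits = fits)
  })

  if ("impedance" %in% stages) run_stage("impedance", function() {
    p <- config$impedance %||% list()
    par <- circuit_params(p$r_sol_ohm %||% 100, p$r_teer_ohm %||% 1000,
                          (p$c_membrane_nf %||% 100) * 1e-9,
                          (p$c_electrode_nf %||% 1000) * 1e-9)
    spec <- simulate_impedance_spectrum(par,
                                        noise_fraction = p$noise_fraction %||% 0.02,
                                        seed = derive_seed(seed, 3L))
    fit <- fit_circuit(spec)
    add_metric("r_teer_ohm", fit$params$r_teer_ohm)
    add_metric("c_membrane_nf", fit$params$c_membrane_f * 1e9)
    add_metric("bode_modulus_12hz_ohm", bode_modulus_at(spec, 12))
    list(truth = par, spectrum = spec, fit = fit)
  })

  if ("fluidics" %in% stages) run_stage("fluidics", function() {
    p <- config$fluidics %||% list()
    geom <- chip_geometry(channel_width_mm = p$channel_width_mm %||% 4)
    params <- transport_params(flow_ul_min = p$flow_ul_min %||% 40)
    sol <- solve_flow(geom, params, resolution = p$resolution %||% 16)
    sol <- solve_oxygen(sol)
    prof <- wall_shear_profile(sol, "membrane")
    add_metric("membrane_shear_dyn_cm2", mean(prof$shear_dyn_cm2))
    add_metric("membrane_velocity_m_s", membrane_velocity(sol))
    add_metric("oxygen_min_mol_m3", sol$oxygen_min)
    sol
  })

  if ("cbf" %in% stages) run_stage("cbf", function() {
    p <- config$cbf %||% list()
    trace <- simulate_cilia_trace(p$cbf_hz %||% 8,
                                  frame_rate = p$frame_rate %||% 100,
                                  duration_s = p$duration_s %||% 2,
                                  noise_sd = p$noise_sd %||% 0,
                                  seed = derive_seed(seed, 4L))
    res <- count_peaks_cbf(trace)
    add_metric("cbf_hz", res$cbf_hz)
    res
  })

  if ("thickness" %in% stages) run_stage("thickness", function() {
    p <- config$thickness %||% list()
    zs <- simulate_two_layer_zstack(p$gap_um %||% 39.4,
                                    z_spacing_um = p$z_spacing_um %||% 1,
                                    seed = derive_seed(seed, 5L))
    res <- mucus_thickness(zs)
    add_metric("mucus_thickness_um", res$thickness_um)
    res
  })

  report <- structure(
    list(stages = results, metrics = metrics, config = config,
         seed = seed, log = log_lines),
    class = "pipeline_report"
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(metrics, file.path(config$output_dir, "metrics.csv"))
    jsonlite::write_json(
      list(seed = seed, stages = stages,
           metrics = setNames(as.list(metrics$value), metrics$metric)),
      file.path(config$output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(config$output_dir, "run.log"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> seed %d, stages: %s\n", x$seed,
              if (length(x$stages)) paste(names(x$stages), collapse = ", ")
              else "(none)"))
  if (nrow(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Summarise replicate runs by experimental condition
#'
#' Collects the scalar metrics of several [run_pipeline()] reports, groups
#' them by condition, and reports group means and standard deviations plus
#' the direction of each metric's difference relative to the first group.
#' Optional significance testing is delegated to the standard routines
#' (one-way ANOVA with Tukey HSD, or Kruskal-Wallis) and reported
#' pass-through.
#'
#' @param reports List of `pipeline_report` objects.
#' @param grouping Character/factor of condition labels, one per report.
#' @param test `"none"`, `"anova"`, or `"kruskal"`.
#' @return A tibble `metric`, `group`, `n`, `mean`, `sd` (NA for single
#'   runs), `direction_vs_first`; when testing is requested, attribute
#'   `tests` holds a tibble of p-values per metric.
#' @export
compare_conditions <- function(reports, grouping,
                               test = c("none", "anova", "kruskal")) {
  test <- match.arg(test)
  if (!length(reports)) abort("no reports supplied.")
  if (length(grouping) != length(reports)) {
    abort("`grouping` must have one label per report.")
  }
  long <- purrr::map2_dfr(reports, as.character(grouping), function(r, g) {
    stopifnot(inherits(r, "pipeline_report"))
    mutate(r$metrics, group = g)
  })
  if (!nrow(long)) abort("reports carry no metrics (empty groups?).")
  summ <- long |>
    group_by(.data$metric, .data$group) |>
    summarise(n = n(), mean = mean(.data$value),
              sd = if (n() > 1) sd(.data$value) else NA_real_,
              .groups = "drop")
  first_group <- as.character(grouping)[1]
  ref <- summ |> filter(.data$group == first_group) |>
    select("metric", ref_mean = "mean")
  summ <- summ |>
    left_join(ref, by = "metric") |>
    mutate(direction_vs_first = sign(.data$mean - .data$ref_mean)) |>
    select(-"ref_mean")
  if (test != "none" && dplyr::n_distinct(grouping) > 1) {
    tests <- purrr::map_dfr(split(long, long$metric), function(d) {
      if (dplyr::n_distinct(d$group) < 2 || nrow(d) < 3) return(NULL)
      p <- if (test == "anova") {
        summary(stats::aov(value ~ group, data = d))[[1]][["Pr(>F)"]][1]
      } else {
        stats::kruskal.test(value ~ factor(group), data = d)$p.value
      }
      tibble(metric = d$metric[1], test = test, p_value = p)
    })
    attr(summ, "tests") <- tests
  }
  summ
}
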