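#' Solve the steady laminar flow through the chip
#'
#' Incompressible Stokes flow on a 2D vertical mid-plane slice of the
#' inlet-channel / pool / outlet-channel domain, discretized on a staggered
#' (MAC) grid and solved as one sparse saddle-point system. The local
#' effective width `w(x)` of the 3D device enters the continuity equation,
#' so the section-averaged velocity drops by the width ratio when the flow
#' enters the pool. Boundary conditions: a parabolic inlet profile carrying
#' the flow rate, no-slip top (membrane) and bottom walls, and a zero
#' reference pressure at the outlet. Inertia is neglected: the Reynolds
#' number at the default perfusion rate is well below one, and the solution
#' carries it so callers can verify the laminar assumption.
#'
#' @param geom A [chip_geometry()].
#' @param params A [transport_params()].
#' @param resolution Number of cells across the liquid depth (>= 10).
#' @param nx Number of cells along the flow; default keeps the cell aspect
#'   ratio near 2.5.
#' @return A `field_solution` list: face velocities `u` (m/s,
#'   `(nx+1) x nz`), `v` (`nx x (nz+1)`), cell pressures `p` (Pa), grid
#'   vectors (mm), widths, flow rate, Reynolds number.
#' @examples
#' \donttest{
#' sol <- solve_flow(chip_geometry(), transport_params(), resolution = 10)
#' }
#' @export
solve_flow <- function(geom, params, resolution = 16, nx = NULL) {
  stopifnot(inherits(geom, "chip_geometry"), inherits(params, "transport_params"))
  nz <- check_count(resolution, "resolution", min = 10L)
  L <- geom$domain_length_mm * 1e-3
  h <- geom$channel_height_mm * 1e-3
  dz <- h / nz
  nx <- nx %||% max(20L, as.integer(round(L / (2.5 * dz))))
  nx <- check_count(nx, "nx", min = 5L)
  dx <- L / nx
  mu <- params$viscosity_pas
  Q <- params$flow_ul_min * 1e-9 / 60  # m^3/s

  x_c <- (seq_len(nx) - 0.5) * dx      # cell centers, m
  x_f <- (seq_len(nx + 1) - 1) * dx    # u-face positions, m
  z_c <- (seq_len(nz) - 0.5) * dz
  w_c <- geom_width_mm(geom, x_c * 1e3) * 1e-3
  w_f <- c(w_c[1], (w_c[-1] + w_c[-nx]) / 2, w_c[nx])

  # inlet parabola normalized to carry exactly Q on the discrete grid
  u_in <- (z_c / h) * (1 - z_c / h)
  u_in <- u_in * Q / (w_f[1] * sum(u_in) * dz)

  n_u <- nx * nz            # unknown u faces i = 2..nx+1
  n_v <- nx * (nz - 1)      # unknown v faces j = 2..nz
  n_p <- nx * nz
  iu <- function(i, j) (j - 1L) * nx + (i - 1L)          # i in 2..nx+1
  iv <- function(i, j) n_u + (j - 2L) * nx + i           # j in 2..nz
  ip <- function(i, j) n_u + n_v + (j - 1L) * nx + i

  cap <- 14L * (n_u + n_v + n_p)
  ti <- integer(cap); tj <- integer(cap); tv <- numeric(cap)
  k <- 0L
  add <- function(r, c, v) {
    k <<- k + 1L
    ti[k] <<- r; tj[k] <<- c; tv[k] <<- v
  }
  rhs <- numeric(n_u + n_v + n_p)

  idx2 <- 1 / dx^2; idz2 <- 1 / dz^2
  # u momentum -----------------------------------------------------------
  for (j in seq_len(nz)) {
    for (i in 2:(nx + 1L)) {
      r <- iu(i, j)
      if (i <= nx) {
        add(r, iu(i, j), -2 * mu * idx2)
        if (i > 2L) add(r, iu(i - 1L, j), mu * idx2) else
          rhs[r] <- rhs[r] - mu * idx2 * u_in[j]
        add(r, iu(i + 1L, j), mu * idx2)
        add(r, ip(i - 1L, j), 1 / dx)
        add(r, ip(i, j), -1 / dx)
      } else {
        # outlet face: zero-gradient in x, face pressure pinned to 0
        add(r, iu(i, j), -mu * idx2)
        add(r, iu(i - 1L, j), mu * idx2)
        add(r, ip(nx, j), 2 / dx)
      }
      # z-Laplacian with quadratic no-slip ghosts at the walls (exact for
      # parabolic profiles, so the Poiseuille limit is recovered to
      # solver precision)
      if (j == 1L && nz >= 2L) {
        add(r, iu(i, j), -4 * mu * idz2)
        add(r, iu(i, j + 1L), (4 / 3) * mu * idz2)
      } else if (j == nz && nz >= 2L) {
        add(r, iu(i, j), -4 * mu * idz2)
        add(r, iu(i, j - 1L), (4 / 3) * mu * idz2)
      } else {
        add(r, iu(i, j), -2 * mu * idz2)
        add(r, iu(i, j - 1L), mu * idz2)
        add(r, iu(i, j + 1L), mu * idz2)
      }
    }
  }
  # v momentum -----------------------------------------------------------
  if (nz >= 2L) {
    for (j in 2:nz) {
      for (i in seq_len(nx)) {
        r <- iv(i, j)
        # x part
        if (i == 1L) {
          add(r, iv(i, j), -3 * mu * idx2)
          add(r, iv(i + 1L, j), mu * idx2)
        } else if (i == nx) {
          add(r, iv(i, j), -mu * idx2)
          add(r, iv(i - 1L, j), mu * idx2)
        } else {
          add(r, iv(i, j), -2 * mu * idx2)
          add(r, iv(i - 1L, j), mu * idx2)
          add(r, iv(i + 1L, j), mu * idx2)
        }
        # z part (v = 0 on walls handled by dropping those terms)
        add(r, iv(i, j), -2 * mu * idz2)
        if (j > 2L) add(r, iv(i, j - 1L), mu * idz2)
        if (j < nz) add(r, iv(i, j + 1L), mu * idz2)
        add(r, ip(i, j - 1L), 1 / dz)
        add(r, ip(i, j), -1 / dz)
      }
    }
  }
  # continuity ------------------------------------------------------------
  for (j in seq_len(nz)) {
    for (i in seq_len(nx)) {
      r <- ip(i, j)
      add(r, iu(i + 1L, j), w_f[i + 1] / dx)
      if (i > 1L) add(r, iu(i, j), -w_f[i] / dx) else
        rhs[r] <- rhs[r] + w_f[1] * u_in[j] / dx
      if (j < nz) add(r, iv(i, j + 1L), w_c[i] / dz)
      if (j > 1L) add(r, iv(i, j), -w_c[i] / dz)
    }
  }

  A <- Matrix::sparseMatrix(i = ti[1:k], j = tj[1:k], x = tv[1:k],
                            dims = c(n_u + n_v + n_p, n_u + n_v + n_p))
  sol <- tryCatch(
    as.numeric(Matrix::solve(A, rhs)),
    error = function(e) abort(paste0("flow solve failed: ", conditionMessage(e)))
  )
  if (any(!is.finite(sol))) abort("flow solve returned non-finite values.")

  U <- matrix(0, nx + 1L, nz)
  U[1, ] <- u_in
  U[2:(nx + 1L), ] <- matrix(sol[1:n_u], nx, nz)
  V <- matrix(0, nx, nz + 1L)
  if (nz >= 2L) V[, 2:nz] <- matrix(sol[n_u + seq_len(n_v)], nx, nz - 1L)
  P <- matrix(sol[n_u + n_v + seq_len(n_p)], nx, nz)

  u_mean_channel <- Q / (geom$channel_width_mm * 1e-3 * h)
  reynolds <- params$density_kg_m3 * u_mean_channel * h / mu
  if (reynolds > 10) {
    warn(sprintf("Reynolds number %.3g exceeds 10; the Stokes model assumes creeping flow.",
                 reynolds))
  }

  structure(
    list(u = U, v = V, p = P,
         x_c_mm = x_c * 1e3, x_f_mm = x_f * 1e3, z_c_mm = z_c * 1e3,
         dx_m = dx, dz_m = dz, w_c_m = w_c, w_f_m = w_f,
         nx = nx, nz = nz, height_m = h,
         Q_m3_s = Q, reynolds = reynolds,
         geom = geom, params = params),
    class = "field_solution"
  )
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %d x %d cells over %.3g x %.3g mm\n",
              x$nx, x$nz, max(x$x_f_mm), x$height_m * 1e3))
  cat(sprintf("  Q = %.3g m^3/s, Re = %.3g, max |u| = %.3g m/s\n",
              x$Q_m3_s, x$reynolds, max(abs(x$u))))
  if (!is.null(x$oxygen)) {
    cat(sprintf("  oxygen: min %.4g mol/m^3\n", min(x$oxygen)))
  }
  invisible(x)
}

#' Volumetric flux through every vertical cross-section
#'
#' Discrete conservation check: `sum_j w(x) u(x, z_j) dz` at each u-face,
#' which should equal the imposed flow rate everywhere.
#'
#' @param sol A `field_solution`.
#' @return A tibble `x_mm`, `flux_m3_s`.
#' @export
section_flux <- function(sol) {
  flux <- colSums(t(sol$u) * sol$dz_m) * sol$w_f_m
  tibble(x_mm = sol$x_f_mm, flux_m3_s = flux)
}

#' Field values at cell centers as a tidy table
#'
#' @param sol A `field_solution` (with oxygen if [solve_oxygen()] ran).
#' @return A tibble `x_mm`, `z_mm`, `u_m_s`, `v_m_s`, `p_pa` (+ `o2_mol_m3`).
#' @export
field_points <- function(sol) {
  uc <- (sol$u[-1, , drop = FALSE] + sol$u[-(sol$nx + 1L), , drop = FALSE]) / 2
  vc <- (sol$v[, -1, drop = FALSE] + sol$v[, -(sol$nz + 1L), drop = FALSE]) / 2
  grid <- expand.grid(i = seq_len(sol$nx), j = seq_len(sol$nz))
  out <- tibble(
    x_mm = sol$x_c_mm[grid$i], z_mm = sol$z_c_mm[grid$j],
    u_m_s = uc[cbind(grid$i, grid$j)],
    v_m_s = vc[cbind(grid$i, grid$j)],
    p_pa = sol$p[cbind(grid$i, grid$j)]
  )
  if (!is.null(sol$oxygen)) out$o2_mol_m3 <- sol$oxygen[cbind(grid$i, grid$j)]
  out
}

#' Heatmap of a solved field
#'
#' @param object A `field_solution`.
#' @param field One of `"u"`, `"p"`, `"oxygen"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot field_solution
#' @export
autoplot.field_solution <- function(object, field = c("u", "p", "oxygen"),
                                    ...) {
  field <- match.arg(field)
  df <- field_points(object)
  val <- switch(field, u = df$u_m_s, p = df$p_pa,
                oxygen = df$o2_mol_m3 %||% abort("run solve_oxygen() first."))
  df$value <- val
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$z_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = field) +
    ggplot2::labs(x = "x (mm)", y = "z (mm)") +
    ggplot2::theme_minimal()
}
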