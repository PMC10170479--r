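# Reduced-order chip flow and oxygen transport.

test_that("the straight channel reproduces plane Poiseuille flow", {
  sol <- straight_channel_solution()
  Q <- sol$Q_m3_s
  w <- 4e-3; h <- 1.5e-3; mu <- 1e-3
  # mean velocity at mid-length equals Q / (w h)
  mid <- which.min(abs(sol$x_c_mm - 7.5))
  u_mid <- mean(sol$u[mid, ])
  expect_equal(u_mid, Q / (w * h), tolerance = 0.01)
  # wall shear matches 6 mu Q / (w h^2) within 2%
  prof <- wall_shear_profile(sol, "top")
  interior <- abs(prof$x_mm - 7.5) < 3
  tau_ref <- 6 * mu * Q / (w * h^2)
  expect_true(all(abs(prof$shear_pa[interior] / tau_ref - 1) < 0.02))
  # bottom wall carries the same magnitude by symmetry
  prof_b <- wall_shear_profile(sol, "bottom")
  expect_equal(mean(prof_b$shear_pa[interior]),
               mean(prof$shear_pa[interior]), tolerance = 1e-6)
})

test_that("zero flow gives a fluid at rest", {
  sol <- solve_flow(chip_geometry(include_pool = FALSE),
                    transport_params(flow_ul_min = 0), resolution = 10)
  expect_lt(max(abs(sol$u)), 1e-15)
  expect_lt(max(abs(sol$v)), 1e-15)
  expect_lt(max(wall_shear_profile(sol, "top")$shear_pa), 1e-12)
})

test_that("mass is conserved through every cross-section", {
  sol <- default_chip_solution()
  fx <- section_flux(sol)
  expect_true(all(abs(fx$flux_m3_s / sol$Q_m3_s - 1) < 0.01))
})

test_that("the creeping-flow assumption holds and responses are linear in mu and Q", {
  sol <- default_chip_solution()
  expect_lt(sol$reynolds, 10)
  geom <- chip_geometry(include_pool = FALSE)
  s1 <- solve_flow(geom, transport_params(), resolution = 10)
  s2 <- solve_flow(geom, transport_params(viscosity_pas = 2e-3),
                   resolution = 10)
  # doubling mu doubles the shear at fixed flow rate (velocity unchanged)
  expect_equal(2 * mean(wall_shear_profile(s1, "top")$shear_pa),
               mean(wall_shear_profile(s2, "top")$shear_pa),
               tolerance = 1e-8)
  expect_equal(s1$u, s2$u, tolerance = 1e-8)
  # doubling Q doubles the near-membrane speed (Stokes linearity)
  p1 <- solve_flow(chip_geometry(), transport_params(), resolution = 10)
  p2 <- solve_flow(chip_geometry(), transport_params(flow_ul_min = 80),
                   resolution = 10)
  expect_equal(2 * membrane_velocity(p1), membrane_velocity(p2),
               tolerance = 1e-6)
})

test_that("membrane shear and velocity sit in the physiological design window", {
  sol <- default_chip_solution()
  prof <- wall_shear_profile(sol, "membrane")
  shear <- mean(prof$shear_dyn_cm2)
  expect_gt(shear, 1e-4)
  expect_lt(shear, 1e-2)
  vel <- membrane_velocity(sol)
  expect_gt(vel, 1e-6)
  expect_lt(vel, 1e-4)
})

test_that("shear uniformity behaves by definition and ranks the two channel widths", {
  flat <- tibble::tibble(shear_pa = rep(2, 50))
  expect_equal(shear_uniformity(flat), 0)
  spike <- tibble::tibble(shear_pa = c(rep(1, 9), 11))
  expect_equal(shear_uniformity(spike), sd(spike$shear_pa) / 2)
  expect_error(shear_uniformity(tibble::tibble(shear_pa = rep(0, 5))),
               "zero")
  s4 <- solve_flow(chip_geometry(channel_width_mm = 4), transport_params(),
                   resolution = 10)
  s1 <- solve_flow(chip_geometry(channel_width_mm = 1), transport_params(),
                   resolution = 10)
  cv4 <- shear_uniformity(wall_shear_profile(s4, "pool"))
  cv1 <- shear_uniformity(wall_shear_profile(s1, "pool"))
  expect_lt(cv4, cv1)
})

test_that("without a sink the oxygen field is uniformly at the inlet value", {
  sol <- cached("chip_lowres", solve_flow(chip_geometry(),
                                          transport_params(),
                                          resolution = 10))
  nosink <- solve_oxygen(sol, transport_params(v_max_mol_cell_s = 1e-30))
  expect_equal(range(nosink$oxygen), c(0.22, 0.22), tolerance = 1e-9)
})

test_that("oxygen stays within physical bounds and the flux budget closes", {
  sol <- default_chip_solution()
  expect_gte(min(sol$oxygen), 0)
  expect_lte(max(sol$oxygen), 0.22 * (1 + 1e-8))
  b <- sol$oxygen_balance
  imbalance <- (b$inlet_mol_s - b$outlet_mol_s - b$consumed_mol_s) /
    b$inlet_mol_s
  expect_lt(abs(imbalance), 0.02)
  # the minimum sits under the tissue, not in the free stream
  expect_lt(sol$oxygen_min, 0.22)
})

test_that("shear and minimum oxygen are grid-converged within 5% under 2x refinement", {
  coarse <- cached("chip_conv_coarse", {
    solve_oxygen(solve_flow(chip_geometry(), transport_params(),
                            resolution = 10, nx = 128))
  })
  fine <- cached("chip_conv_fine", {
    solve_oxygen(solve_flow(chip_geometry(), transport_params(),
                            resolution = 20, nx = 256))
  })
  sh_c <- mean(wall_shear_profile(coarse, "membrane")$shear_pa)
  sh_f <- mean(wall_shear_profile(fine, "membrane")$shear_pa)
  expect_equal(sh_c / sh_f, 1, tolerance = 0.05)
  expect_equal(coarse$oxygen_min / fine$oxygen_min, 1, tolerance = 0.05)
})

test_that("geometry derivations and precondition checks hold", {
  g <- chip_geometry()
  expect_equal(g$pool_depth_mm, 0.312 / 2.08 * 10)
  expect_equal(g$pool_eff_width_mm * g$pool_length_mm, 208)  # area preserved
  expect_error(chip_geometry(channel_width_mm = -1), "positive")
  expect_error(solve_flow(chip_geometry(), transport_params(),
                          resolution = 4), "integer")
  expect_error(wall_shear_profile(straight_channel_solution(), "membrane"),
               "footprint")
})
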