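## Build a synthetic field on a grid with prescribed face velocities.
synthetic_field <- function(grid, u_val = 0, v_val = 0) {
  structure(list(u = matrix(u_val, grid$nx + 1L, grid$ny),
                 v = matrix(v_val, grid$nx, grid$ny + 1L),
                 p = matrix(0, grid$nx, grid$ny),
                 grid = grid, props = fluid_properties(),
                 kind = "steady"),
            class = "flow_field")
}

test_that("wall shear stress matches the Poiseuille closed form", {
  pz <- poiseuille_case()
  wt <- wall_shear_table(pz$field)
  tau_true <- 6 * 0.0035 * pz$U / pz$H
  expect_equal(mean(wt$tau), tau_true, tolerance = 0.05)
  ## dome-wall requirement on aneurysm grids
  expect_error(wall_shear_stress(pz$field), "dome-wall")
})

test_that("normalized WSS is scale-invariant in the Stokes regime and
           zero fields are flagged", {
  grid <- rasterize(make_geometry("sidewall"), 0.4)
  set <- solver_settings(steady_tolerance = 1e-6)
  f1 <- solve_steady(grid, fluid_properties(),
                     boundary_conditions(0.002), NULL, set)
  f2 <- solve_steady(grid, fluid_properties(),
                     boundary_conditions(0.004), NULL, set)
  w1 <- wall_shear_stress(f1); w2 <- wall_shear_stress(f2)
  expect_equal(w1$normalized_wss, w2$normalized_wss, tolerance = 0.05)
  ## zero field: wss 0, normalized reported 0 with flag
  z <- synthetic_field(grid)
  wz <- wall_shear_stress(z, grid, fluid_properties())
  expect_equal(wz$wss_dome, 0)
  expect_equal(wz$normalized_wss, 0)
  expect_equal(wz$flag, "zero-reference")
})

test_that("dome mean velocity is the volume-weighted cell-centre mean", {
  grid <- rasterize(make_geometry("sidewall"), 0.4)
  f <- synthetic_field(grid, u_val = 0.02)
  expect_equal(dome_mean_velocity(f, grid), 2.0)
  expect_equal(dome_mean_velocity(synthetic_field(grid), grid), 0)
  ## independent quadrature oracle over the dome cell list
  sw <- packing_sweep_case()
  fd <- sw$fields[[1]]
  dome <- which(sw$grid$flags == 2L, arr.ind = TRUE)
  nxg <- sw$grid$nx
  uc <- (fd$u[dome] + fd$u[cbind(dome[, 1] + 1L, dome[, 2])]) / 2
  vc <- (fd$v[dome] + fd$v[cbind(dome[, 1], dome[, 2] + 1L)]) / 2
  oracle <- mean(sqrt(uc^2 + vc^2)) * 100
  expect_equal(dome_mean_velocity(fd, sw$grid), oracle, tolerance = 1e-12)
})

test_that("neck zones split by the sign of the normal velocity", {
  grid <- rasterize(make_geometry("sidewall"), 0.4)
  na <- length(grid$neck_i) * grid$h * grid$slab_depth
  ## uniform upward flow through the whole neck
  up <- synthetic_field(grid, v_val = 0.03)
  nz <- neck_zone_analysis(up, grid)
  expect_equal(nz$inflow_area, na)
  expect_equal(nz$outflow_area, 0)
  expect_equal(nz$inflow_velocity, 3.0)
  ## antisymmetric half-up/half-down field
  f <- synthetic_field(grid)
  nn <- length(grid$neck_i)
  s <- 0.02
  f$v[cbind(grid$neck_i[seq_len(nn / 2)], grid$neck_j)] <- s
  f$v[cbind(grid$neck_i[(nn / 2 + 1):nn], grid$neck_j)] <- -s
  nz2 <- neck_zone_analysis(f, grid)
  expect_equal(nz2$inflow_area, na / 2)
  expect_equal(nz2$outflow_area, na / 2)
  expect_equal(nz2$inflow_velocity, 100 * s)
  expect_equal(nz2$outflow_velocity, 100 * s)
  ## all-zero: both zones empty, flagged
  expect_warning(nz0 <- neck_zone_analysis(synthetic_field(grid), grid),
                 "zero")
  expect_equal(nz0$inflow_area + nz0$outflow_area, 0)
  ## conservation through the neck of a converged control run (the dome
  ## is a closed incompressible cavity)
  sw <- packing_sweep_case()
  nzc <- neck_zone_analysis(sw$fields[[1]], sw$grid)
  expect_lt(abs(nzc$inflow_flux - nzc$outflow_flux) /
              max(nzc$inflow_flux, 1e-300), 1e-3)
})

test_that("RFV counts dome cells strictly above the speed threshold", {
  grid <- rasterize(make_geometry("sidewall"), 0.4)
  DV <- morphometrics(grid)$dome_volume
  f <- synthetic_field(grid, u_val = 0.02)    # 2 cm/s everywhere
  expect_equal(residual_flow_volume(f, grid, 1.0), DV)
  expect_equal(residual_flow_volume(f, grid, 5.0), 0)
  ## strict inequality at the threshold: speed == threshold is excluded
  f1 <- synthetic_field(grid, u_val = 0.01)
  expect_equal(residual_flow_volume(f1, grid, 1.0), 0)
  expect_error(residual_flow_volume(f, grid, -1), "positive")
  ## half above / half below
  fh <- synthetic_field(grid)
  dome <- which(grid$flags == 2L)
  sp <- matrix(0, grid$nx, grid$ny)
  half <- dome[seq_len(length(dome) %/% 2)]
  ## drive u on both faces of chosen cells (cells are dome-interior)
  di <- which(grid$flags == 2L, arr.ind = TRUE)
  hsel <- di[seq_len(nrow(di) %/% 2), , drop = FALSE]
  fh$u[hsel] <- 0.04; fh$u[cbind(hsel[, 1] + 1L, hsel[, 2])] <- 0.04
  got <- residual_flow_volume(fh, grid, 1.0)
  cellv <- grid$h^2 * grid$slab_depth
  ## every selected cell moves at >= 2 cm/s; neighbours of the block get
  ## half-speed faces, so allow the one-cell fringe
  expect_gte(got, nrow(hsel) * cellv)
  expect_lte(got, (nrow(hsel) + nrow(di)) * cellv / 1)
})

test_that("threshold scan is nonincreasing and consistent per threshold", {
  sw <- packing_sweep_case()
  f <- sw$fields[[1]]
  scan <- threshold_scan(f, sw$grid)
  expect_length(scan, 5L)
  expect_true(all(diff(scan) <= 0))
  for (k in seq_along(RFV_THRESHOLDS_CM_S))
    expect_identical(unname(scan[k]),
                     residual_flow_volume(f, sw$grid,
                                          RFV_THRESHOLDS_CM_S[k]))
  expect_error(threshold_scan(f, sw$grid, numeric(0)), "empty")
  expect_error(threshold_scan(f, sw$grid, c(1, -2)), "positive")
})

test_that("transient RFV reduces to the steady RFV for a constant waveform", {
  tc <- terminal_transient_case()
  r_st <- residual_flow_volume(tc$steady, tc$grid, 1.0)
  r_tr <- rfv_transient(tc$pulsatile, tc$grid, 1.0)
  expect_gt(r_st, 0)
  expect_equal(r_tr, r_st, tolerance = 0.01)
  ## an all-zero history gives zero
  fake <- tc$pulsatile
  fake$mean_speed <- matrix(0, tc$grid$nx, tc$grid$ny)
  expect_equal(rfv_transient(fake, tc$grid), 0)
  ## truncated cycle is rejected
  fake$complete <- FALSE
  expect_error(rfv_transient(fake, tc$grid), "full final cycle")
})

test_that("porous runs lower dome WSS and velocity below the control run", {
  sw <- packing_sweep_case()
  w <- vapply(sw$fields, function(f)
    wall_shear_stress(f, sw$grid)$wss_dome, numeric(1))
  v <- vapply(sw$fields, function(f)
    dome_mean_velocity(f, sw$grid), numeric(1))
  expect_true(all(w[-1] < w[1]))
  expect_true(all(v[-1] < v[1]))
})
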