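test_that("waveforms are periodic with mean one", {
  wc <- make_waveform("constant")
  expect_equal(waveform_scale(wc, c(0, 0.3, 5)), rep(1, 3))
  ws <- make_waveform("sine", period = 1, amplitude = 0.4)
  tt <- seq(0, 1, length.out = 4001)[-4001]
  sc <- waveform_scale(ws, tt)
  expect_equal(mean(sc), 1, tolerance = 1e-6)
  expect_equal(min(sc), 0.6, tolerance = 1e-3)
  expect_equal(max(sc), 1.4, tolerance = 1e-3)
  ## arbitrary positive table renormalized to mean 1 (trapezoid check)
  set.seed(2)
  tb <- data.frame(time = seq(0, 0.8, by = 0.1),
                   scale = runif(9, 0.3, 2.5))
  wt <- make_waveform("table", period = 0.9, table = tb)
  tt <- seq(0, 0.9, length.out = 20001)[-20001]
  expect_equal(mean(waveform_scale(wt, tt)), 1, tolerance = 1e-4)
  ## periodicity
  expect_equal(waveform_scale(wt, 0.25), waveform_scale(wt, 0.25 + 0.9))
  expect_error(make_waveform("table", table = NULL), "empty")
  expect_error(make_waveform("sine", period = -1), "positive")
  expect_error(make_waveform("table", period = 1,
                             table = data.frame(time = c(0, 0.2, 0.1),
                                                scale = 1:3)),
               "increasing")
})

test_that("steady channel flow reproduces plane Poiseuille", {
  pz <- poiseuille_case()
  sp <- cell_speed(pz$field)
  mid <- sp[pz$grid$nx %/% 2, ]
  expect_equal(max(mid), 1.5 * pz$U, tolerance = 0.02)
  ## global mass conservation
  fin <- inlet_flux(pz$field); fout <- outlet_flux(pz$field)
  expect_lt(abs(fin - fout) / fin, 1e-3)
  ## projection leaves fluid cells divergence-free
  expect_lt(max_divergence(pz$field), 1e-8 * pz$U / (pz$grid$h * 1e-3))
})

test_that("zero inlet velocity yields an identically zero field", {
  grid <- channel_grid(length = 8, height = 4, h = 0.4)
  f <- solve_steady(grid, fluid_properties(), boundary_conditions(0),
                    settings = solver_settings(steady_tolerance = 1e-6,
                                               ramp_steps = 5))
  expect_equal(max(abs(f$u)), 0)
  expect_equal(max(abs(f$v)), 0)
  expect_equal(max(abs(f$p)), 0)
})

test_that("velocity error decreases under grid refinement", {
  U <- 0.1; H <- 4e-3
  err <- vapply(c(0.5, 0.25), function(h) {
    grid <- channel_grid(length = 6, height = 4, h = h)
    f <- solve_steady(grid, fluid_properties(), boundary_conditions(U),
                      settings = solver_settings(steady_tolerance = 1e-6))
    ny <- grid$ny; nx <- grid$nx
    y <- (seq_len(ny) - 0.5) * h * 1e-3 + grid$y0 * 1e-3
    uex <- ifelse(y > 0 & y < H, 6 * U * (y / H) * (1 - y / H), 0)
    uc <- cell_speed(f)[nx %/% 2, ]
    sqrt(mean((uc - uex)^2))
  }, numeric(1))
  expect_lt(err[2], err[1] / 2)   # at least first order, near second
})

test_that("a homogeneous porous plug obeys the integrated Darcy balance", {
  pl <- plug_case()
  h <- pl$grid$h
  i0 <- round(4 / h); i1 <- round(12 / h)
  col_p <- function(i) {
    fl <- pl$grid$flags[i, ]
    mean(pl$field$p[i, fl == 1L | fl == 2L])
  }
  dp <- col_p(i0 - 3L) - col_p(i1 + 3L)
  K <- darcy_resistance(pl$pc, pl$U)
  expect_equal(dp, K * pl$U * pl$L, tolerance = 0.05)
  ## mass balance through the plug
  expect_lt(abs(inlet_flux(pl$field) - outlet_flux(pl$field)) /
              inlet_flux(pl$field), 1e-3)
})

test_that("a fully open coil (kappa = 1) reproduces the control run exactly", {
  grid <- rasterize(make_geometry("sidewall"), 0.4)
  bc <- boundary_conditions(0.15)
  set <- solver_settings(steady_tolerance = 1e-4)
  f0 <- solve_steady(grid, fluid_properties(), bc, NULL, set)
  f1 <- solve_steady(grid, fluid_properties(), bc,
                     porous_coefficients(kappa = 1), set)
  expect_identical(f0$u, f1$u)
  expect_identical(f0$v, f1$v)
  expect_identical(f0$p, f1$p)
})

test_that("dome damping grows monotonically as the bed closes", {
  sw <- packing_sweep_case()
  vel <- vapply(sw$fields, function(f) dome_mean_velocity(f, sw$grid),
                numeric(1))
  expect_true(all(diff(vel) < 0))
})

test_that("pulsatile runs conserve the waveform flux bookkeeping", {
  tc <- terminal_transient_case()
  ## constant waveform: final-cycle time-mean field matches steady
  expect_lt(max(abs(tc$pulsatile$mean_speed - cell_speed(tc$steady))),
            0.01 * tc$U)
  ## cycle-2 mean inlet flux equals the steady (mean) inlet flux
  target <- inlet_flux(tc$steady)
  expect_equal(tc$pulsatile$inlet_flux_per_cycle[2], target,
               tolerance = 5e-3)
  ## sine waveform keeps the cycle-mean flux at the waveform mean
  bc_sin <- boundary_conditions(tc$U, make_waveform("sine",
                                                    period = tc$period,
                                                    amplitude = 0.4))
  set <- tc$settings; set$time_step <- 2e-4
  ps <- solve_pulsatile(tc$grid, tc$props, bc_sin, tc$pc, set)
  expect_equal(ps$inlet_flux_per_cycle[2], target, tolerance = 5e-3)
  ## periodicity: one extra cycle changes the final-cycle mean dome
  ## speed by well under 1%
  set1 <- set; set1$n_cycles <- 1
  ps1 <- solve_pulsatile(tc$grid, tc$props, bc_sin, tc$pc, set1)
  dome <- tc$grid$flags == 2L
  m1 <- mean(ps1$mean_speed[dome]); m2 <- mean(ps$mean_speed[dome])
  expect_lt(abs(m2 - m1) / max(m2, 1e-12), 0.01)
})

test_that("an unstable pulsatile time step is rejected with a suggestion", {
  grid <- rasterize(make_geometry("sidewall"), 0.4)
  bc <- boundary_conditions(0.25, make_waveform("constant", period = 0.3))
  expect_error(
    solve_pulsatile(grid, fluid_properties(), bc, NULL,
                    solver_settings(time_step = 0.05)),
    "CFL violation.*time_step <=")
})

test_that("non-convergence raises an error carrying the residual", {
  grid <- channel_grid(length = 8, height = 4, h = 0.4)
  err <- tryCatch(
    solve_steady(grid, fluid_properties(), boundary_conditions(0.1),
                 settings = solver_settings(steady_tolerance = 1e-12,
                                            max_iterations = 30L)),
    error = function(e) e)
  expect_s3_class(err, "coilflow_no_convergence")
  expect_true(is.finite(err$residual))
})
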