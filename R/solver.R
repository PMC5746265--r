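#' Fluid properties
#'
#' @param rho density (kg/m^3), default blood (1056).
#' @param mu dynamic viscosity (Pa s), default blood (0.0035).
#' @param body_force constant body acceleration `c(Fx, Fy)` (m/s^2),
#'   default zero (gravity off).
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = BLOOD_RHO, mu = BLOOD_MU,
                             body_force = c(0, 0)) {
  if (rho <= 0 || mu <= 0) stop("rho and mu must be positive")
  structure(list(rho = rho, mu = mu, body_force = body_force),
            class = "fluid_properties")
}

#' Inlet waveform
#'
#' Periodic, mean-one scale series multiplying the mean inlet velocity.
#' `constant` gives scale 1 everywhere; `sine` gives
#' `1 + amplitude * sin(2 pi t / period)`; `table` interpolates user
#' samples periodically and renormalizes them so the period mean is 1
#' (to within 1e-6).
#'
#' @param kind `"constant"`, `"sine"` or `"table"`.
#' @param period cycle length (s), default 0.9 (a resting heart beat).
#' @param amplitude relative amplitude of the sine, default 0.4.
#' @param table data.frame/matrix with columns time (s, strictly
#'   increasing, within one period) and scale (> 0).
#' @return object of class `waveform`.
#' @export
make_waveform <- function(kind = c("constant", "sine", "table"),
                          period = 0.9, amplitude = 0.4, table = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(period) || period <= 0) stop("period must be positive")
  w <- list(kind = kind, period = period, amplitude = amplitude,
            table = NULL)
  if (kind == "table") {
    if (is.null(table) || NROW(table) == 0L) stop("empty waveform table")
    tb <- as.data.frame(table)
    names(tb)[1:2] <- c("time", "scale")
    if (any(diff(tb$time) <= 0))
      stop("waveform table times must be strictly increasing")
    if (max(tb$time) > period) stop("waveform table exceeds one period")
    if (any(tb$scale < 0)) stop("waveform scales must be nonnegative")
    w$table <- tb
    ## renormalize so the trapezoid mean over one period equals 1
    m <- waveform_mean_raw(w)
    if (m <= 0) stop("waveform mean must be positive")
    w$table$scale <- tb$scale / m
  }
  class(w) <- "waveform"
  w
}

waveform_mean_raw <- function(w) {
  tt <- seq(0, w$period, length.out = 2001L)
  mean(waveform_scale_raw(w, tt[-length(tt)]))
}

waveform_scale_raw <- function(w, t) {
  tm <- t %% w$period
  switch(w$kind,
         constant = rep(1, length(t)),
         sine = 1 + w$amplitude * sin(2 * pi * tm / w$period),
         table = {
           tb <- w$table
           ## periodic wrap: append first sample shifted by one period
           tx <- c(tb$time, tb$time[1] + w$period)
           sx <- c(tb$scale, tb$scale[1])
           tw <- ifelse(tm < tb$time[1], tm + w$period, tm)
           approx(tx, sx, xout = tw, rule = 2)$y
         })
}

#' Evaluate a waveform scale factor
#' @param w a [make_waveform()] object.
#' @param t time(s) in seconds; vectorized.
#' @return scale factor(s), period mean 1.
#' @export
waveform_scale <- function(w, t) {
  stopifnot(inherits(w, "waveform"))
  waveform_scale_raw(w, t)
}

#' Inlet/outlet boundary conditions
#'
#' No-slip walls and traction-free outlets are implied; this object fixes
#' the inlet forcing: a fully developed (parabolic) or flat profile with
#' the given mean speed, modulated in time by a mean-one waveform.
#'
#' @param inlet_mean_velocity mean inlet speed (m/s).
#' @param waveform a [make_waveform()] object (default constant).
#' @param profile `"parabolic"` (fully developed laminar, default) or
#'   `"flat"`.
#' @return object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(inlet_mean_velocity,
                                waveform = make_waveform("constant"),
                                profile = c("parabolic", "flat")) {
  profile <- match.arg(profile)
  if (!is.numeric(inlet_mean_velocity) || inlet_mean_velocity < 0)
    stop("inlet_mean_velocity must be nonnegative")
  stopifnot(inherits(waveform, "waveform"))
  structure(list(inlet_mean_velocity = inlet_mean_velocity,
                 waveform = waveform, profile = profile),
            class = "boundary_conditions")
}

#' Solver settings
#'
#' @param time_step pulsatile time step (s), default 1e-4.
#' @param n_cycles number of pulsatile cycles, default 2 (only the final
#'   cycle feeds the transient statistics).
#' @param steady_tolerance relative steady residual, default 1e-6.
#' @param max_iterations pseudo-time iteration cap for the steady solver.
#' @param under_relaxation reserved knob (the marching scheme does not
#'   need it); kept for config compatibility.
#' @param scheme convection scheme, `"upwind"` (default) or `"central"`.
#' @param cfl_safety CFL safety factor in (0, 1).
#' @param ramp_steps inlet ramp-up steps for the steady march.
#' @param n_save_per_cycle pulsatile snapshots kept per cycle.
#' @param init_tolerance steady tolerance used to initialize a pulsatile
#'   run from the mean-flow solution.
#' @param seed reserved (the solver is deterministic).
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(time_step = 1e-4, n_cycles = 2,
                            steady_tolerance = 1e-6,
                            max_iterations = 50000L,
                            under_relaxation = 1,
                            scheme = c("upwind", "central"),
                            cfl_safety = 0.4, ramp_steps = 200L,
                            n_save_per_cycle = 8L,
                            init_tolerance = 1e-4, seed = NULL) {
  scheme <- match.arg(scheme)
  if (time_step <= 0) stop("time_step must be positive")
  if (steady_tolerance <= 0 || steady_tolerance >= 1)
    stop("steady_tolerance must lie in (0, 1)")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  structure(list(time_step = time_step, n_cycles = n_cycles,
                 steady_tolerance = steady_tolerance,
                 max_iterations = as.integer(max_iterations),
                 under_relaxation = under_relaxation, scheme = scheme,
                 cfl_safety = cfl_safety,
                 ramp_steps = as.integer(ramp_steps),
                 n_save_per_cycle = as.integer(n_save_per_cycle),
                 init_tolerance = init_tolerance, seed = seed),
            class = "solver_settings")
}

## ---------------------------------------------------------------------
## Internal: precompute all index vectors + the pressure Poisson operator
## for a grid.  Velocities live on faces (MAC arrangement): u on vertical
## faces (nx+1 x ny), v on horizontal faces (nx x ny+1), p on cells.
## ---------------------------------------------------------------------
solver_setup <- function(grid, props, bc, porous, settings) {
  nx <- grid$nx; ny <- grid$ny
  hm <- grid$h * 1e-3                       # cell size in metres
  flags <- grid$flags
  fluid <- flags == FLAG_LUMEN | flags == FLAG_DOME
  dome  <- flags == FLAG_DOME

  uidx <- function(i, j) i + (j - 1L) * (nx + 1L)
  vidx <- function(i, j) i + (j - 1L) * nx
  pidx <- function(i, j) i + (j - 1L) * nx

  ## --- face states -----------------------------------------------------
  US <- matrix(0L, nx + 1L, ny)             # 0 fixed-zero, 1 unknown,
  VS <- matrix(0L, nx, ny + 1L)             # 2 inlet, 3 outlet
  US[2:nx, ] <- (fluid[1:(nx - 1), ] & fluid[2:nx, ]) * 1L
  VS[, 2:ny] <- (fluid[, 1:(ny - 1)] & fluid[, 2:ny]) * 1L
  inlet <- grid$inlet
  for (o in grid$outlet) {
    if (o$side == "right") US[nx + 1L, o$j] <- 3L
    if (o$side == "left")  US[1L, o$j] <- 3L
  }
  if (inlet$side == "left")   US[1L, inlet$j] <- 2L
  if (inlet$side == "bottom") VS[inlet$i, 1L] <- 2L

  ## --- inlet profile (discrete mean renormalized to the target mean) ---
  if (inlet$side == "left") {
    js <- inlet$j
    yc <- grid$y0 + (js - 0.5) * grid$h
    span <- length(js) * grid$h
    ymid <- (min(yc) - grid$h / 2 + max(yc) + grid$h / 2) / 2
    xi <- 2 * (yc - ymid) / span
    prof <- if (bc$profile == "parabolic") 1.5 * (1 - xi^2) else rep(1, length(js))
    prof <- prof / mean(prof)
    inlet_faces <- uidx(1L, js)
  } else {
    is <- inlet$i
    xc <- grid$x0 + (is - 0.5) * grid$h
    span <- length(is) * grid$h
    xmid <- (min(xc) - grid$h / 2 + max(xc) + grid$h / 2) / 2
    xi <- 2 * (xc - xmid) / span
    prof <- if (bc$profile == "parabolic") 1.5 * (1 - xi^2) else rep(1, length(is))
    prof <- prof / mean(prof)
    inlet_faces <- vidx(is, 1L)
  }
  inlet_prof <- prof * bc$inlet_mean_velocity

  ## --- u unknowns ------------------------------------------------------
  uw <- which(US == 1L, arr.ind = TRUE)
  ui <- uw[, 1]; uj <- uw[, 2]
  U <- list(self = uidx(ui, uj),
            xm = uidx(ui - 1L, uj), xp = uidx(ui + 1L, uj))
  upA <- US[cbind(ui, pmin(uj + 1L, ny))] > 0L & uj < ny
  dnA <- US[cbind(ui, pmax(uj - 1L, 1L))] > 0L & uj > 1L
  U$upI <- ifelse(upA, uidx(ui, uj + 1L), U$self)
  U$upC <- ifelse(upA, 1, -1)
  U$dnI <- ifelse(dnA, uidx(ui, uj - 1L), U$self)
  U$dnC <- ifelse(dnA, 1, -1)
  U$va <- vidx(ui - 1L, uj); U$vb <- vidx(ui - 1L, uj + 1L)
  U$vc <- vidx(ui, uj);      U$vd <- vidx(ui, uj + 1L)
  U$pL <- pidx(ui - 1L, uj); U$pR <- pidx(ui, uj)
  U$pf <- (dome[cbind(ui - 1L, uj)] + dome[cbind(ui, uj)]) / 2

  ## --- v unknowns ------------------------------------------------------
  vw <- which(VS == 1L, arr.ind = TRUE)
  vi <- vw[, 1]; vj <- vw[, 2]
  V <- list(self = vidx(vi, vj),
            ym = vidx(vi, vj - 1L), yp = vidx(vi, vj + 1L))
  rgA <- VS[cbind(pmin(vi + 1L, nx), vj)] > 0L & vi < nx
  lfA <- VS[cbind(pmax(vi - 1L, 1L), vj)] > 0L & vi > 1L
  V$rgI <- ifelse(rgA, vidx(vi + 1L, vj), V$self)
  V$rgC <- ifelse(rgA, 1, -1)
  V$lfI <- ifelse(lfA, vidx(vi - 1L, vj), V$self)
  V$lfC <- ifelse(lfA, 1, -1)
  V$ua <- uidx(vi, vj - 1L); V$ub <- uidx(vi + 1L, vj - 1L)
  V$uc <- uidx(vi, vj);      V$ud <- uidx(vi + 1L, vj)
  V$pB <- pidx(vi, vj - 1L); V$pT <- pidx(vi, vj)
  V$pf <- (dome[cbind(vi, vj - 1L)] + dome[cbind(vi, vj)]) / 2

  ## --- outlet faces ----------------------------------------------------
  OUT <- list(idx = integer(0), nb = integer(0), p = integer(0),
              sgn = numeric(0))
  for (o in grid$outlet) {
    if (o$side == "right") {
      OUT$idx <- c(OUT$idx, uidx(nx + 1L, o$j))
      OUT$nb  <- c(OUT$nb,  uidx(nx, o$j))
      OUT$p   <- c(OUT$p,   pidx(nx, o$j))
      OUT$sgn <- c(OUT$sgn, rep(+1, length(o$j)))
    } else if (o$side == "left") {
      OUT$idx <- c(OUT$idx, uidx(1L, o$j))
      OUT$nb  <- c(OUT$nb,  uidx(2L, o$j))
      OUT$p   <- c(OUT$p,   pidx(1L, o$j))
      OUT$sgn <- c(OUT$sgn, rep(-1, length(o$j)))
    }
  }

  ## --- fluid cells and the Poisson operator ----------------------------
  fc <- which(fluid, arr.ind = TRUE)
  ci <- fc[, 1]; cj <- fc[, 2]
  cell_of <- matrix(NA_integer_, nx, ny)
  cell_of[fc] <- seq_len(nrow(fc))
  C <- list(lin = pidx(ci, cj),
            uW = uidx(ci, cj), uE = uidx(ci + 1L, cj),
            vS = vidx(ci, cj), vN = vidx(ci, cj + 1L))
  ## assemble A = -Laplacian (SPD thanks to the outlet Dirichlet faces)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  diag_x <- numeric(nrow(fc))
  add_nb <- function(di, dj, fstate) {
    ni <- ci + di; nj <- cj + dj
    ok <- ni >= 1L & ni <= nx & nj >= 1L & nj <= ny
    nb <- rep(NA_integer_, length(ci))
    nb[ok] <- cell_of[cbind(ni[ok], nj[ok])]
    has <- !is.na(nb)
    trip_i <<- c(trip_i, which(has)); trip_j <<- c(trip_j, nb[has])
    trip_x <<- c(trip_x, rep(-1, sum(has)))
    diag_x[has] <<- diag_x[has] + 1
  }
  add_nb(1L, 0L); add_nb(-1L, 0L); add_nb(0L, 1L); add_nb(0L, -1L)
  ## outlet Dirichlet ghost (p = 0 on the open face) strengthens the diag
  if (length(OUT$p)) {
    k <- cell_of[matrix(c((OUT$p - 1L) %% nx + 1L,
                          (OUT$p - 1L) %/% nx + 1L), ncol = 2)]
    for (kk in k) diag_x[kk] <- diag_x[kk] + 2
  }
  A <- Matrix::sparseMatrix(
    i = c(trip_i, seq_len(nrow(fc))), j = c(trip_j, seq_len(nrow(fc))),
    x = c(trip_x, diag_x) / hm^2, dims = rep(nrow(fc), 2), symmetric = FALSE)
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  chol <- Matrix::Cholesky(A, LDL = FALSE)

  list(nx = nx, ny = ny, hm = hm, nu = props$mu / props$rho,
       rho = props$rho, F = props$body_force,
       fluid = fluid, dome = dome, US = US, VS = VS,
       U = U, V = V, C = C, OUT = OUT, chol = chol,
       inlet_faces = inlet_faces, inlet_prof = inlet_prof,
       inlet_side = inlet$side,
       has_porous = !is.null(porous) && porous$kappa < 1,
       alpha = if (is.null(porous)) 0 else porous$alpha,
       beta = if (is.null(porous)) 0 else porous$beta,
       scheme = settings$scheme)
}

## One explicit predictor + porous sink + pressure projection step.
## st: setup list; u, v, p: current matrices; dt: step; scale: inlet scale.
## Returns list(u, v, p).
solver_step <- function(st, u, v, p, dt, scale) {
  hm <- st$hm; nu <- st$nu; rho <- st$rho
  U <- st$U; V <- st$V

  ## inlet values for this step
  if (st$inlet_side == "left") u[st$inlet_faces] <- st$inlet_prof * scale
  else v[st$inlet_faces] <- st$inlet_prof * scale

  ## ---- u predictor ----
  us <- u[U$self]
  uxm <- u[U$xm]; uxp <- u[U$xp]
  uup <- U$upC * u[U$upI]; udn <- U$dnC * u[U$dnI]
  vav <- 0.25 * (v[U$va] + v[U$vb] + v[U$vc] + v[U$vd])
  if (st$scheme == "upwind") {
    dudx <- ifelse(us > 0, (us - uxm), (uxp - us)) / hm
    dudy <- ifelse(vav > 0, (us - udn), (uup - us)) / hm
  } else {
    dudx <- (uxp - uxm) / (2 * hm)
    dudy <- (uup - udn) / (2 * hm)
  }
  lap_u <- (uxp - 2 * us + uxm + uup - 2 * us + udn) / hm^2
  dpdx <- (p[U$pR] - p[U$pL]) / hm
  ustar <- us + dt * (-(us * dudx + vav * dudy) + nu * lap_u -
                        dpdx / rho + st$F[1])
  if (st$has_porous) {
    w <- U$pf > 0
    if (any(w)) {
      sp <- sqrt(us[w]^2 + vav[w]^2)
      K <- st$alpha * sp + st$beta
      ustar[w] <- ustar[w] / (1 + dt * U$pf[w] * K / rho)
    }
  }

  ## ---- v predictor ----
  vs <- v[V$self]
  vym <- v[V$ym]; vyp <- v[V$yp]
  vrg <- V$rgC * v[V$rgI]; vlf <- V$lfC * v[V$lfI]
  uav <- 0.25 * (u[V$ua] + u[V$ub] + u[V$uc] + u[V$ud])
  if (st$scheme == "upwind") {
    dvdy <- ifelse(vs > 0, (vs - vym), (vyp - vs)) / hm
    dvdx <- ifelse(uav > 0, (vs - vlf), (vrg - vs)) / hm
  } else {
    dvdy <- (vyp - vym) / (2 * hm)
    dvdx <- (vrg - vlf) / (2 * hm)
  }
  lap_v <- (vyp - 2 * vs + vym + vrg - 2 * vs + vlf) / hm^2
  dpdy <- (p[V$pT] - p[V$pB]) / hm
  vstar <- vs + dt * (-(uav * dvdx + vs * dvdy) + nu * lap_v -
                        dpdy / rho + st$F[2])
  if (st$has_porous) {
    w <- V$pf > 0
    if (any(w)) {
      sp <- sqrt(vs[w]^2 + uav[w]^2)
      K <- st$alpha * sp + st$beta
      vstar[w] <- vstar[w] / (1 + dt * V$pf[w] * K / rho)
    }
  }

  u[U$self] <- ustar
  v[V$self] <- vstar
  ## outlet: zero-gradient convective copy before projection
  if (length(st$OUT$idx)) u[st$OUT$idx] <- u[st$OUT$nb]

  ## ---- projection ----
  div <- (u[st$C$uE] - u[st$C$uW] + v[st$C$vN] - v[st$C$vS]) / hm
  phi <- as.numeric(Matrix::solve(st$chol, -(rho / dt) * div))
  phim <- matrix(0, st$nx, st$ny)
  phim[st$C$lin] <- phi
  u[U$self] <- u[U$self] - (dt / rho) * (phim[U$pR] - phim[U$pL]) / hm
  v[V$self] <- v[V$self] - (dt / rho) * (phim[V$pT] - phim[V$pB]) / hm
  if (length(st$OUT$idx))
    u[st$OUT$idx] <- u[st$OUT$idx] +
      st$OUT$sgn * 2 * (dt / rho) * phim[st$OUT$p] / hm
  p[st$C$lin] <- p[st$C$lin] + phi
  list(u = u, v = v, p = p)
}

## Initial guess: extend the inlet profile through the parent vessel.
solver_init <- function(grid, st) {
  nx <- grid$nx; ny <- grid$ny
  u <- matrix(0, nx + 1L, ny); v <- matrix(0, nx, ny + 1L)
  p <- matrix(0, nx, ny)
  if (st$inlet_side == "left") {
    js <- grid$inlet$j
    for (k in seq_along(js)) {
      j <- js[k]
      row_ok <- st$US[, j] %in% c(1L, 3L)
      u[row_ok, j] <- st$inlet_prof[k]
    }
    ## keep only faces whose whole row is vessel lumen (not dome)
    dome_rows <- which(apply(st$dome, 2, any))
    if (length(dome_rows)) u[, dome_rows] <- 0
  }
  list(u = u, v = v, p = p)
}

stable_dt <- function(st, vmax, safety) {
  safety / (max(vmax, 1e-9) / st$hm + 4 * st$nu / st$hm^2)
}

#' Solve steady flow
#'
#' Marches the incompressible momentum equations in pseudo-time (explicit
#' upwind convection and diffusion, incremental pressure projection with a
#' cached sparse Cholesky) to a steady state.  With `porous` supplied, the
#' dome cells carry the Brinkman-type momentum sink `-(K(|v|)/rho) v` with
#' `K = alpha |v| + beta`, i.e. a single unified Navier-Stokes-Brinkman
#' system; when the sink dominates, the dome obeys the Darcy balance
#' `0 = -grad p - K v`.  `porous = NULL` gives the untreated ("control")
#' aneurysm.
#'
#' @param grid a [rasterize()]d grid (or [channel_grid()]).
#' @param props [fluid_properties()].
#' @param bc [boundary_conditions()]; the steady inlet speed is the mean
#'   velocity (waveform ignored).
#' @param porous [porous_coefficients()] or `NULL`.
#' @param settings [solver_settings()].
#' @return object of class `flow_field` with staggered `u`, `v` (m/s),
#'   cell pressures `p` (Pa), convergence metadata.
#' @export
solve_steady <- function(grid, props = fluid_properties(), bc,
                         porous = NULL, settings = solver_settings()) {
  stopifnot(inherits(grid, "flow_grid"), inherits(bc, "boundary_conditions"))
  st <- solver_setup(grid, props, bc, porous, settings)
  Re <- props$rho * bc$inlet_mean_velocity *
    (length(st$inlet_prof) * st$hm) / props$mu
  if (Re > 2000)
    warning(sprintf("inlet Reynolds number %.0f > 2000: laminar assumption questionable", Re))
  f <- solver_init(grid, st)
  u <- f$u; v <- f$v; p <- f$p
  Uref <- max(bc$inlet_mean_velocity, 1e-12)
  vmax_est <- max(3 * bc$inlet_mean_velocity, 1e-6)
  dt <- stable_dt(st, vmax_est, settings$cfl_safety)
  tol <- settings$steady_tolerance
  ramp <- max(1L, settings$ramp_steps)
  res <- Inf; it <- 0L
  while (it < settings$max_iterations) {
    it <- it + 1L
    scale <- min(1, it / ramp)
    u0 <- u; v0 <- v
    f <- solver_step(st, u, v, p, dt, scale)
    u <- f$u; v <- f$v; p <- f$p
    if (!all(is.finite(u[st$U$self])))
      stop("steady solve diverged (non-finite velocities)")
    res <- max(max(abs(u - u0)), max(abs(v - v0))) / (dt * Uref)
    if (it > ramp && res <= tol) break
    if (it %% 25L == 0L) {
      vmax <- max(abs(u), abs(v), 1e-9)
      dtn <- stable_dt(st, 1.2 * vmax, settings$cfl_safety)
      if (dtn < dt / 1.2 || dtn > dt * 2) dt <- dtn
    }
  }
  if (res > tol) {
    cond <- simpleError(sprintf(
      "steady solve did not converge in %d iterations (residual %.3e > %.3e)",
      settings$max_iterations, res, tol))
    class(cond) <- c("coilflow_no_convergence", class(cond))
    cond$residual <- res
    stop(cond)
  }
  structure(list(u = u, v = v, p = p, grid = grid, props = props, bc = bc,
                 porous = porous, converged = TRUE, iterations = it,
                 residual = res, dt = dt, kind = "steady"),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field (%s): %d iterations, residual %.2e, max speed %.4f m/s\n",
              x$kind, x$iterations, x$residual,
              max(abs(x$u), abs(x$v))))
  invisible(x)
}

#' Solve pulsatile flow
#'
#' Time-accurate run at `settings$time_step` over `settings$n_cycles`
#' waveform periods, initialized from the steady solution at the mean
#' inlet rate.  Only the final cycle feeds the transient statistics: its
#' per-cell time-mean speed is accumulated for [rfv_transient()].
#'
#' @inheritParams solve_steady
#' @return object of class `pulsatile_flow`: snapshot list, per-cell
#'   final-cycle mean speed matrix (m/s), inlet flux bookkeeping, and the
#'   final instantaneous field.
#' @export
solve_pulsatile <- function(grid, props = fluid_properties(), bc,
                            porous = NULL, settings = solver_settings()) {
  stopifnot(inherits(grid, "flow_grid"), inherits(bc, "boundary_conditions"))
  wf <- bc$waveform
  st <- solver_setup(grid, props, bc, porous, settings)
  dt <- settings$time_step
  smax <- max(waveform_scale(wf, seq(0, wf$period, length.out = 501L)))
  vmax_est <- max(3 * bc$inlet_mean_velocity * smax, 1e-6)
  dt_max <- stable_dt(st, vmax_est, 0.5)
  if (dt > dt_max)
    stop(sprintf(
      "CFL violation: time_step %.3e s unstable at this resolution; use time_step <= %.3e s",
      dt, dt_max))
  init_set <- settings
  init_set$steady_tolerance <- settings$init_tolerance
  f <- solve_steady(grid, props, bc, porous, init_set)
  u <- f$u; v <- f$v; p <- f$p

  nper <- max(2L, round(wf$period / dt))
  nstep <- nper * settings$n_cycles
  save_every <- max(1L, nper %/% settings$n_save_per_cycle)
  snapshots <- list(); times <- numeric(0)
  mean_speed <- matrix(0, grid$nx, grid$ny)
  infl <- numeric(settings$n_cycles)
  hm <- st$hm
  depth_m <- grid$slab_depth * 1e-3
  for (k in seq_len(nstep)) {
    t <- k * dt
    scale <- waveform_scale(wf, t)
    f <- solver_step(st, u, v, p, dt, scale)
    u <- f$u; v <- f$v; p <- f$p
    if (!all(is.finite(u[st$U$self])))
      stop("pulsatile solve diverged (non-finite velocities)")
    cyc <- (k - 1L) %/% nper + 1L
    if (st$inlet_side == "left")
      infl[cyc] <- infl[cyc] + sum(u[st$inlet_faces]) * hm * depth_m
    else
      infl[cyc] <- infl[cyc] + sum(v[st$inlet_faces]) * hm * depth_m
    if (cyc == settings$n_cycles)
      mean_speed <- mean_speed + cell_speed_uv(u, v, grid)
    if (k %% save_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <-
        list(u = u, v = v, p = p, t = t)
      times <- c(times, t)
    }
  }
  structure(list(snapshots = snapshots, times = times,
                 mean_speed = mean_speed / nper,
                 inlet_flux_per_cycle = infl / nper,
                 final = structure(
                   list(u = u, v = v, p = p, grid = grid, props = props,
                        bc = bc, porous = porous, converged = TRUE,
                        iterations = nstep, residual = NA_real_,
                        dt = dt, kind = "pulsatile"),
                   class = "flow_field"),
                 grid = grid, waveform = wf, dt = dt,
                 n_cycles = settings$n_cycles, steps_per_cycle = nper,
                 complete = TRUE),
            class = "pulsatile_flow")
}

#' @export
print.pulsatile_flow <- function(x, ...) {
  cat(sprintf(
    "pulsatile_flow: %d cycles x %d steps (dt = %.2e s), %d snapshots\n",
    x$n_cycles, x$steps_per_cycle, x$dt, length(x$snapshots)))
  invisible(x)
}

## Cell-centred speed magnitude from staggered components (m/s).
cell_speed_uv <- function(u, v, grid) {
  nx <- grid$nx; ny <- grid$ny
  uc <- (u[1:nx, , drop = FALSE] + u[2:(nx + 1), , drop = FALSE]) / 2
  vc <- (v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1), drop = FALSE]) / 2
  sqrt(uc^2 + vc^2)
}

#' Cell-centred speed field
#' @param field a `flow_field`.
#' @return matrix (nx x ny) of speed magnitudes (m/s).
#' @export
cell_speed <- function(field) {
  cell_speed_uv(field$u, field$v, field$grid)
}

#' Inlet and outlet volumetric flux
#'
#' @param field a `flow_field`.
#' @return flux in m^3/s (2D flux times slab depth).
#' @export
inlet_flux <- function(field) {
  g <- field$grid; hm <- g$h * 1e-3; depth <- g$slab_depth * 1e-3
  if (g$inlet$side == "left")
    sum(field$u[1, g$inlet$j]) * hm * depth
  else
    sum(field$v[g$inlet$i, 1]) * hm * depth
}

#' @rdname inlet_flux
#' @export
outlet_flux <- function(field) {
  g <- field$grid; hm <- g$h * 1e-3; depth <- g$slab_depth * 1e-3
  tot <- 0
  for (o in g$outlet) {
    if (o$side == "right") tot <- tot + sum(field$u[g$nx + 1, o$j]) * hm * depth
    if (o$side == "left")  tot <- tot - sum(field$u[1, o$j]) * hm * depth
  }
  tot
}

#' Maximum divergence of a field (continuity check)
#' @param field a `flow_field`.
#' @return maximum absolute discrete divergence over fluid cells (1/s).
#' @export
max_divergence <- function(field) {
  g <- field$grid; hm <- g$h * 1e-3
  fluid <- g$flags == FLAG_LUMEN | g$flags == FLAG_DOME
  fc <- which(fluid, arr.ind = TRUE)
  nx <- g$nx
  uE <- field$u[cbind(fc[, 1] + 1L, fc[, 2])]
  uW <- field$u[fc]
  vN <- field$v[cbind(fc[, 1], fc[, 2] + 1L)]
  vS <- field$v[fc]
  max(abs(uE - uW + vN - vS) / hm)
}
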