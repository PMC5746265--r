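## Independent oracles (hand enumeration / brute force) and shared,
## lazily solved flow fixtures.

## ---- memoized fixtures ------------------------------------------------
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

## Plane Poiseuille channel solved at h = H/20 (verification workhorse)
poiseuille_case <- function() fixture("poiseuille", function() {
  grid <- channel_grid(length = 12, height = 4, h = 0.2)
  bc <- boundary_conditions(0.1)
  field <- solve_steady(grid, fluid_properties(), bc,
                        settings = solver_settings(steady_tolerance = 1e-6))
  list(grid = grid, field = field, U = 0.1, H = 4e-3)
})

## Porous plug channel (Darcy balance verification)
plug_case <- function() fixture("plug", function() {
  grid <- channel_grid(length = 16, height = 4, h = 0.2,
                       porous_x = c(4, 12))
  pc <- porous_coefficients(kappa = 0.7)
  bc <- boundary_conditions(0.05)
  field <- solve_steady(grid, fluid_properties(), bc, porous = pc,
                        settings = solver_settings(steady_tolerance = 1e-6))
  list(grid = grid, field = field, pc = pc, U = 0.05, L = 8e-3)
})

## Fixed sidewall aneurysm swept over packing density (coarse grid)
packing_sweep_case <- function() fixture("sweep", function() {
  grid <- rasterize(make_geometry("sidewall"), h = 0.4)
  bc <- boundary_conditions(0.25)
  set <- solver_settings(steady_tolerance = 1e-5)
  packings <- c(0, 10, 20, 30, 40)
  fields <- lapply(packings, function(pd) {
    por <- if (pd > 0) porous_coefficients(packing = pd) else NULL
    solve_steady(grid, fluid_properties(), bc, por, set)
  })
  list(grid = grid, packings = packings, fields = fields)
})

## Terminal aneurysm, porous, steady + constant-waveform pulsatile
terminal_transient_case <- function() fixture("terminal_trans", function() {
  grid <- rasterize(make_geometry("terminal", vessel_diameter = 3,
                                  dome_diameter = 10, neck_width = 6),
                    h = 0.5)
  pc <- porous_coefficients(packing = 20)
  props <- fluid_properties()
  set <- solver_settings(time_step = 2e-4, n_cycles = 2,
                         steady_tolerance = 1e-5, init_tolerance = 1e-5)
  bc_st <- boundary_conditions(0.25)
  steady <- solve_steady(grid, props, bc_st, pc, set)
  bc_pw <- boundary_conditions(0.25, make_waveform("constant",
                                                   period = 0.3))
  pulsatile <- solve_pulsatile(grid, props, bc_pw, pc, set)
  list(grid = grid, pc = pc, steady = steady, pulsatile = pulsatile,
       U = 0.25, period = 0.3, settings = set, props = props)
})

## ---- Mann-Whitney exact null enumeration ------------------------------
## U distribution over all C(n1+n2, n1) rank assignments (no ties).
mwu_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx)
    sum(sort(r)[idx]) - n1 * (n1 + 1) / 2)
  ## ranks are 1..N so sort(r)[idx] = idx
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

## ---- Fisher 2x2 exact enumeration (hypergeometric) --------------------
fisher_enum_p <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## ---- AUC by brute-force pair counting ---------------------------------
auc_brute <- function(scores, labels) {
  y <- as.integer(labels == 1 | labels == levels(factor(labels))[2])
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
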