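#' Idealized aneurysm geometry
#'
#' Parametric stand-in for a patient-specific aneurysm surface.  Two
#' configurations are supported: a `sidewall` aneurysm (circular dome
#' sitting on one wall of a straight parent vessel, opening through a neck
#' gap) and a `terminal` aneurysm (dome on the far wall of a symmetric
#' T-junction, one inlet stem and two outlet branches).  The model is
#' planar; `slab_depth` is the declared out-of-plane depth used to convert
#' areas to volumes (mm^2 -> mm^3) and lengths to areas.
#'
#' Coordinates: the neck midpoint is the origin, the neck segment lies on
#' `y = 0`, and the dome occupies `y > 0`.
#'
#' @param configuration `"sidewall"` or `"terminal"`.
#' @param vessel_diameter parent vessel diameter (mm).
#' @param dome_diameter dome diameter (mm); must be >= `neck_width`.
#' @param neck_width neck gap width (mm).
#' @param inlet_length,outlet_length straight vessel lengths upstream and
#'   downstream of the neck (mm).
#' @param slab_depth out-of-plane depth (mm), default 1.
#' @return object of class `aneurysm_geometry`.
#' @examples
#' geom <- make_geometry("sidewall", vessel_diameter = 4,
#'                       dome_diameter = 8, neck_width = 4)
#' @export
make_geometry <- function(configuration = c("sidewall", "terminal"),
                          vessel_diameter = 4, dome_diameter = 8,
                          neck_width = 4, inlet_length = 8,
                          outlet_length = 8, slab_depth = 1) {
  configuration <- match.arg(configuration)
  len <- c(vessel_diameter = vessel_diameter, dome_diameter = dome_diameter,
           neck_width = neck_width, inlet_length = inlet_length,
           outlet_length = outlet_length, slab_depth = slab_depth)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("all geometry lengths must be positive, got: ",
         paste(names(len)[!is.finite(len) | len <= 0], collapse = ", "))
  if (neck_width > dome_diameter)
    stop("neck_width (", neck_width, " mm) exceeds dome_diameter (",
         dome_diameter, " mm)")
  R <- dome_diameter / 2
  ## dome centre height chosen so the circle's chord on y = 0 is the neck
  yc <- sqrt(R^2 - (neck_width / 2)^2)
  structure(list(configuration = configuration,
                 vessel_diameter = vessel_diameter,
                 dome_diameter = dome_diameter,
                 neck_width = neck_width,
                 inlet_length = inlet_length,
                 outlet_length = outlet_length,
                 slab_depth = slab_depth,
                 dome_radius = R, dome_center = c(0, yc)),
            class = "aneurysm_geometry")
}

#' @export
print.aneurysm_geometry <- function(x, ...) {
  cat(sprintf(
    "%s aneurysm: vessel %.2f mm, dome %.2f mm, neck %.2f mm (slab %.2f mm)\n",
    x$configuration, x$vessel_diameter, x$dome_diameter, x$neck_width,
    x$slab_depth))
  invisible(x)
}

in_dome_region <- function(geom, x, y) {
  cx <- geom$dome_center[1]; cy <- geom$dome_center[2]
  ((x - cx)^2 + (y - cy)^2 < geom$dome_radius^2) & y > 0
}

in_lumen_region <- function(geom, x, y, y_bottom) {
  Dv <- geom$vessel_diameter
  circ <- (x - geom$dome_center[1])^2 + (y - geom$dome_center[2])^2 <
    geom$dome_radius^2
  base <- y > -Dv & y < 0                       # parent vessel channel
  low  <- circ & y <= 0                         # circle spill below the neck
  if (geom$configuration == "terminal") {
    stem <- abs(x) < Dv / 2 & y <= -Dv & y >= y_bottom
    base | low | stem
  } else {
    base | low
  }
}

## Cell flag codes
FLAG_EXTERIOR <- 0L
FLAG_LUMEN    <- 1L
FLAG_DOME     <- 2L
FLAG_WALL     <- 3L

#' Rasterize an aneurysm geometry to a computational grid
#'
#' Builds a uniform Cartesian cell grid covering the geometry, flags each
#' cell by a cell-centre point-in-region test (lumen / dome / wall /
#' exterior), and identifies the neck-plane faces (oriented lumen -> dome),
#' wall faces (tagged dome-wall or vessel-wall), and the open inlet/outlet
#' faces on the domain boundary.
#'
#' @param geom an [make_geometry()] object.
#' @param h cell size (mm).  Must satisfy `h <= neck_width / 4` so at
#'   least four faces span the neck.
#' @return object of class `flow_grid`.
#' @export
rasterize <- function(geom, h) {
  stopifnot(inherits(geom, "aneurysm_geometry"))
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("h must be positive")
  if (h > geom$neck_width / 4 + 1e-12)
    stop(sprintf(
      "cell size h = %g mm too coarse to resolve the neck; minimum resolution h <= %g mm",
      h, geom$neck_width / 4))
  W <- geom$neck_width; Dv <- geom$vessel_diameter
  R <- geom$dome_radius; yc <- geom$dome_center[2]
  if (geom$configuration == "sidewall") {
    nxl <- ceiling((W / 2 + geom$inlet_length) / h)
    nxr <- ceiling((W / 2 + geom$outlet_length) / h)
    nb  <- ceiling(Dv / h) + 1L             # rows below y=0 incl. wall layer
  } else {
    nxr <- ceiling((W / 2 + geom$outlet_length) / h)
    nxl <- nxr
    nb  <- round((Dv + geom$inlet_length) / h)  # inlet flush with box bottom
  }
  if ((R + h) > (nxl * h) || (R + h) > (nxr * h))
    stop("inlet_length/outlet_length too short to contain the dome laterally")
  nt <- ceiling((yc + R) / h) + 1L          # rows above y=0 incl. wall layer
  x0 <- -nxl * h; y0 <- -nb * h
  nx <- nxl + nxr; ny <- nb + nt
  cx <- x0 + (seq_len(nx) - 0.5) * h
  cy <- y0 + (seq_len(ny) - 0.5) * h
  X <- matrix(cx, nx, ny); Y <- matrix(cy, nx, ny, byrow = TRUE)
  dome  <- in_dome_region(geom, X, Y)
  lumen <- in_lumen_region(geom, X, Y, y_bottom = y0) & !dome
  flags <- matrix(FLAG_EXTERIOR, nx, ny)
  flags[lumen] <- FLAG_LUMEN
  flags[dome]  <- FLAG_DOME
  ## vessel-wall lip on y = 0 outside the neck gap: the dome circle is
  ## wider than its chord just above the neck, so without this the
  ## aperture would exceed neck_width by O(h)-independent overhang
  lip <- nb + 1L
  flags[abs(cx) > W / 2 & flags[, lip] == FLAG_DOME, lip] <- FLAG_WALL
  fluid <- flags == FLAG_LUMEN | flags == FLAG_DOME
  ## wall = non-fluid cells 4-adjacent to a fluid cell
  nb4 <- matrix(FALSE, nx, ny)
  nb4[-nx, ] <- nb4[-nx, ] | fluid[-1, ]
  nb4[-1, ]  <- nb4[-1, ]  | fluid[-nx, ]
  nb4[, -ny] <- nb4[, -ny] | fluid[, -1]
  nb4[, -1]  <- nb4[, -1]  | fluid[, -ny]
  flags[!fluid & nb4] <- FLAG_WALL

  ## neck faces: horizontal faces on y = 0 with lumen below, dome above
  jn <- nb + 1L   # cell row whose bottom face sits on y = 0
  neck_i <- which(flags[, nb] == FLAG_LUMEN & flags[, jn] == FLAG_DOME)
  if (length(neck_i) == 0L) stop("rasterization produced no neck faces")

  ## open boundary faces
  if (geom$configuration == "sidewall") {
    inlet  <- list(side = "left", comp = "u",
                   j = which(flags[1, ] == FLAG_LUMEN))
    outlet <- list(list(side = "right", comp = "u",
                        j = which(flags[nx, ] == FLAG_LUMEN)))
  } else {
    inlet  <- list(side = "bottom", comp = "v",
                   i = which(flags[, 1] == FLAG_LUMEN))
    outlet <- list(list(side = "left", comp = "u",
                        j = which(flags[1, ] == FLAG_LUMEN)),
                   list(side = "right", comp = "u",
                        j = which(flags[nx, ] == FLAG_LUMEN)))
  }
  if (length(if (geom$configuration == "sidewall") inlet$j else inlet$i) == 0L)
    stop("no inlet faces found on the domain boundary")
  if (any(vapply(outlet, function(o) length(o$j %||% o$i) == 0L, logical(1))))
    stop("no outlet faces found on the domain boundary")

  grid <- structure(list(h = h, x0 = x0, y0 = y0, nx = nx, ny = ny,
                         flags = flags, slab_depth = geom$slab_depth,
                         neck_j = jn, neck_i = neck_i,
                         inlet = inlet, outlet = outlet,
                         geom = geom),
                    class = "flow_grid")
  grid$wall_faces <- wall_face_table(grid)
  grid
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Enumerate wall faces: fluid cell + side (1=E,2=W,3=N,4=S) + wall type.
wall_face_table <- function(grid) {
  flags <- grid$flags; nx <- grid$nx; ny <- grid$ny
  fluid <- flags == FLAG_LUMEN | flags == FLAG_DOME
  res <- list()
  shift <- list(E = c(1L, 0L), W = c(-1L, 0L), N = c(0L, 1L), S = c(0L, -1L))
  for (s in names(shift)) {
    d <- shift[[s]]
    ii <- which(fluid, arr.ind = TRUE)
    ni <- ii[, 1] + d[1]; nj <- ii[, 2] + d[2]
    ok <- ni >= 1 & ni <= nx & nj >= 1 & nj <= ny
    sel <- ok
    sel[ok] <- flags[cbind(ni[ok], nj[ok])] == FLAG_WALL
    if (any(sel))
      res[[s]] <- data.frame(i = ii[sel, 1], j = ii[sel, 2], side = s,
                             dome = flags[ii[sel, , drop = FALSE]] == FLAG_DOME)
  }
  do.call(rbind, res)
}

#' @export
print.flow_grid <- function(x, ...) {
  tab <- table(factor(x$flags, levels = 0:3,
                      labels = c("exterior", "lumen", "dome", "wall")))
  cat(sprintf("flow_grid %d x %d cells, h = %g mm\n", x$nx, x$ny, x$h))
  print(tab)
  cat(sprintf("neck faces: %d (width %.3f mm)\n",
              length(x$neck_i), length(x$neck_i) * x$h))
  invisible(x)
}

#' Morphological parameters of a rasterized aneurysm
#'
#' Computes the standard morphometrics: maximum dome size (largest chord
#' of the dome region), dome volume `DV` (dome cell count x h^2 x
#' slab_depth), neck width and neck area (neck face measure x slab_depth).
#'
#' @param grid a [rasterize()]d grid.
#' @param geom the generating geometry (defaults to the one stored in the
#'   grid).
#' @return list of class `morphology_summary` with `max_size` (mm),
#'   `dome_volume` (mm^3), `neck_width` (mm), `neck_area` (mm^2).
#' @export
morphometrics <- function(grid, geom = grid$geom) {
  stopifnot(inherits(grid, "flow_grid"))
  h <- grid$h; depth <- grid$slab_depth
  dome_idx <- which(grid$flags == FLAG_DOME, arr.ind = TRUE)
  if (nrow(dome_idx) == 0L) stop("empty dome region")
  xs <- grid$x0 + (dome_idx[, 1] - 0.5) * h
  ys <- grid$y0 + (dome_idx[, 2] - 0.5) * h
  ## largest chord via convex hull of dome cell centres (+ one cell size)
  pts <- cbind(xs, ys)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  dmax <- if (nrow(hull) > 1) max(stats::dist(hull)) else 0
  structure(list(max_size = dmax + h,
                 dome_volume = nrow(dome_idx) * h^2 * depth,
                 neck_width = length(grid$neck_i) * h,
                 neck_area = length(grid$neck_i) * h * depth),
            class = "morphology_summary")
}

#' @export
print.morphology_summary <- function(x, ...) {
  cat(sprintf(
    "max size %.2f mm | dome volume %.2f mm^3 | neck width %.2f mm | neck area %.2f mm^2\n",
    x$max_size, x$dome_volume, x$neck_width, x$neck_area))
  invisible(x)
}

#' Straight-channel verification grid
#'
#' Builds a plane channel grid (no dome) with optional porous band, used
#' for solver verification against closed forms (plane Poiseuille flow,
#' 1D Darcy pressure drop through a plug).  The band cells are flagged as
#' dome cells so the porous momentum sink applies there.
#'
#' @param length,height channel dimensions (mm).
#' @param h cell size (mm).
#' @param porous_x optional `c(x_start, x_end)` (mm, from the inlet) of a
#'   porous plug spanning the full channel height; snapped to cell faces.
#' @param slab_depth out-of-plane depth (mm).
#' @return a `flow_grid` (left inlet, right outlet, no neck faces).
#' @export
channel_grid <- function(length = 20, height = 4, h = 0.2,
                         porous_x = NULL, slab_depth = 1) {
  nx <- round(length / h); ny_f <- round(height / h)
  ny <- ny_f + 2L  # wall layers top and bottom
  flags <- matrix(FLAG_EXTERIOR, nx, ny)
  flags[, 2:(ny_f + 1)] <- FLAG_LUMEN
  flags[, 1] <- FLAG_WALL; flags[, ny] <- FLAG_WALL
  if (!is.null(porous_x)) {
    i0 <- max(1L, round(porous_x[1] / h) + 1L)
    i1 <- min(nx, round(porous_x[2] / h))
    if (i1 < i0) stop("empty porous band")
    flags[i0:i1, 2:(ny_f + 1)] <- FLAG_DOME
  }
  grid <- structure(list(h = h, x0 = 0, y0 = -h, nx = nx, ny = ny,
                         flags = flags, slab_depth = slab_depth,
                         neck_j = NA_integer_, neck_i = integer(0),
                         inlet = list(side = "left", comp = "u",
                                      j = 2:(ny_f + 1)),
                         outlet = list(list(side = "right", comp = "u",
                                            j = 2:(ny_f + 1))),
                         geom = NULL),
                    class = "flow_grid")
  grid$wall_faces <- wall_face_table(grid)
  grid
}
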