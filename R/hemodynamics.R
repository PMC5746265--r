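#' Wall shear stress over the dome and parent vessel
#'
#' Per wall face, the shear is `mu * |u_t| / (h/2)`: a one-sided
#' difference between the no-slip wall and the tangential velocity at the
#' first cell centre.  The dome value is the area-weighted mean over
#' dome-wall faces; `normalized_wss` divides it by the area-weighted mean
#' over parent-vessel wall faces of the same run (reported as 0 with a
#' warning flag when the reference shear is zero).
#'
#' @param field a converged `flow_field`.
#' @param grid the grid the field was solved on.
#' @param props [fluid_properties()].
#' @return list with `wss_dome` (Pa), `wss_vessel` (Pa),
#'   `normalized_wss`, and `flag` (`"ok"` or `"zero-reference"`).
#' @export
wall_shear_stress <- function(field, grid = field$grid,
                              props = field$props) {
  wf <- grid$wall_faces
  if (is.null(wf) || !any(wf$dome)) stop("grid has no dome-wall faces")
  tau <- wall_shear_table(field, grid, props)$tau
  wss_dome <- mean(tau[wf$dome])         # equal face measures: area mean
  wss_vessel <- if (any(!wf$dome)) mean(tau[!wf$dome]) else 0
  if (wss_vessel > 0) {
    list(wss_dome = wss_dome, wss_vessel = wss_vessel,
         normalized_wss = wss_dome / wss_vessel, flag = "ok")
  } else {
    list(wss_dome = wss_dome, wss_vessel = wss_vessel,
         normalized_wss = 0, flag = "zero-reference")
  }
}

#' Per-face wall shear stress table
#'
#' One row per wall face with its fluid cell index, side, dome/vessel tag
#' and shear `tau = mu |u_t| / (h/2)` from a one-sided difference.
#'
#' @inheritParams wall_shear_stress
#' @return data.frame with columns `i`, `j`, `side`, `dome`, `tau` (Pa).
#' @export
wall_shear_table <- function(field, grid = field$grid,
                             props = field$props) {
  wf <- grid$wall_faces
  if (is.null(wf) || nrow(wf) == 0L) stop("grid has no wall faces")
  hm <- grid$h * 1e-3
  tang <- numeric(nrow(wf))
  horiz <- wf$side %in% c("N", "S")      # wall normal is y: tangential = u
  if (any(horiz)) {
    i <- wf$i[horiz]; j <- wf$j[horiz]
    tang[horiz] <- (field$u[cbind(i, j)] + field$u[cbind(i + 1L, j)]) / 2
  }
  if (any(!horiz)) {
    i <- wf$i[!horiz]; j <- wf$j[!horiz]
    tang[!horiz] <- (field$v[cbind(i, j)] + field$v[cbind(i, j + 1L)]) / 2
  }
  wf$tau <- props$mu * abs(tang) / (hm / 2)
  wf
}

#' Mean flow velocity in the aneurysm dome
#'
#' Volume-weighted mean of the cell-centred speed over dome cells.
#'
#' @inheritParams wall_shear_stress
#' @return mean dome speed in cm/s.
#' @export
dome_mean_velocity <- function(field, grid = field$grid) {
  dome <- grid$flags == FLAG_DOME
  if (!any(dome)) stop("empty dome region")
  sp <- cell_speed_uv(field$u, field$v, grid)
  mean(sp[dome]) * 100
}

#' Neck-plane inflow/outflow zone analysis
#'
#' Splits the neck faces by the sign of the velocity component normal to
#' the neck plane (lumen -> dome positive = inflow).  Zone area is the
#' face measure times slab depth; zone velocity is the face-measure
#' weighted mean magnitude of the normal component.
#'
#' @inheritParams wall_shear_stress
#' @return list with `inflow_area`, `outflow_area` (mm^2),
#'   `inflow_velocity`, `outflow_velocity` (cm/s) and `flag`.
#' @export
neck_zone_analysis <- function(field, grid = field$grid) {
  if (length(grid$neck_i) == 0L) stop("grid has no neck faces")
  vn <- field$v[cbind(grid$neck_i, grid$neck_j)]   # +y is lumen -> dome
  a_face <- grid$h * grid$slab_depth               # mm^2 per face
  up <- vn > 0; dn <- vn < 0
  flag <- if (!any(up) && !any(dn)) "all-zero" else "ok"
  if (flag == "all-zero")
    warning("all neck-plane normal velocities are zero; both zones empty")
  list(inflow_area = sum(up) * a_face,
       outflow_area = sum(dn) * a_face,
       inflow_velocity = if (any(up)) mean(vn[up]) * 100 else 0,
       outflow_velocity = if (any(dn)) mean(-vn[dn]) * 100 else 0,
       inflow_flux = sum(vn[up]) * (grid$h * 1e-3) *
         (grid$slab_depth * 1e-3),
       outflow_flux = -sum(vn[dn]) * (grid$h * 1e-3) *
         (grid$slab_depth * 1e-3),
       flag = flag)
}

#' Residual flow volume (RFV)
#'
#' The dome volume still moving faster than a threshold speed: the sum of
#' cell volumes (`h^2 * slab_depth`) over dome cells whose cell-centre
#' speed strictly exceeds `threshold`.
#'
#' @inheritParams wall_shear_stress
#' @param threshold speed threshold in cm/s (default 1.0, the best
#'   predictor among 0.5-10 cm/s in prior calibration).
#' @return RFV in mm^3.
#' @export
residual_flow_volume <- function(field, grid = field$grid, threshold = 1.0) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive (cm/s)")
  dome <- grid$flags == FLAG_DOME
  if (!any(dome)) stop("empty dome region")
  sp <- cell_speed_uv(field$u, field$v, grid) * 100   # cm/s
  sum(sp[dome] > threshold) * grid$h^2 * grid$slab_depth
}

#' RFV from a transient run
#'
#' Per-cell time-mean speed over the final cardiac cycle, thresholded and
#' summed exactly as in [residual_flow_volume()].
#'
#' @param pulsatile a [solve_pulsatile()] result.
#' @param grid grid (defaults to the one in the run).
#' @param threshold speed threshold in cm/s.
#' @return RFV_trans in mm^3.
#' @export
rfv_transient <- function(pulsatile, grid = pulsatile$grid, threshold = 1.0) {
  stopifnot(inherits(pulsatile, "pulsatile_flow"))
  if (!isTRUE(pulsatile$complete))
    stop("transient run does not contain a full final cycle")
  if (threshold <= 0) stop("threshold must be positive (cm/s)")
  dome <- grid$flags == FLAG_DOME
  if (!any(dome)) stop("empty dome region")
  sp <- pulsatile$mean_speed * 100
  sum(sp[dome] > threshold) * grid$h^2 * grid$slab_depth
}

#' RFV across a set of speed thresholds
#'
#' @inheritParams residual_flow_volume
#' @param thresholds vector of thresholds in cm/s
#'   (default `c(0.5, 1, 2, 5, 10)`).
#' @return named numeric vector, RFV (mm^3) per threshold; nonincreasing
#'   in the threshold by construction.
#' @export
threshold_scan <- function(field, grid = field$grid,
                           thresholds = RFV_THRESHOLDS_CM_S) {
  if (length(thresholds) == 0L) stop("empty threshold set")
  if (any(thresholds <= 0)) stop("thresholds must be positive (cm/s)")
  out <- vapply(thresholds, function(th)
    residual_flow_volume(field, grid, threshold = th), numeric(1))
  names(out) <- format(thresholds)
  out
}

#' Full hemodynamic parameter vector for one run
#'
#' Collects the per-aneurysm summary: dome WSS, normalized WSS, dome mean
#' velocity, neck inflow/outflow areas and velocities, and RFV at the
#' given threshold.
#'
#' @inheritParams wall_shear_stress
#' @param rfv_threshold RFV speed threshold (cm/s).
#' @param analysis_kind `"steady"` or `"transient"` label for the row.
#' @return object of class `hemodynamic_summary` (also a one-row
#'   data.frame via [as.data.frame()]).
#' @export
hemodynamic_summary <- function(field, grid = field$grid,
                                props = field$props, rfv_threshold = 1.0,
                                analysis_kind = "steady") {
  w <- wall_shear_stress(field, grid, props)
  nz <- neck_zone_analysis(field, grid)
  structure(list(wss = w$wss_dome, normalized_wss = w$normalized_wss,
                 flow_velocity = dome_mean_velocity(field, grid),
                 inflow_area = nz$inflow_area,
                 outflow_area = nz$outflow_area,
                 inflow_velocity = nz$inflow_velocity,
                 outflow_velocity = nz$outflow_velocity,
                 rfv = residual_flow_volume(field, grid, rfv_threshold),
                 rfv_threshold = rfv_threshold,
                 analysis_kind = analysis_kind),
            class = "hemodynamic_summary")
}

#' @export
as.data.frame.hemodynamic_summary <- function(x, ...) {
  data.frame(wss = x$wss, normalized_wss = x$normalized_wss,
             flow_velocity = x$flow_velocity,
             inflow_area = x$inflow_area, outflow_area = x$outflow_area,
             inflow_velocity = x$inflow_velocity,
             outflow_velocity = x$outflow_velocity,
             rfv = x$rfv, rfv_threshold = x$rfv_threshold,
             analysis_kind = x$analysis_kind)
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat(sprintf("hemodynamics (%s): WSS %.3f Pa (normalized %.3f)\n",
              x$analysis_kind, x$wss, x$normalized_wss))
  cat(sprintf("  dome velocity %.3f cm/s | inflow %.2f mm^2 @ %.2f cm/s | outflow %.2f mm^2 @ %.2f cm/s\n",
              x$flow_velocity, x$inflow_area, x$inflow_velocity,
              x$outflow_area, x$outflow_velocity))
  cat(sprintf("  RFV %.3f mm^3 (threshold %.1f cm/s)\n", x$rfv,
              x$rfv_threshold))
  invisible(x)
}
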