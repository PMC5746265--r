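#' Read a pipeline configuration file
#'
#' Minimal structured key-value format (a TOML dialect): `[table]`
#' headers, `key = value` pairs with numbers, booleans (`true`/`false`),
#' double-quoted strings and flat arrays `[v1, v2, ...]`; `#` starts a
#' comment.  All lengths are in mm, velocities in m/s.
#'
#' @param path file path.
#' @return named list of tables.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  cfg <- list(); current <- NULL
  parse_scalar <- function(tok) {
    tok <- trimws(tok)
    if (grepl('^".*"$', tok)) return(substr(tok, 2, nchar(tok) - 1))
    if (tok %in% c("true", "false")) return(tok == "true")
    num <- suppressWarnings(as.numeric(tok))
    if (!is.na(num)) return(num)
    stop("cannot parse config value: ", tok)
  }
  for (k in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[k])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.+\\]$", ln)) {
      current <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[current]])) cfg[[current]] <- list()
      next
    }
    if (!grepl("=", ln))
      stop(sprintf("config parse error at line %d: '%s'", k, lines[k]))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parsed <- if (grepl("^\\[.*\\]$", val)) {
      inner <- substr(val, 2, nchar(val) - 1)
      toks <- strsplit(inner, ",")[[1]]
      unlist(lapply(toks, parse_scalar))
    } else parse_scalar(val)
    if (is.null(current)) cfg[[key]] <- parsed
    else cfg[[current]][[key]] <- parsed
  }
  cfg
}

cfg_require <- function(cfg, table, keys = character(0)) {
  if (is.null(cfg[[table]]))
    stop(sprintf("config validation error: missing [%s] table", table))
  for (k in keys)
    if (is.null(cfg[[table]][[k]]))
      stop(sprintf("config validation error: missing key '%s' in [%s]",
                   k, table))
  invisible(TRUE)
}

#' Build pipeline objects from a configuration list
#'
#' Validates the `[geometry]`, `[coil]`, `[fluid]`, `[boundary]` and
#' `[solver]` tables and instantiates the corresponding objects.
#'
#' @param cfg a [read_config()] result.
#' @return list with `geom`, `grid`, `porous`, `props`, `bc`,
#'   `settings`, `h`.
#' @export
config_to_objects <- function(cfg) {
  cfg_require(cfg, "geometry", c("dome_diameter", "neck_width"))
  gt <- cfg$geometry
  geom <- make_geometry(
    configuration = gt$configuration %||% "sidewall",
    vessel_diameter = gt$vessel_diameter %||% 4,
    dome_diameter = gt$dome_diameter,
    neck_width = gt$neck_width,
    inlet_length = gt$inlet_length %||% 8,
    outlet_length = gt$outlet_length %||% 8,
    slab_depth = gt$slab_depth %||% 1)
  h <- gt$h %||% (gt$neck_width / 8)
  grid <- rasterize(geom, h)

  porous <- NULL
  if (!is.null(cfg$coil)) {
    ct <- cfg$coil
    D_P <- if (!is.null(ct$D_P_inches)) ct$D_P_inches * 0.0254 else
      COIL_D_P_M
    pd <- if (!is.null(ct$packing_density)) ct$packing_density
    else if (!is.null(ct$CV))
      packing_density(ct$CV, morphometrics(grid)$dome_volume)
    else stop("config validation error: [coil] needs CV or packing_density")
    porous <- porous_coefficients(packing = pd, D_P = D_P,
                                  rho = cfg$fluid$rho %||% BLOOD_RHO,
                                  mu = cfg$fluid$mu %||% BLOOD_MU)
  }
  props <- fluid_properties(rho = cfg$fluid$rho %||% BLOOD_RHO,
                            mu = cfg$fluid$mu %||% BLOOD_MU)
  cfg_require(cfg, "boundary", "inlet_mean_velocity")
  bt <- cfg$boundary
  wf <- make_waveform(kind = bt$waveform %||% "constant",
                      period = bt$period %||% 0.9,
                      amplitude = bt$amplitude %||% 0.4)
  bc <- boundary_conditions(bt$inlet_mean_velocity, waveform = wf,
                            profile = bt$profile %||% "parabolic")
  sl <- cfg$solver %||% list()
  settings <- solver_settings(
    time_step = sl$time_step %||% 1e-4,
    n_cycles = sl$n_cycles %||% 2,
    steady_tolerance = sl$steady_tolerance %||% 1e-6,
    max_iterations = sl$max_iterations %||% 50000L,
    scheme = sl$scheme %||% "upwind")
  list(geom = geom, grid = grid, porous = porous, props = props,
       bc = bc, settings = settings, h = h)
}
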