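## ASCII legacy VTK structured-points I/O.  Cell data on the uniform
## raster: velocity (cell-centred vectors, m/s), pressure (Pa), flags.

#' Write a flow field as a legacy VTK structured-points file
#'
#' ASCII, `DATASET STRUCTURED_POINTS`, with the cell-centred velocity as
#' a `VECTORS` array and pressure plus cell flags as `SCALARS`.  Spacing
#' and origin are in mm.
#'
#' @param field a `flow_field`.
#' @param grid its grid.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, grid = field$grid, path) {
  nx <- grid$nx; ny <- grid$ny
  if (nx == 0 || ny == 0) stop("empty grid")
  uc <- (field$u[1:nx, , drop = FALSE] +
           field$u[2:(nx + 1), , drop = FALSE]) / 2
  vc <- (field$v[, 1:ny, drop = FALSE] + field$v[, 2:(ny + 1),
                                                 drop = FALSE]) / 2
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "coilflow field (cell data; lengths mm, velocity m/s)",
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx + 1L, ny + 1L),
               sprintf("ORIGIN %.9g %.9g 0", grid$x0, grid$y0),
               sprintf("SPACING %.9g %.9g %.9g", grid$h, grid$h,
                       grid$slab_depth),
               sprintf("CELL_DATA %d", nx * ny)), con)
  writeLines("VECTORS velocity double", con)
  ## VTK cell order: x fastest
  writeLines(sprintf("%.9g %.9g 0", as.vector(uc), as.vector(vc)), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", as.vector(field$p)), con)
  writeLines(c("SCALARS cell_flags int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", as.vector(grid$flags)), con)
  invisible(path)
}

#' Write a grid's cell flags as a legacy VTK structured-points file
#' @param grid a `flow_grid`.
#' @param path output file.
#' @export
write_grid_vtk <- function(grid, path) {
  zero <- list(u = matrix(0, grid$nx + 1L, grid$ny),
               v = matrix(0, grid$nx, grid$ny + 1L),
               p = matrix(0, grid$nx, grid$ny), grid = grid)
  write_field_vtk(zero, grid, path)
}

#' Read a legacy VTK structured-points field file
#'
#' Parses the ASCII dialect written by [write_field_vtk()].
#'
#' @param path file path.
#' @return list with `velocity` (nx x ny x 2 array, m/s), `pressure`,
#'   `flags`, `nx`, `ny`, `origin`, `spacing`.
#' @export
read_field_vtk <- function(path) {
  if (!file.exists(path)) stop("VTK file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  fail <- function(k, why)
    stop(sprintf("VTK parse error at line %d: %s (expected ASCII legacy structured-points dialect)",
                 k, why))
  if (length(lines) < 8) fail(length(lines), "file truncated")
  if (!grepl("^# vtk DataFile", lines[1])) fail(1, "missing VTK header")
  if (trimws(lines[3]) != "ASCII") fail(3, "only ASCII supported")
  if (trimws(lines[4]) != "DATASET STRUCTURED_POINTS")
    fail(4, "only STRUCTURED_POINTS supported")
  dims <- as.integer(strsplit(trimws(lines[5]), "\\s+")[[1]][-1])
  origin <- as.numeric(strsplit(trimws(lines[6]), "\\s+")[[1]][-1])
  spacing <- as.numeric(strsplit(trimws(lines[7]), "\\s+")[[1]][-1])
  nx <- dims[1] - 1L; ny <- dims[2] - 1L
  ncell <- nx * ny
  if (is.na(ncell) || ncell <= 0) fail(5, "bad DIMENSIONS")
  k <- 8L
  if (!grepl("^CELL_DATA", lines[k])) fail(k, "missing CELL_DATA")
  out <- list(nx = nx, ny = ny, origin = origin, spacing = spacing)
  k <- k + 1L
  while (k <= length(lines)) {
    hd <- trimws(lines[k])
    if (hd == "") { k <- k + 1L; next }
    toks <- strsplit(hd, "\\s+")[[1]]
    if (toks[1] == "VECTORS") {
      if (k + ncell > length(lines)) fail(k, "truncated VECTORS block")
      vals <- strsplit(trimws(lines[(k + 1):(k + ncell)]), "\\s+")
      m <- matrix(as.numeric(unlist(vals)), ncol = 3, byrow = TRUE)
      if (any(is.na(m))) fail(k + 1L, "non-numeric vector data")
      arr <- array(0, c(nx, ny, 2))
      arr[, , 1] <- matrix(m[, 1], nx, ny)
      arr[, , 2] <- matrix(m[, 2], nx, ny)
      out[[toks[2]]] <- arr
      k <- k + ncell + 1L
    } else if (toks[1] == "SCALARS") {
      if (k + 1L > length(lines) ||
          !grepl("^LOOKUP_TABLE", lines[k + 1L]))
        fail(k + 1L, "missing LOOKUP_TABLE")
      if (k + 1L + ncell > length(lines)) fail(k, "truncated SCALARS block")
      vals <- as.numeric(lines[(k + 2):(k + 1 + ncell)])
      if (any(is.na(vals))) fail(k + 2L, "non-numeric scalar data")
      out[[toks[2]]] <- matrix(vals, nx, ny)
      k <- k + ncell + 2L
    } else fail(k, paste("unknown data block", toks[1]))
  }
  if (!is.null(out$cell_flags)) out$flags <- out$cell_flags
  if (!is.null(out$pressure)) out$pressure <- out$pressure
  out
}
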