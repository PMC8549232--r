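#' Pressure-mat geometry
#'
#' Describes the sensor grid of a pressure mat and how its (row, col)
#' indices map onto the test's millimetre coordinate system. The reference
#' device is a mat of miniature force sensors with an 8.0 mm pitch sampled
#' at 60 Hz; any grid size, pitch and rate can be described.
#'
#' The mapping between sensor indices and millimetres is carried by
#' `origin_cell` (the 0-based `(row, col)` of the sensor whose centre sits
#' at the proximal target centre, i.e. the origin) and `y_axis`, which
#' names the grid direction that points from the proximal towards the
#' distal target (`"+row"`, `"-row"`, `"+col"` or `"-col"`). The x axis is
#' the remaining grid direction with positive sign.
#'
#' @param n_rows,n_cols Grid dimensions (sensors).
#' @param cell_pitch Sensor pitch in mm (default 8.0, i.e. 0.80 cm cells).
#' @param sampling_rate Frames per second (default 60).
#' @param origin_cell Integer vector `c(row, col)`, 0-based, of the sensor
#'   cell whose centre is the coordinate origin.
#' @param y_axis One of `"+row"`, `"-row"`, `"+col"`, `"-col"`.
#' @return An object of class `mat_geometry`.
#' @export
#' @examples
#' g <- mat_geometry(72, 32, origin_cell = c(14, 15))
#' cell_to_point(14, 15, g)  # the origin cell -> (0, 0)
mat_geometry <- function(n_rows, n_cols, cell_pitch = 8.0,
                         sampling_rate = 60,
                         origin_cell = c(0L, 0L),
                         y_axis = "+row") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, cell_pitch > 0, sampling_rate > 0,
            length(origin_cell) == 2L)
  y_axis <- match.arg(y_axis, c("+row", "-row", "+col", "-col"))
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 cell_pitch = as.numeric(cell_pitch),
                 sampling_rate = as.numeric(sampling_rate),
                 origin_cell = as.numeric(origin_cell),
                 y_axis = y_axis),
            class = "mat_geometry")
}

#' Target layout of the coordination test
#'
#' The proximal target centre defines the origin; the distal target lies
#' 300 mm away along +y, matching the standard 30 cm target spacing. Each
#' target owns a zone band of `zone_half_width` mm along y; contacts whose
#' endpoint falls outside both bands are between-target touches.
#'
#' The physical diameter of the painted target is not standardised by the
#' test description, so `target_radius` is explicit configuration
#' (default 25 mm) and is echoed in every output header.
#'
#' @param proximal_center,distal_center Numeric `c(x, y)` in mm.
#' @param target_radius Target disc radius in mm (closed disc).
#' @param zone_half_width Half-width of each target's zone band along y, mm.
#' @return An object of class `target_layout`.
#' @export
target_layout <- function(proximal_center = c(0, 0),
                          distal_center = c(0, 300),
                          target_radius = 25,
                          zone_half_width = 100) {
  stopifnot(length(proximal_center) == 2L, length(distal_center) == 2L,
            target_radius > 0, zone_half_width > 0)
  if (isTRUE(all(proximal_center == distal_center)))
    stop("proximal and distal target centers must be distinct")
  sep_y <- abs(distal_center[2] - proximal_center[2])
  if (sep_y <= 2 * zone_half_width)
    stop("target zone bands overlap: |y separation| (", sep_y,
         " mm) must exceed 2 * zone_half_width (", 2 * zone_half_width, " mm)")
  structure(list(proximal_center = as.numeric(proximal_center),
                 distal_center = as.numeric(distal_center),
                 target_radius = as.numeric(target_radius),
                 zone_half_width = as.numeric(zone_half_width)),
            class = "target_layout")
}

#' Convert sensor indices to mm coordinates (and back)
#'
#' `cell_to_point()` returns the centre of sensor cell `(row, col)`
#' (0-based) in the test coordinate system: origin at the proximal target
#' centre, +y towards the distal target. `point_to_cell()` is its inverse
#' for any point strictly inside a cell.
#'
#' @param row,col 0-based sensor indices (vectorised).
#' @param geometry A [mat_geometry()].
#' @return `cell_to_point()`: an n x 2 matrix of (x, y) mm;
#'   `point_to_cell()`: an n x 2 integer matrix of (row, col).
#' @export
cell_to_point <- function(row, col, geometry) {
  stopifnot(inherits(geometry, "mat_geometry"))
  if (any(row < 0 | row >= geometry$n_rows | col < 0 | col >= geometry$n_cols))
    stop("sensor index out of range")
  p <- geometry$cell_pitch
  dr <- row - geometry$origin_cell[1]
  dc <- col - geometry$origin_cell[2]
  xy <- switch(geometry$y_axis,
    "+row" = cbind(x = dc * p, y =  dr * p),
    "-row" = cbind(x = dc * p, y = -dr * p),
    "+col" = cbind(x = dr * p, y =  dc * p),
    "-col" = cbind(x = dr * p, y = -dc * p))
  xy
}

#' @param x,y Coordinates in mm (vectorised).
#' @rdname cell_to_point
#' @export
point_to_cell <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "mat_geometry"))
  p <- geometry$cell_pitch
  inv <- switch(geometry$y_axis,
    "+row" = cbind(r =  y / p, c = x / p),
    "-row" = cbind(r = -y / p, c = x / p),
    "+col" = cbind(r =  x / p, c = y / p),
    "-col" = cbind(r =  x / p, c = -y / p))
  row <- as.integer(round(inv[, "r"] + geometry$origin_cell[1]))
  col <- as.integer(round(inv[, "c"] + geometry$origin_cell[2]))
  if (any(row < 0 | row >= geometry$n_rows | col < 0 | col >= geometry$n_cols))
    stop("point falls outside the sensor grid")
  cbind(row = row, col = col)
}

#' @export
print.mat_geometry <- function(x, ...) {
  cat(sprintf("<mat_geometry> %d x %d sensors, %.2f mm pitch, %g Hz\n",
              x$n_rows, x$n_cols, x$cell_pitch, x$sampling_rate))
  cat(sprintf("  origin cell (%g, %g), y axis along %s\n",
              x$origin_cell[1], x$origin_cell[2], x$y_axis))
  invisible(x)
}

#' @export
print.target_layout <- function(x, ...) {
  cat(sprintf(
    "<target_layout> proximal (%g, %g), distal (%g, %g) mm; radius %g mm, zone half-width %g mm\n",
    x$proximal_center[1], x$proximal_center[2],
    x$distal_center[1], x$distal_center[2],
    x$target_radius, x$zone_half_width))
  invisible(x)
}
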