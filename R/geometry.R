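#' Grid geometry for a toroidal neuron sheet
#'
#' Defines the rectangular grid of neurons folded as a torus. Neurons are
#' identified either by zero-based integer index `idx` or by grid coordinates
#' `(x, y)` with `idx = x * ncol + y` (the column-major convention used for
#' polar-sampling wiring). All distances are measured in grid units; the
#' physical spacing (default 10 um between neighbouring nodes) is kept only
#' for unit conversion in displays.
#'
#' @param ncol,nrow Grid dimensions (default 100 x 100, i.e. 10,000 neurons).
#' @param spacing_um Physical distance between neighbouring grid nodes, in um.
#' @return An object of class `grid_geometry`.
#' @examples
#' geom <- grid_geometry(100, 100)
#' idx_from_xy(1, 0, geom)   # 100
#' @export
grid_geometry <- function(ncol = 100L, nrow = 100L, spacing_um = 10) {
  stopifnot(ncol >= 1, nrow >= 1, spacing_um > 0)
  structure(
    list(ncol = as.integer(ncol), nrow = as.integer(nrow),
         n = as.integer(ncol) * as.integer(nrow),
         spacing_um = spacing_um, topology = "torus"),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d torus (%d neurons, %g um spacing)\n",
              x$ncol, x$nrow, x$n, x$spacing_um))
  invisible(x)
}

#' Convert grid coordinates to a neuron index
#'
#' Uses the convention `idx = x * ncol + y` with zero-based `x`, `y` and
#' `idx`. Coordinates are wrapped onto the torus first, so any integer input
#' is valid.
#'
#' @param x,y Integer grid coordinates (vectorised; wrapped modulo the grid).
#' @param geometry A [grid_geometry()] (or an integer `ncol` for a square
#'   grid, as a convenience).
#' @return Zero-based neuron indices in `[0, N)`.
#' @seealso [xy_from_idx()]
#' @export
idx_from_xy <- function(x, y, geometry = grid_geometry()) {
  if (is.numeric(geometry)) geometry <- grid_geometry(geometry, geometry)
  x <- as.integer(x) %% geometry$nrow
  y <- as.integer(y) %% geometry$ncol
  x * geometry$ncol + y
}

#' Convert neuron indices to grid coordinates
#'
#' Inverse of [idx_from_xy()]: recovers the zero-based `(x, y)` pair.
#'
#' @param idx Zero-based neuron indices.
#' @inheritParams idx_from_xy
#' @return A tibble with columns `idx`, `x`, `y`.
#' @export
xy_from_idx <- function(idx, geometry = grid_geometry()) {
  if (is.numeric(geometry)) geometry <- grid_geometry(geometry, geometry)
  idx <- as.integer(idx)
  stopifnot(all(idx >= 0), all(idx < geometry$n))
  tibble::tibble(idx = idx,
                 x = idx %/% geometry$ncol,
                 y = idx %% geometry$ncol)
}

#' Signed minimal offset along one torus dimension
#'
#' Returns the representative of `d` modulo `len` lying in
#' `(-len/2, len/2]`.
#' @noRd
torus_offset <- function(d, len) {
  d <- d %% len
  ifelse(d > len / 2, d - len, d)
}

#' Torus distance between grid sites
#'
#' Euclidean distance with periodic wrapping in both dimensions, in grid
#' units. Each coordinate difference is reduced to at most half the grid
#' extent.
#'
#' @param x1,y1,x2,y2 Grid coordinates (vectorised, recycled).
#' @inheritParams idx_from_xy
#' @return Numeric vector of distances in grid units.
#' @export
torus_distance <- function(x1, y1, x2, y2, geometry = grid_geometry()) {
  if (is.numeric(geometry)) geometry <- grid_geometry(geometry, geometry)
  dx <- torus_offset(x1 - x2, geometry$nrow)
  dy <- torus_offset(y1 - y2, geometry$ncol)
  sqrt(dx^2 + dy^2)
}
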