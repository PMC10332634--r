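#' Bilinear sampling of a grid field at arbitrary positions
#'
#' Interpolates a scalar grid (matrix indexed `[x, y]`) bilinearly from the
#' four surrounding grid points. Used to couple agents to the fluid, the
#' vorticity and the prey fields; each staggered velocity component is
#' interpolated from its own face grid. Bilinear interpolation reproduces
#' affine fields exactly and returns node values exactly at node positions.
#'
#' @param M numeric matrix, first index x, second index y.
#' @param x,y positions (vectors of equal length), in metres.
#' @param origin coordinates `(x, y)` of grid point `M[1, 1]`.
#' @param spacing grid spacing (m), one value or `c(dx, dy)`.
#' @param geometry optional [tank_geometry()]; when supplied, positions
#'   outside the tank raise an error (the grid itself may extend past the
#'   tank by ghost layers).
#' @return numeric vector of interpolated values.
#' @examples
#' M <- outer(0:4, 0:3, function(i, j) 2 * i + 3 * j)  # affine field
#' sample_field(M, 1.25, 0.5, origin = c(0, 0), spacing = 1)
#' @export
sample_field <- function(M, x, y, origin, spacing, geometry = NULL) {
  if (!is.null(geometry)) stopifnot_inside(x, y, geometry)
  dx <- spacing[1]; dy <- if (length(spacing) > 1) spacing[2] else spacing[1]
  nx <- nrow(M); ny <- ncol(M)
  gx <- (x - origin[1]) / dx + 1
  gy <- (y - origin[2]) / dy + 1
  # allow the half-cell margin of cell-centered grids, clamp within it
  if (any(gx < 0.5 - 1e-9 | gx > nx + 0.5 + 1e-9 |
          gy < 0.5 - 1e-9 | gy > ny + 0.5 + 1e-9))
    stop("position outside the sampled grid")
  i0 <- pmin(pmax(floor(gx), 1), nx - 1L)
  j0 <- pmin(pmax(floor(gy), 1), ny - 1L)
  wx <- pmin(pmax(gx - i0, 0), 1)
  wy <- pmin(pmax(gy - j0, 0), 1)
  idx <- function(i, j) (j - 1L) * nx + i
  M[idx(i0, j0)] * (1 - wx) * (1 - wy) +
    M[idx(i0 + 1L, j0)] * wx * (1 - wy) +
    M[idx(i0, j0 + 1L)] * (1 - wx) * wy +
    M[idx(i0 + 1L, j0 + 1L)] * wx * wy
}

#' Sample the staggered flow velocity at agent positions
#'
#' @param field a `flow_field`.
#' @param x,y positions inside the tank.
#' @return list with vectors `u` and `v` (m/s).
#' @export
sample_flow_velocity <- function(field, x, y) {
  g <- field$geometry
  stopifnot_inside(x, y, g)
  # u grid spans ghost columns: origin half a cell below the tank floor
  u <- sample_field(field$u, x, y,
                    origin = c(g$x_min, g$y_min - g$dy / 2), spacing = g$dx)
  v <- sample_field(field$v, x, y,
                    origin = c(g$x_min - g$dx / 2, g$y_min), spacing = g$dx)
  list(u = u, v = v)
}
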