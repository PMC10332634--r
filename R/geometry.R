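#' Tank geometry for a simulation scenario
#'
#' Defines the rectangular tank, the uniform grid and the scenario tag that
#' selects the driving boundary conditions. The three built-in scenarios are
#' the lid-driven cavity (10 m x 10 m, top lid moving in +x), the long
#' channel (40 m x 5 m, Poiseuille inflow at the right end, flow towards -x)
#' and the double gyre (10 m x 5 m, both side walls moving in +y). Grid
#' point counts refer to cell corners (nodes); pressure and scalar fields
#' live on the (nx-1) x (ny-1) cell centers of the staggered layout.
#'
#' @param scenario one of `"cavity"`, `"channel"`, `"double_gyre"`.
#' @param nx,ny number of grid nodes in x and y. Defaults per scenario keep
#'   a common 0.125 m spacing: channel 321 x 41, cavity 81 x 81, double
#'   gyre 81 x 41.
#' @param x_min,x_max,y_min,y_max tank extent in metres. Defaults per
#'   scenario: cavity `[0,10] x [0,10]`, channel `[-20,20] x [0,5]`, double
#'   gyre `[-5,5] x [0,5]`.
#' @return an object of class `tank_geometry`: a list with the extents,
#'   node counts `nx`, `ny`, uniform spacing `dx` (= `dy`) and `scenario`.
#' @examples
#' g <- tank_geometry("channel")
#' c(g$nx, g$ny, g$dx)
#' @export
tank_geometry <- function(scenario = c("cavity", "channel", "double_gyre"),
                          nx = NULL, ny = NULL,
                          x_min = NULL, x_max = NULL,
                          y_min = NULL, y_max = NULL) {
  scenario <- match.arg(scenario)
  def <- switch(scenario,
    cavity      = list(x = c(0, 10),  y = c(0, 10), nx = 81,  ny = 81),
    channel     = list(x = c(-20, 20), y = c(0, 5),  nx = 321, ny = 41),
    double_gyre = list(x = c(-5, 5),  y = c(0, 5),  nx = 81,  ny = 41))
  x_min <- x_min %||% def$x[1]; x_max <- x_max %||% def$x[2]
  y_min <- y_min %||% def$y[1]; y_max <- y_max %||% def$y[2]
  nx <- nx %||% def$nx; ny <- ny %||% def$ny
  if (nx < 3 || ny < 3) stop("need at least 3 grid nodes per direction")
  dx <- (x_max - x_min) / (nx - 1)
  dy <- (y_max - y_min) / (ny - 1)
  if (abs(dx - dy) > 1e-12 * max(dx, dy))
    stop("grid spacing must be uniform (dx == dy); got dx=", dx, " dy=", dy)
  structure(list(scenario = scenario,
                 x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max,
                 nx = nx, ny = ny, dx = dx, dy = dy),
            class = "tank_geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tank_geometry <- function(x, ...) {
  cat(sprintf("<tank_geometry: %s, [%g, %g] x [%g, %g] m, %d x %d nodes, dx = %g m>\n",
              x$scenario, x$x_min, x$x_max, x$y_min, x$y_max, x$nx, x$ny, x$dx))
  invisible(x)
}

# cell-center coordinate vectors of the (nx-1) x (ny-1) pressure/scalar grid
cell_centers <- function(geom) {
  list(x = geom$x_min + (seq_len(geom$nx - 1) - 0.5) * geom$dx,
       y = geom$y_min + (seq_len(geom$ny - 1) - 0.5) * geom$dy)
}

# node coordinate vectors (cell corners), nx x ny
node_coords <- function(geom) {
  list(x = geom$x_min + (seq_len(geom$nx) - 1) * geom$dx,
       y = geom$y_min + (seq_len(geom$ny) - 1) * geom$dy)
}

stopifnot_inside <- function(x, y, geom) {
  if (any(x < geom$x_min | x > geom$x_max | y < geom$y_min | y > geom$y_max))
    stop("position outside the tank domain")
}
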