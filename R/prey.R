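#' Create a prey concentration field
#'
#' Prey concentration `F` lives on the cell centers of the tank grid, in
#' units of the saturation level `F_0` (so values are dimensionless and
#' normally within `[0, 1]`). The field is advected by the flow and
#' diffuses with diffusivity `D_F`; walls are no-flux, so total prey mass
#' is conserved.
#'
#' @param geometry a [tank_geometry()].
#' @param F optional initial concentration matrix `(nx-1) x (ny-1)`;
#'   defaults to zero.
#' @param D_F prey diffusivity (m^2/s); default 0.001.
#' @return an object of class `prey_field`.
#' @export
prey_field <- function(geometry, F = NULL, D_F = 0.001) {
  ncx <- geometry$nx - 1L; ncy <- geometry$ny - 1L
  if (is.null(F)) F <- matrix(0, ncx, ncy)
  if (!identical(dim(F), c(ncx, ncy))) {
    if (nrow(F) != ncx || ncol(F) != ncy)
      stop("F must be a ", ncx, " x ", ncy, " matrix of cell-center values")
  }
  if (D_F < 0) stop("D_F must be non-negative")
  structure(list(F = F, D_F = D_F, geometry = geometry, time = 0),
            class = "prey_field")
}

#' Initial prey distribution for the double-gyre foraging scenario
#'
#' Prey saturates the left half of the tank (`F = 1` in units of `F_0` for
#' `x < 0`) and is absent from the right half, with the step smoothed over
#' two cells at the interface to avoid dispersive ringing.
#'
#' @param geometry a [tank_geometry()] with scenario `"double_gyre"`.
#' @param D_F prey diffusivity (m^2/s).
#' @return a `prey_field`.
#' @export
init_double_gyre_prey <- function(geometry, D_F = 0.001) {
  if (geometry$scenario != "double_gyre")
    stop("prey initialization is defined for the double_gyre scenario")
  cc <- cell_centers(geometry)
  prof <- 0.5 * (1 - tanh(cc$x / (2 * geometry$dx)))
  prey_field(geometry, F = matrix(prof, length(cc$x), length(cc$y)), D_F = D_F)
}

# van Leer limited slopes along the first dimension; G has one ghost cell
# (zero-gradient) folded in by the caller via edge replication
limited_slope <- function(a, b) {
  s <- a * b
  out <- ifelse(s > 0, 2 * s / (a + b), 0)
  out[!is.finite(out)] <- 0
  out
}

# advective flux through x-faces of a cell-centered scalar, MUSCL/van Leer
advective_flux_x <- function(F, uf) {
  ncx <- nrow(F); ncy <- ncol(F)
  Fp <- rbind(F[1L, , drop = FALSE], F, F[ncx, , drop = FALSE])  # ghosts
  dF <- Fp[2:(ncx + 2L), , drop = FALSE] - Fp[1:(ncx + 1L), , drop = FALSE]
  # slope in cell i (padded index i+1) from neighbouring differences
  slope <- limited_slope(dF[1:ncx, , drop = FALSE], dF[2:(ncx + 1L), , drop = FALSE])
  flux <- matrix(0, ncx + 1L, ncy)
  int <- 2:ncx  # interior faces; boundary faces keep zero (no-flux walls)
  upL <- F[int - 1L, , drop = FALSE] + 0.5 * slope[int - 1L, , drop = FALSE]
  upR <- F[int, , drop = FALSE] - 0.5 * slope[int, , drop = FALSE]
  uface <- uf[int, , drop = FALSE]
  flux[int, ] <- uface * ifelse(uface >= 0, upL, upR)
  # open boundaries (channel): advect through end faces first-order upwind
  flux[1L, ] <- pmin(uf[1L, ], 0) * F[1L, ]
  flux[ncx + 1L, ] <- pmax(uf[ncx + 1L, ], 0) * F[ncx, ]
  flux
}

#' Advance the prey field by one time step
#'
#' One explicit conservative step of the advection-diffusion equation:
#' second-order MUSCL advection with a van Leer slope limiter (monotone,
#' so concentrations stay non-negative) using the staggered face
#' velocities, plus central-difference diffusion. Walls are no-flux.
#'
#' @param prey a `prey_field`.
#' @param flow a `flow_field` on the same geometry, or `NULL` for still
#'   water.
#' @param dt time step (s); must satisfy the advective CFL bound
#'   `dt <= dx / max|u|` and the diffusive bound `dt <= dx^2 / (4 D_F)`.
#' @return the advanced `prey_field`.
#' @export
step_prey <- function(prey, flow = NULL, dt) {
  g <- prey$geometry
  ncx <- g$nx - 1L; ncy <- g$ny - 1L
  dx <- g$dx; dy <- g$dy
  F <- prey$F
  if (is.null(flow)) {
    uf <- matrix(0, ncx + 1L, ncy); vf <- matrix(0, ncx, ncy + 1L)
  } else {
    uf <- flow$u[, 2:(ncy + 1L), drop = FALSE]
    vf <- flow$v[2:(ncx + 1L), , drop = FALSE]
  }
  vmax <- max(abs(uf), abs(vf))
  if (vmax > 0 && dt > dx / vmax)
    stop(sprintf("prey step unstable: advective CFL requires dt <= %.4g s", dx / vmax))
  if (prey$D_F > 0 && dt > dx^2 / (4 * prey$D_F))
    stop(sprintf("prey step unstable: diffusive bound requires dt <= %.4g s",
                 dx^2 / (4 * prey$D_F)))

  adv_x <- advective_flux_x(F, uf)
  adv_y <- t(advective_flux_x(t(F), t(vf)))
  dif_x <- matrix(0, ncx + 1L, ncy)
  dif_x[2:ncx, ] <- -prey$D_F *
    (F[2:ncx, , drop = FALSE] - F[1:(ncx - 1L), , drop = FALSE]) / dx
  dif_y <- matrix(0, ncx, ncy + 1L)
  dif_y[, 2:ncy] <- -prey$D_F *
    (F[, 2:ncy, drop = FALSE] - F[, 1:(ncy - 1L), drop = FALSE]) / dy

  fx <- adv_x + dif_x; fy <- adv_y + dif_y
  prey$F <- F - dt * ((fx[2:(ncx + 1L), , drop = FALSE] - fx[1:ncx, , drop = FALSE]) / dx +
                      (fy[, 2:(ncy + 1L), drop = FALSE] - fy[, 1:ncy, drop = FALSE]) / dy)
  prey$time <- prey$time + dt
  prey
}

# cell-centered gradient matrices of the prey concentration
prey_gradient <- function(prey) {
  g <- prey$geometry
  list(gx = grad_x(prey$F, g$dx), gy = grad_y(prey$F, g$dy))
}

#' Direction of the local prey gradient
#'
#' Returns the full-quadrant angle `delta_F = atan2(dF/dy, dF/dx)` of the
#' ascending prey gradient at the given positions, the gradient magnitude,
#' and a degeneracy flag raised where the magnitude falls below
#' `threshold` (couplings that steer by `delta_F` are suppressed there).
#'
#' @param prey a `prey_field`.
#' @param x,y positions inside the tank.
#' @param threshold gradient magnitude (units `F_0`/m) below which the
#'   direction is flagged undefined; default `1e-8`.
#' @return list with vectors `angle` (rad), `magnitude` and logical
#'   `degenerate`.
#' @export
prey_direction <- function(prey, x, y, threshold = 1e-8) {
  g <- prey$geometry
  stopifnot_inside(x, y, g)
  cc <- cell_centers(g)
  gr <- prey_gradient(prey)
  org <- c(cc$x[1], cc$y[1])
  gx <- sample_field(gr$gx, x, y, origin = org, spacing = g$dx)
  gy <- sample_field(gr$gy, x, y, origin = org, spacing = g$dx)
  mag <- sqrt(gx^2 + gy^2)
  list(angle = atan2(gy, gx), magnitude = mag, degenerate = mag < threshold)
}

#' Sample the prey concentration at positions
#'
#' @param prey a `prey_field`.
#' @param x,y positions inside the tank.
#' @return vector of concentrations (units `F_0`).
#' @export
sample_prey <- function(prey, x, y) {
  g <- prey$geometry
  cc <- cell_centers(g)
  sample_field(prey$F, x, y, origin = c(cc$x[1], cc$y[1]), spacing = g$dx,
               geometry = g)
}
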