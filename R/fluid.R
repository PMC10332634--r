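#' Create a staggered-grid flow field
#'
#' Allocates the marker-and-cell (MAC) layout for a tank scenario: the
#' horizontal velocity `u` on vertical cell faces, the vertical velocity
#' `v` on horizontal cell faces and the pressure `p` on cell centers.
#' Tangential wall conditions are imposed through one layer of ghost values
#' on each side, so `u` has dimensions `nx x (ny+1)` and `v` has
#' `(nx+1) x ny` where the tank has `(nx-1) x (ny-1)` cells.
#'
#' @param geometry a [tank_geometry()].
#' @param params a [fluid_params()].
#' @param init `"zero"` for fluid at rest or `"poiseuille"` (channel only)
#'   to fill the whole channel with the analytic parabolic inflow profile.
#' @return an object of class `flow_field` with components `u`, `v`, `p`,
#'   `geometry`, `params`, `time` and the previous explicit tendency used
#'   by the two-step time scheme.
#' @seealso [step_flow()], [vorticity_fields()]
#' @export
flow_field <- function(geometry, params = fluid_params(),
                       init = c("zero", "poiseuille")) {
  init <- match.arg(init)
  ncx <- geometry$nx - 1L; ncy <- geometry$ny - 1L
  f <- structure(list(
    u = matrix(0, ncx + 1L, ncy + 2L),  # ghost cols j=1, ncy+2
    v = matrix(0, ncx + 2L, ncy + 1L),  # ghost rows i=1, ncx+2
    p = matrix(0, ncx, ncy),
    geometry = geometry, params = params, time = 0,
    tend_u = NULL, tend_v = NULL), class = "flow_field")
  if (init == "poiseuille") {
    if (geometry$scenario != "channel")
      stop("poiseuille initialization requires the channel scenario")
    yc <- geometry$y_min + (seq_len(ncy) - 0.5) * geometry$dy
    prof <- poiseuille_profile(yc, geometry, params)
    f$u[, 2:(ncy + 1L)] <- matrix(prof, ncx + 1L, ncy, byrow = TRUE)
  }
  apply_boundary_conditions(f)
}

# analytic fully developed profile at cell-row heights y
poiseuille_profile <- function(y, geometry, params) {
  H <- geometry$y_max - geometry$y_min
  s <- (y - geometry$y_min) / H
  params$inflow_peak * 4 * s * (1 - s)
}

#' Impose scenario boundary conditions
#'
#' Sets the normal wall velocities and the tangential ghost values of a
#' flow field according to its scenario: cavity (top lid moving at
#' `wall_speed` in +x, other walls no-slip), channel (fully developed
#' Poiseuille inflow at the +x end with peak `inflow_peak`, zero-gradient
#' outflow at the -x end, no-slip side walls) or double gyre (left and
#' right walls moving at `wall_speed` in +y, top and bottom no-slip).
#'
#' @param field a `flow_field`.
#' @param geometry,params optional overrides; default to those stored in
#'   the field.
#' @return the field with boundary and ghost values refreshed.
#' @export
apply_boundary_conditions <- function(field, geometry = field$geometry,
                                      params = field$params) {
  ncx <- geometry$nx - 1L; ncy <- geometry$ny - 1L
  u <- field$u; v <- field$v
  jc <- 2:(ncy + 1L)   # physical u columns
  ir <- 2:(ncx + 1L)   # physical v rows
  if (geometry$scenario == "cavity") {
    u[1L, jc] <- 0; u[ncx + 1L, jc] <- 0          # left/right walls sealed
    v[ir, 1L] <- 0; v[ir, ncy + 1L] <- 0          # bottom/top sealed
    u[, 1L] <- -u[, 2L]                           # bottom no-slip
    u[, ncy + 2L] <- 2 * params$wall_speed - u[, ncy + 1L]  # moving lid
    v[1L, ] <- -v[2L, ]                           # left no-slip
    v[ncx + 2L, ] <- -v[ncx + 1L, ]               # right no-slip
  } else if (geometry$scenario == "double_gyre") {
    u[1L, jc] <- 0; u[ncx + 1L, jc] <- 0
    v[ir, 1L] <- 0; v[ir, ncy + 1L] <- 0
    u[, 1L] <- -u[, 2L]                           # bottom no-slip
    u[, ncy + 2L] <- -u[, ncy + 1L]               # top no-slip
    v[1L, ] <- 2 * params$wall_speed - v[2L, ]    # left wall moving +y
    v[ncx + 2L, ] <- 2 * params$wall_speed - v[ncx + 1L, ]  # right wall +y
  } else if (geometry$scenario == "channel") {
    yc <- geometry$y_min + (seq_len(ncy) - 0.5) * geometry$dy
    u[ncx + 1L, jc] <- poiseuille_profile(yc, geometry, params)  # inlet (+x end)
    u[1L, jc] <- u[2L, jc]                        # zero-gradient outflow
    v[ir, 1L] <- 0; v[ir, ncy + 1L] <- 0          # side walls sealed
    u[, 1L] <- -u[, 2L]                           # bottom no-slip
    u[, ncy + 2L] <- -u[, ncy + 1L]               # top no-slip
    v[1L, ] <- v[2L, ]                            # outflow zero-gradient
    v[ncx + 2L, ] <- -v[ncx + 1L, ]               # inlet: no transverse flow
  } else stop("unknown scenario: ", geometry$scenario)
  field$u <- u; field$v <- v
  field
}

# discrete divergence on cell centers, ncx x ncy
flow_divergence <- function(field) {
  g <- field$geometry
  ncx <- g$nx - 1L; ncy <- g$ny - 1L
  u <- field$u; v <- field$v
  (u[2:(ncx + 1L), 2:(ncy + 1L), drop = FALSE] -
     u[1:ncx, 2:(ncy + 1L), drop = FALSE]) / g$dx +
  (v[2:(ncx + 1L), 2:(ncy + 1L), drop = FALSE] -
     v[2:(ncx + 1L), 1:ncy, drop = FALSE]) / g$dy
}

# red-black SOR for  lap(p) = rhs  with Neumann walls (channel: p = 0 at the
# outflow face). Returns list(p, iters, residual).
sor_pressure_solve <- function(rhs, geometry, params, p0 = NULL) {
  ncx <- nrow(rhs); ncy <- ncol(rhs)
  dx2 <- geometry$dx^2
  p <- if (is.null(p0)) matrix(0, ncx, ncy) else p0
  omega <- params$sor_omega
  outflow_dirichlet <- geometry$scenario == "channel"
  ii <- matrix(seq_len(ncx), ncx, ncy)
  jj <- matrix(seq_len(ncy), ncx, ncy, byrow = TRUE)
  red <- (ii + jj) %% 2L == 0L
  rhs_norm <- sqrt(mean(rhs^2))
  scale <- max(rhs_norm, 1e-30)

  pad <- function(p) {
    # edge replication encodes dp/dn = 0; outflow west face gets p = 0
    P <- matrix(0, ncx + 2L, ncy + 2L)
    P[2:(ncx + 1L), 2:(ncy + 1L)] <- p
    P[1L, 2:(ncy + 1L)] <- if (outflow_dirichlet) -p[1L, ] else p[1L, ]
    P[ncx + 2L, 2:(ncy + 1L)] <- p[ncx, ]
    P[2:(ncx + 1L), 1L] <- p[, 1L]
    P[2:(ncx + 1L), ncy + 2L] <- p[, ncy]
    P
  }
  nb_sum <- function(P) {
    P[1:ncx, 2:(ncy + 1L)] + P[3:(ncx + 2L), 2:(ncy + 1L)] +
      P[2:(ncx + 1L), 1:ncy] + P[2:(ncx + 1L), 3:(ncy + 2L)]
  }
  for (it in seq_len(params$sor_max_iter)) {
    for (mask in list(red, !red)) {
      P <- pad(p)
      gs <- (nb_sum(P) - dx2 * rhs) / 4
      p[mask] <- (1 - omega) * p[mask] + omega * gs[mask]
    }
    if (!outflow_dirichlet) p <- p - mean(p)  # pin the Neumann null space
    P <- pad(p)
    resid <- (nb_sum(P) - 4 * p) / dx2 - rhs
    res_norm <- sqrt(mean(resid^2))
    if (res_norm <= params$sor_tol * scale)
      return(list(p = p, iters = it, residual = res_norm))
  }
  stop(sprintf(
    "SOR pressure solve did not converge in %d iterations (residual %.3e, target %.3e)",
    params$sor_max_iter, res_norm, params$sor_tol * scale))
}

# explicit advection + diffusion tendencies on interior faces
flow_tendency <- function(field) {
  g <- field$geometry
  ncx <- g$nx - 1L; ncy <- g$ny - 1L
  dx <- g$dx; dy <- g$dy
  nu <- field$params$mu / field$params$rho
  u <- field$u; v <- field$v

  # u faces, interior i = 2..ncx, columns j = 2..ncy+1
  i <- 2:ncx; j <- 2:(ncy + 1L)
  uc <- u[i, j, drop = FALSE]
  dudx <- (u[i + 1L, j, drop = FALSE] - u[i - 1L, j, drop = FALSE]) / (2 * dx)
  dudy <- (u[i, j + 1L, drop = FALSE] - u[i, j - 1L, drop = FALSE]) / (2 * dy)
  vbar <- (v[i, j - 1L, drop = FALSE] + v[i + 1L, j - 1L, drop = FALSE] +
           v[i, j, drop = FALSE] + v[i + 1L, j, drop = FALSE]) / 4
  lap_u <- (u[i + 1L, j, drop = FALSE] - 2 * uc + u[i - 1L, j, drop = FALSE]) / dx^2 +
           (u[i, j + 1L, drop = FALSE] - 2 * uc + u[i, j - 1L, drop = FALSE]) / dy^2
  Tu <- -(uc * dudx + vbar * dudy) + nu * lap_u

  # v faces, interior rows a = 2..ncx+1, b = 2..ncy
  a <- 2:(ncx + 1L); b <- 2:ncy
  vc <- v[a, b, drop = FALSE]
  dvdx <- (v[a + 1L, b, drop = FALSE] - v[a - 1L, b, drop = FALSE]) / (2 * dx)
  dvdy <- (v[a, b + 1L, drop = FALSE] - v[a, b - 1L, drop = FALSE]) / (2 * dy)
  ubar <- (u[a - 1L, b, drop = FALSE] + u[a, b, drop = FALSE] +
           u[a - 1L, b + 1L, drop = FALSE] + u[a, b + 1L, drop = FALSE]) / 4
  lap_v <- (v[a + 1L, b, drop = FALSE] - 2 * vc + v[a - 1L, b, drop = FALSE]) / dx^2 +
           (v[a, b + 1L, drop = FALSE] - 2 * vc + v[a, b - 1L, drop = FALSE]) / dy^2
  Tv <- -(ubar * dvdx + vc * dvdy) + nu * lap_v

  list(u = Tu, v = Tv)
}

#' Advance the flow by one fluid time step
#'
#' One step of the second-order scheme: an explicit Adams-Bashforth-2
#' advection-diffusion predictor (forward Euler on the first step), a
#' successive over-relaxation solve of the pressure Poisson equation and a
#' projection that returns the velocity to a discretely divergence-free
#' state. Boundary conditions are re-imposed before and after projection.
#'
#' @param field a `flow_field`.
#' @param params,geometry optional overrides of the stored parameters.
#' @return the advanced `flow_field`; `field$time` is incremented by
#'   `dt_fluid` and attribute fields record the SOR iteration count.
#' @export
step_flow <- function(field, params = field$params, geometry = field$geometry) {
  field$params <- params; field$geometry <- geometry
  dt <- params$dt_fluid
  ncx <- geometry$nx - 1L; ncy <- geometry$ny - 1L
  vmax <- max(abs(field$u), abs(field$v))
  if (vmax * dt / geometry$dx > 1)
    stop(sprintf("CFL violation: max|u| dt/dx = %.3f > 1", vmax * dt / geometry$dx))

  field <- apply_boundary_conditions(field)
  tend <- flow_tendency(field)
  if (is.null(field$tend_u)) {
    du <- tend$u; dv <- tend$v                       # first step: Euler
  } else {
    du <- 1.5 * tend$u - 0.5 * field$tend_u          # Adams-Bashforth-2
    dv <- 1.5 * tend$v - 0.5 * field$tend_v
  }
  field$tend_u <- tend$u; field$tend_v <- tend$v

  i <- 2:ncx; j <- 2:(ncy + 1L)
  field$u[i, j] <- field$u[i, j] + dt * du
  a <- 2:(ncx + 1L); b <- 2:ncy
  field$v[a, b] <- field$v[a, b] + dt * dv
  field <- apply_boundary_conditions(field)

  div <- flow_divergence(field)
  sol <- sor_pressure_solve(div * params$rho / dt, geometry, params, p0 = field$p)
  p <- sol$p
  # project interior faces; boundary normal velocities stay prescribed
  field$u[i, j] <- field$u[i, j] -
    dt / params$rho * (p[i, ] - p[i - 1L, ]) / geometry$dx
  field$v[a, b] <- field$v[a, b] -
    dt / params$rho * (p[a - 1L, b] - p[a - 1L, b - 1L]) / geometry$dy
  field$p <- p
  field <- apply_boundary_conditions(field)
  field$time <- field$time + dt
  field$sor_iters <- sol$iters
  field$sor_residual <- sol$residual
  field
}

#' Advance the flow over an interval
#'
#' Convenience wrapper calling [step_flow()] until `t_end` (relative to the
#' field's current time) is reached.
#'
#' @param field a `flow_field`.
#' @param t_end duration to integrate (s).
#' @return the advanced field.
#' @export
spin_up_flow <- function(field, t_end) {
  n <- round(t_end / field$params$dt_fluid)
  for (k in seq_len(n)) field <- step_flow(field)
  field
}

#' Vorticity magnitude and its gradient
#'
#' Computes the scalar vorticity `C = dv/dx - du/dy` at the grid nodes by
#' central differencing of the staggered face velocities (the ghost layers
#' make the same stencil valid up to the walls), then `|C|` and the
#' gradient of `|C|` (central differences in the interior, one-sided at
#' boundary nodes).
#'
#' @param field a `flow_field`.
#' @return list with node matrices (`nx x ny`): `C`, `absC`, `dabsC_dx`,
#'   `dabsC_dy`.
#' @export
vorticity_fields <- function(field) {
  g <- field$geometry
  nx <- g$nx; ny <- g$ny
  u <- field$u; v <- field$v
  # node (i, j): dv/dx from v rows i, i+1 (ghost-aware), du/dy from u cols j, j+1
  dvdx <- (v[2:(nx + 1L), , drop = FALSE] - v[1:nx, , drop = FALSE]) / g$dx
  dudy <- (u[, 2:(ny + 1L), drop = FALSE] - u[, 1:ny, drop = FALSE]) / g$dy
  C <- dvdx - dudy
  absC <- abs(C)
  list(C = C, absC = absC,
       dabsC_dx = grad_x(absC, g$dx), dabsC_dy = grad_y(absC, g$dy))
}

grad_x <- function(M, dx) {
  n <- nrow(M)
  G <- M
  if (n >= 3) G[2:(n - 1L), ] <- (M[3:n, , drop = FALSE] - M[1:(n - 2L), , drop = FALSE]) / (2 * dx)
  G[1L, ] <- (M[2L, ] - M[1L, ]) / dx
  G[n, ] <- (M[n, ] - M[n - 1L, ]) / dx
  G
}

grad_y <- function(M, dy) t(grad_x(t(M), dy))

# cell-centered velocity components (ncx x ncy), for sampling and export
flow_at_centers <- function(field) {
  g <- field$geometry
  ncx <- g$nx - 1L; ncy <- g$ny - 1L
  list(u = (field$u[1:ncx, 2:(ncy + 1L), drop = FALSE] +
              field$u[2:(ncx + 1L), 2:(ncy + 1L), drop = FALSE]) / 2,
       v = (field$v[2:(ncx + 1L), 1:ncy, drop = FALSE] +
              field$v[2:(ncx + 1L), 2:(ncy + 1L), drop = FALSE]) / 2)
}

#' Build a frozen flow snapshot from a stream function
#'
#' Fills the staggered faces from differences of a node-valued stream
#' function `psi`: `u = d(psi)/dy`, `v = -d(psi)/dx`. The resulting field
#' is discretely divergence-free by construction, which makes it a
#' convenient analytic stand-in for a solver snapshot (for example a
#' double-gyre pattern) when driving agent ensembles. A `psi` that
#' vanishes on the boundary gives sealed walls. The snapshot is meant to
#' be replayed frozen, not stepped.
#'
#' @param geometry a [tank_geometry()].
#' @param psi function `psi(x, y)` (vectorized) or an `nx x ny` matrix of
#'   node values (m^2/s).
#' @return a `flow_field` with the prescribed velocities and zero
#'   pressure.
#' @export
stream_function_flow <- function(geometry, psi) {
  g <- geometry
  ncx <- g$nx - 1L; ncy <- g$ny - 1L
  if (is.function(psi)) {
    nd <- node_coords(g)
    psi <- outer(nd$x, nd$y, psi)
  }
  if (!all(dim(psi) == c(g$nx, g$ny)))
    stop("psi must be an nx x ny node matrix")
  f <- structure(list(
    u = matrix(0, ncx + 1L, ncy + 2L),
    v = matrix(0, ncx + 2L, ncy + 1L),
    p = matrix(0, ncx, ncy),
    geometry = g, params = fluid_params(), time = 0,
    tend_u = NULL, tend_v = NULL), class = "flow_field")
  f$u[, 2:(ncy + 1L)] <- (psi[, 2:g$ny, drop = FALSE] -
                            psi[, 1:ncy, drop = FALSE]) / g$dy
  f$v[2:(ncx + 1L), ] <- -(psi[2:g$nx, , drop = FALSE] -
                             psi[1:ncx, , drop = FALSE]) / g$dx
  f$u[, 1L] <- f$u[, 2L]; f$u[, ncy + 2L] <- f$u[, ncy + 1L]
  f$v[1L, ] <- f$v[2L, ]; f$v[ncx + 2L, ] <- f$v[ncx + 1L, ]
  f
}
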