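test_that("still water with stationary walls is an exact fixed point", {
  g <- tank_geometry("cavity", nx = 17, ny = 17)
  f <- flow_field(g, fluid_params(wall_speed = 0))
  expect_equal(max(abs(f$u)), 0)
  for (k in 1:10) f <- step_flow(f)
  expect_equal(max(abs(f$u)), 0)
  expect_equal(max(abs(f$v)), 0)
})

test_that("scenario boundary conditions match the driving speeds", {
  pf <- fluid_params()
  # cavity: lid tangential velocity is +0.4 m/s (ghost-midpoint value)
  g <- tank_geometry("cavity", nx = 17, ny = 17)
  f <- flow_field(g, pf)
  ncy <- g$ny - 1L
  lid_tangential <- (f$u[, ncy + 1L] + f$u[, ncy + 2L]) / 2
  expect_equal(unname(lid_tangential), rep(0.4, nrow(f$u)))
  # channel inlet: parabolic profile with peak -0.045 at mid-height
  gc <- tank_geometry("channel")
  fc <- flow_field(gc, pf)
  inlet <- fc$u[gc$nx - 1L + 1L, 2:(gc$ny)]
  expect_equal(min(inlet), -0.045, tolerance = 1e-3)
  yc <- gc$y_min + (seq_len(gc$ny - 1L) - 0.5) * gc$dy
  H <- gc$y_max - gc$y_min
  expect_equal(unname(inlet), -0.045 * 4 * (yc / H) * (1 - yc / H))
  # double gyre: both side walls move upward at +0.4
  gd <- tank_geometry("double_gyre", nx = 17, ny = 9)
  fd <- flow_field(gd, pf)
  left_tang <- (fd$v[1L, ] + fd$v[2L, ]) / 2
  right_tang <- (fd$v[nrow(fd$v) - 1L, ] + fd$v[nrow(fd$v), ]) / 2
  expect_equal(unname(left_tang), rep(0.4, ncol(fd$v)))
  expect_equal(unname(right_tang), rep(0.4, ncol(fd$v)))
  # all-stationary variant: every boundary velocity zero
  f0 <- flow_field(g, fluid_params(wall_speed = 0))
  expect_equal(max(abs(f0$u)), 0)
  expect_equal(max(abs(f0$v)), 0)
})

test_that("projection leaves the field divergence-free", {
  g <- tank_geometry("cavity", nx = 25, ny = 25)
  f <- flow_field(g)
  set.seed(11)
  # perturb the interior away from any solenoidal state
  f$u[2:24, 2:25] <- f$u[2:24, 2:25] + 0.05 * matrix(rnorm(23 * 24), 23, 24)
  f$v[2:25, 2:24] <- f$v[2:25, 2:24] + 0.05 * matrix(rnorm(24 * 23), 24, 23)
  div_pre <- max(abs(medusim:::flow_divergence(apply_boundary_conditions(f))))
  f <- step_flow(f)
  div <- max(abs(medusim:::flow_divergence(f)))
  # the SOR tolerance (1e-4 relative) bounds the residual divergence
  expect_lt(div, 1e-2 * div_pre)
  for (k in 1:5) f <- step_flow(f)
  expect_lt(max(abs(medusim:::flow_divergence(f))), 1e-5)
})

test_that("the analytic Poiseuille profile is a steady channel state", {
  g <- tank_geometry("channel", nx = 81, ny = 21,
                     x_min = -5, x_max = 5, y_min = 0, y_max = 2.5)
  f <- flow_field(g, init = "poiseuille")
  u0 <- f$u
  for (k in 1:500) f <- step_flow(f)
  expect_lt(max(abs(f$u - u0)) / 0.045, 1e-3)
  expect_lt(max(abs(f$v)), 1e-4)
})

test_that("a lid moving rightward spins up a clockwise primary gyre", {
  f <- cavity_snapshot()
  vort <- vorticity_fields(f)
  expect_lt(mean(vort$C), 0)  # clockwise = negative scalar vorticity
  # and the flow is nontrivial
  expect_gt(max(abs(f$u)), 0.05)
})

test_that("vorticity of canonical fields matches hand differentiation", {
  g <- tank_geometry("cavity", nx = 21, ny = 21)
  nd <- medusim:::node_coords(g)
  f <- flow_field(g)
  ncx <- g$nx - 1L; ncy <- g$ny - 1L
  # rigid-body rotation about the tank center: C = 2 omega, grad|C| = 0
  omega <- 0.3
  xc <- 5; yc <- 5
  yu <- g$y_min + (seq_len(ncy + 2L) - 1.5) * g$dy
  f$u <- outer(nd$x, yu, function(x, y) -omega * (y - yc))
  xv <- g$x_min + (seq_len(ncx + 2L) - 1.5) * g$dx
  f$v <- outer(xv, nd$y, function(x, y) omega * (x - xc))
  vort <- vorticity_fields(f)
  expect_equal(vort$C, matrix(2 * omega, g$nx, g$ny), tolerance = 1e-12)
  expect_equal(max(abs(vort$dabsC_dx)), 0, tolerance = 1e-9)
  # pure shear u = gamma * y: C = -gamma
  gam <- 0.7
  f$u <- outer(nd$x, yu, function(x, y) gam * y)
  f$v[] <- 0
  vort <- vorticity_fields(f)
  expect_equal(vort$C, matrix(-gam, g$nx, g$ny), tolerance = 1e-12)
  # zero field
  f$u[] <- 0
  expect_equal(vorticity_fields(f)$C, matrix(0, g$nx, g$ny))
})

test_that("advection-diffusion stencil is second-order accurate", {
  # manufactured smooth solenoidal field on the unit square
  tend_error <- function(nx) {
    g <- tank_geometry("cavity", nx = nx, ny = nx, x_min = 0, x_max = 1,
                       y_min = 0, y_max = 1)
    pf <- fluid_params(rho = 1, mu = 0.01)
    f <- flow_field(g, pf)
    ncx <- nx - 1L
    nd <- medusim:::node_coords(g)
    yu <- g$y_min + (seq_len(ncx + 2L) - 1.5) * g$dy
    xv <- g$x_min + (seq_len(ncx + 2L) - 1.5) * g$dx
    uf <- function(x, y) sin(pi * x) * cos(pi * y)
    vf <- function(x, y) -cos(pi * x) * sin(pi * y)
    f$u <- outer(nd$x, yu, uf)
    f$v <- outer(xv, nd$y, vf)
    tend <- medusim:::flow_tendency(f)
    nu <- 0.01
    exact_u <- function(x, y) {
      u <- uf(x, y); v <- vf(x, y)
      dudx <- pi * cos(pi * x) * cos(pi * y)
      dudy <- -pi * sin(pi * x) * sin(pi * y)
      -(u * dudx + v * dudy) + nu * (-2 * pi^2 * u)
    }
    i <- 2:(nx - 1L); j <- 2:nx
    ex <- outer(nd$x[i], yu[j], exact_u)
    max(abs(tend$u - ex))
  }
  e1 <- tend_error(17)
  e2 <- tend_error(33)
  expect_gt(e1 / e2, 3.2)  # ~4x per halving for a second-order stencil
})

test_that("Reynolds number reproduces the printed flow regimes", {
  pf <- fluid_params()
  expect_equal(reynolds_number(pf, 0.045, 40), 4500)
  expect_equal(reynolds_number(pf, 0, 10), 0)
  expect_equal(reynolds_number(pf, 0.4, 10), 1e4)
  expect_error(reynolds_number(pf, 0.1, -1), "positive")
})

test_that("CFL violations and bad scenarios are rejected", {
  g <- tank_geometry("cavity", nx = 9, ny = 9)
  f <- flow_field(g, fluid_params(dt_fluid = 10))
  expect_error(step_flow(f), "CFL")
  g$scenario <- "vortex_street"
  expect_error(apply_boundary_conditions(flow_field(tank_geometry("cavity",
    nx = 9, ny = 9)), geometry = g), "unknown scenario")
})

test_that("stream-function snapshots are discretely divergence-free", {
  f <- double_gyre_snapshot(nx = 41, ny = 21)
  expect_lt(max(abs(medusim:::flow_divergence(f))), 1e-12)
  # walls sealed: psi vanishes on the boundary
  expect_equal(max(abs(f$u[1L, 2:20])), 0)
  expect_equal(max(abs(f$v[2:40, c(1L, 21L)])), 0)
})
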