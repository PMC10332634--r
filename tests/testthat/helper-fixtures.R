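# Fixtures built in code: lattices, toy flows, and a memoized spun-up
# cavity snapshot shared by the slower scenario tests.

# hexagonal lattice of m rows x m columns, spacing a
hex_lattice <- function(m = 8, a = 1) {
  rows <- lapply(seq_len(m), function(r) {
    x <- (seq_len(m) - 1) * a + (r %% 2) * a / 2
    cbind(x = x, y = (r - 1) * a * sqrt(3) / 2)
  })
  do.call(rbind, rows)
}

square_lattice <- function(m = 6, a = 1) {
  g <- expand.grid(x = (seq_len(m) - 1) * a, y = (seq_len(m) - 1) * a)
  as.matrix(g)
}

# gentle non-uniform toy flow with variance in both components
toy_env <- function(geom) {
  function(x, y) {
    medusim:::env_list(
      Ux = 0.02 + 0.01 * sin(2 * pi * y / (geom$y_max - geom$y_min)),
      Uy = 0.01 * cos(2 * pi * x / (geom$x_max - geom$x_min)),
      absC = numeric(length(x)), dCx = numeric(length(x)),
      dCy = numeric(length(x)), F = numeric(length(x)),
      gFx = numeric(length(x)), gFy = numeric(length(x)))
  }
}

# toy environment in still water with a prescribed turbulent band: |C| is
# high above the midline; the reported |C| gradient points up everywhere,
# so avoiders should steer towards the calm bottom half
band_env <- function(geom, C_hi = 1, C_lo = 0, slope_width = 1) {
  ymid <- (geom$y_min + geom$y_max) / 2
  function(x, y) {
    s <- pmin(pmax((y - ymid) / slope_width + 0.5, 0), 1)
    n <- length(x)
    medusim:::env_list(
      Ux = numeric(n), Uy = numeric(n),
      absC = C_lo + (C_hi - C_lo) * s,
      dCx = numeric(n),
      dCy = rep((C_hi - C_lo) / slope_width, n),
      F = numeric(n), gFx = numeric(n), gFy = numeric(n))
  }
}

# analytic double-gyre snapshot: two counter-rotating gyres split at x = 0
double_gyre_snapshot <- function(nx = 81, ny = 41, U0 = 0.1) {
  g <- tank_geometry("double_gyre", nx = nx, ny = ny)
  Lx <- g$x_max - g$x_min; Ly <- g$y_max - g$y_min
  psi0 <- U0 * Ly / pi
  stream_function_flow(g, function(x, y)
    psi0 * sin(2 * pi * (x - g$x_min) / Lx) * sin(pi * (y - g$y_min) / Ly))
}

# memoized coarse lid-driven cavity snapshot (shared across tests)
.fixture_cache <- new.env(parent = emptyenv())
cavity_snapshot <- function() {
  if (is.null(.fixture_cache$cavity)) {
    g <- tank_geometry("cavity", nx = 41, ny = 41)
    f <- flow_field(g, fluid_params(dt_fluid = 0.002))
    .fixture_cache$cavity <- spin_up_flow(f, 20)
  }
  .fixture_cache$cavity
}
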