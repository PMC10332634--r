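#' Model reductions as parameter presets
#'
#' Convenience constructors for the standard reductions of the full agent
#' model, built by toggling mechanisms of [model_params()]:
#' \describe{
#'   \item{`params_passive()`}{pure tracers, `dx/dt = U + F_wall`.}
#'   \item{`params_repulsive()`}{tracers plus the soft-core repulsion.}
#'   \item{`params_counter_current()`}{rheotaxis model: advection, bell
#'     pulsed propulsion with the flow-speed response, repulsion, walls,
#'     colored angular noise and the single flow-alignment coupling.}
#'   \item{`params_turbulence()`}{adds the vorticity-avoidance coupling.}
#'   \item{`params_foraging()`}{the full model, with mechanism subsets
#'     `"A"` (frequency + noise responses), `"B"` (activity switch-off of
#'     turbulence avoidance, with `f_C = 0.02`), `"C"` (speed response to
#'     activity) and `"D"` (everything, at the calibrated defaults).}
#' }
#' @param ... overrides passed to [model_params()].
#' @param mechanisms for `params_foraging()`: character subset of
#'   `c("A", "B", "C")`, or `"D"` for the full response dynamics.
#' @return a [model_params()] object.
#' @name presets
NULL

#' @rdname presets
#' @export
params_passive <- function(...) {
  model_params(enable_propulsion = FALSE, enable_repulsion = FALSE,
               enable_counter_current = FALSE,
               enable_turbulence_avoidance = FALSE,
               enable_prey_orientation = FALSE, enable_activity = FALSE,
               enable_freq_response = FALSE, enable_noise_response = FALSE,
               enable_speed_response = FALSE, ...)
}

#' @rdname presets
#' @export
params_repulsive <- function(...) {
  p <- params_passive(...)
  p$enable_repulsion <- TRUE
  p
}

#' @rdname presets
#' @export
params_counter_current <- function(...) {
  model_params(enable_turbulence_avoidance = FALSE,
               enable_prey_orientation = FALSE, enable_activity = FALSE,
               enable_freq_response = FALSE, enable_noise_response = FALSE,
               enable_speed_response = FALSE, ...)
}

#' @rdname presets
#' @export
params_turbulence <- function(...) {
  model_params(enable_prey_orientation = FALSE, enable_activity = FALSE,
               enable_freq_response = FALSE, enable_noise_response = FALSE,
               enable_speed_response = FALSE, ...)
}

#' @rdname presets
#' @export
params_foraging <- function(mechanisms = "D", ...) {
  if (identical(mechanisms, "D")) return(model_params(...))
  stopifnot(all(mechanisms %in% c("A", "B", "C")))
  extra <- list(...)
  args <- list(enable_prey_orientation = FALSE,
               enable_counter_current = TRUE,
               enable_activity = TRUE,
               enable_freq_response = "A" %in% mechanisms,
               enable_noise_response = "A" %in% mechanisms,
               enable_speed_response = "C" %in% mechanisms)
  if ("B" %in% mechanisms) {
    args$enable_turbulence_avoidance <- TRUE
    if (is.null(extra$f_C)) args$f_C <- 0.02
  } else {
    # without the switch-off response the avoidance term stays at eps_C0
    args$enable_turbulence_avoidance <- TRUE
    args$f_C <- 1e12   # effectively constant eps_C
  }
  do.call(model_params, utils::modifyList(args, extra))
}

#' Simulation run configuration
#'
#' @param scenario tank scenario tag (see [tank_geometry()]).
#' @param params a [model_params()].
#' @param fluid a [fluid_params()].
#' @param N number of agents; 128 by default.
#' @param K number of ensemble repetitions; 16 by default.
#' @param dt_agent agent integration step (s).
#' @param record_every record interval (s); 0.1 by default.
#' @param t_total simulated duration (s).
#' @param seed master seed; per-run seeds are derived from it.
#' @param flow `"analytic"`, `"frozen"` or `"live"`; analytic runs use a
#'   closed-form profile (still water, uniform or Poiseuille), frozen runs
#'   replay a precomputed `flow_field` snapshot, live runs step the CFD
#'   solver alongside the agents.
#' @param init_region `"tank"` (uniform over the whole tank) or
#'   `"right_half"` (`x > 0`, the foraging initial condition).
#' @param twin `"none"`, `"passive"` or `"repulsive"`: the reduced twin
#'   ensemble integrated with identical initial positions.
#' @param geometry optional [tank_geometry()] override.
#' @return an object of class `run_config`.
#' @export
run_config <- function(scenario = "cavity", params = model_params(),
                       fluid = fluid_params(), N = 128, K = 16,
                       dt_agent = 0.001, record_every = 0.1, t_total = 300,
                       seed = 1L, flow = c("analytic", "frozen", "live"),
                       init_region = c("tank", "right_half"),
                       twin = c("passive", "none", "repulsive"),
                       geometry = NULL) {
  flow <- match.arg(flow)
  init_region <- match.arg(init_region)
  twin <- match.arg(twin)
  if (N < 1 || K < 1) stop("N and K must be at least 1")
  if (dt_agent <= 0 || t_total <= 0) stop("dt_agent and t_total must be positive")
  if (record_every < dt_agent) stop("record_every must be >= dt_agent")
  structure(list(scenario = scenario, params = params, fluid = fluid,
                 N = as.integer(N), K = as.integer(K), dt_agent = dt_agent,
                 record_every = record_every, t_total = t_total,
                 seed = as.integer(seed), flow = flow,
                 init_region = init_region, twin = twin,
                 geometry = geometry %||% tank_geometry(scenario)),
            class = "run_config")
}

#' Initialize an agent ensemble
#'
#' Positions uniform over the initialization region, orientations and bell
#' phases uniform on the circle, activity zero, and the angular drift
#' drawn from its stationary distribution `N(0, D(0)/lambda_theta)`.
#'
#' @param N number of agents.
#' @param geometry a [tank_geometry()].
#' @param params a [model_params()].
#' @param region `"tank"` or `"right_half"`.
#' @return a list of state vectors `x, y, theta, phi, A, L`.
#' @export
init_agents <- function(N, geometry, params, region = "tank") {
  xlo <- if (region == "right_half") max(geometry$x_min, 0) else geometry$x_min
  eps <- 1e-3 * geometry$dx
  list(x = stats::runif(N, xlo + eps, geometry$x_max - eps),
       y = stats::runif(N, geometry$y_min + eps, geometry$y_max - eps),
       theta = stats::runif(N, -pi, pi),
       phi = stats::runif(N, 0, 2 * pi),
       A = rep(0, N),
       L = stats::rnorm(N, sd = sqrt(params$D_0 / params$lambda_theta)))
}

#' Analytic flow environment samplers
#'
#' Closed-form local environments for driving agents without the CFD
#' solver: `"still"` (no flow), `"uniform"` (constant velocity) and
#' `"poiseuille"` (the steady channel profile, with its analytic absolute
#' shear vorticity and vorticity gradient).
#'
#' @param type one of `"still"`, `"uniform"`, `"poiseuille"`.
#' @param geometry a [tank_geometry()] (needed for `"poiseuille"`).
#' @param fluid a [fluid_params()] (peak inflow for `"poiseuille"`).
#' @param Ux,Uy components for `"uniform"`.
#' @return an environment sampler: `function(x, y)` returning the local
#'   environment list used by [heun_step()].
#' @export
env_analytic <- function(type = c("still", "uniform", "poiseuille"),
                         geometry = NULL, fluid = fluid_params(),
                         Ux = 0, Uy = 0) {
  type <- match.arg(type)
  if (type == "still") { Ux <- 0; Uy <- 0; type <- "uniform" }
  if (type == "uniform") {
    force(Ux); force(Uy)
    return(function(x, y) {
      n <- length(x)
      env_list(rep(Ux, n), rep(Uy, n), absC = numeric(n),
               dCx = numeric(n), dCy = numeric(n),
               F = numeric(n), gFx = numeric(n), gFy = numeric(n))
    })
  }
  if (is.null(geometry)) stop("poiseuille environment needs a geometry")
  H <- geometry$y_max - geometry$y_min
  peak <- fluid$inflow_peak
  function(x, y) {
    s <- (y - geometry$y_min) / H
    u <- peak * 4 * s * (1 - s)
    dudy <- peak * 4 * (1 - 2 * s) / H
    absC <- abs(dudy)                        # C = -du/dy for unidirectional flow
    # d|C|/dy = -sign(dudy) * 8 peak / H^2 (piecewise; zero at centerline)
    dCy <- -sign(dudy) * 8 * peak / H^2
    n <- length(x)
    env_list(u, rep(0, n), absC = absC, dCx = numeric(n), dCy = dCy,
             F = numeric(n), gFx = numeric(n), gFy = numeric(n))
  }
}

# assemble the LocalEnvironment vectors: velocities, |C| and gradients of
# |C| and F, plus full-quadrant direction angles and degeneracy flags
env_list <- function(Ux, Uy, absC, dCx, dCy, F, gFx, gFy, tiny = 1e-8) {
  Umag <- sqrt(Ux^2 + Uy^2)
  gC <- sqrt(dCx^2 + dCy^2)
  gF <- sqrt(gFx^2 + gFy^2)
  list(Ux = Ux, Uy = Uy, Umag = Umag,
       delta_U = atan2(Uy, Ux), deg_U = Umag < tiny,
       absC = absC,
       delta_C = atan2(dCy, dCx), deg_C = gC < tiny,
       F = F, gradF_mag = gF,
       delta_F = atan2(gFy, gFx), deg_F = gF < tiny)
}

#' Grid-based environment sampler
#'
#' Builds a sampler closure over a (frozen) flow field and an optional
#' prey field: velocities are interpolated bilinearly from their staggered
#' face grids, the vorticity magnitude and its gradient from the node
#' grid, and the prey concentration and gradient from the cell-center
#' grid.
#'
#' @param flow a `flow_field` or `NULL` for still water.
#' @param prey a `prey_field` or `NULL`.
#' @param geometry required if both fields are `NULL`.
#' @return an environment sampler `function(x, y)`.
#' @export
env_from_fields <- function(flow = NULL, prey = NULL, geometry = NULL) {
  g <- geometry %||% (if (!is.null(flow)) flow$geometry else prey$geometry)
  if (is.null(g)) stop("need a flow field, a prey field or a geometry")
  vort <- if (!is.null(flow)) vorticity_fields(flow) else NULL
  nodes <- node_coords(g)
  cc <- cell_centers(g)
  gr <- if (!is.null(prey)) prey_gradient(prey) else NULL
  norg <- c(nodes$x[1], nodes$y[1])
  corg <- c(cc$x[1], cc$y[1])
  function(x, y) {
    n <- length(x)
    if (!is.null(flow)) {
      vel <- sample_flow_velocity(flow, x, y)
      absC <- sample_field(vort$absC, x, y, norg, g$dx)
      dCx <- sample_field(vort$dabsC_dx, x, y, norg, g$dx)
      dCy <- sample_field(vort$dabsC_dy, x, y, norg, g$dx)
    } else {
      vel <- list(u = numeric(n), v = numeric(n))
      absC <- dCx <- dCy <- numeric(n)
    }
    if (!is.null(prey)) {
      F <- sample_field(prey$F, x, y, corg, g$dx)
      gFx <- sample_field(gr$gx, x, y, corg, g$dx)
      gFy <- sample_field(gr$gy, x, y, corg, g$dx)
    } else {
      F <- gFx <- gFy <- numeric(n)
    }
    env_list(vel$u, vel$v, absC, dCx, dCy, F, gFx, gFy)
  }
}

# full right-hand side of the agent system at one stage
agent_rhs <- function(st, env, params, geometry) {
  cpl <- coupling_strengths(st$A, env$F, params)
  pos <- positional_rhs(st$x, st$y, st$theta, st$phi, st$A,
                        env$Ux, env$Uy, env$Umag, geometry, params)
  list(vx = pos$vx, vy = pos$vy,
       dtheta = orientation_rhs(st$theta, st$L, cpl, env$delta_U,
                                env$delta_C, env$delta_F,
                                env$deg_U, env$deg_C, env$deg_F),
       dphi = bell_frequency(st$A, params),
       dA = activity_rhs(st$A, st$theta, env$delta_F, env$gradF_mag,
                         params, env$deg_F))
}

clamp_positions <- function(st, geometry, eps = 1e-6) {
  st$x <- pmin(pmax(st$x, geometry$x_min + eps), geometry$x_max - eps)
  st$y <- pmin(pmax(st$y, geometry$y_min + eps), geometry$y_max - eps)
  st
}

#' One stochastic Heun step of the agent ensemble
#'
#' Predictor-corrector update of `(x, y, theta, phi, A, L)` for all
#' agents. The Wiener increment of the colored angular noise is drawn
#' once per step and shared between the two stages, with the noise
#' intensity `D(A)` evaluated at the step's start state. Angles are
#' wrapped and positions clamped to the tank interior (by 1e-6 m) as a
#' safety net beneath the wall force.
#'
#' @param st agent state list (see [init_agents()]).
#' @param env_fn environment sampler `function(x, y)`.
#' @param params a [model_params()].
#' @param dt time step (s).
#' @param geometry a [tank_geometry()].
#' @return the updated state.
#' @export
heun_step <- function(st, env_fn, params, dt, geometry) {
  if (dt <= 0) stop("dt must be positive")
  bad <- which(!is.finite(st$x) | !is.finite(st$y) | !is.finite(st$theta) |
                 !is.finite(st$phi) | !is.finite(st$A) | !is.finite(st$L))
  if (length(bad)) stop("non-finite agent state at index ", bad[1])
  e1 <- env_fn(st$x, st$y)
  k1 <- agent_rhs(st, e1, params, geometry)
  lam <- params$lambda_theta
  sig <- sqrt(2 * noise_intensity(st$A, params))
  dW <- stats::rnorm(length(st$L), sd = sqrt(dt))
  kL1 <- -lam * st$L

  pred <- list(x = st$x + dt * k1$vx, y = st$y + dt * k1$vy,
               theta = st$theta + dt * k1$dtheta,
               phi = st$phi + dt * k1$dphi,
               A = st$A + dt * k1$dA,
               L = st$L + dt * kL1 + sig * dW)
  pred <- clamp_positions(pred, geometry)

  e2 <- env_fn(pred$x, pred$y)
  k2 <- agent_rhs(pred, e2, params, geometry)
  kL2 <- -lam * pred$L

  out <- list(x = st$x + dt / 2 * (k1$vx + k2$vx),
              y = st$y + dt / 2 * (k1$vy + k2$vy),
              theta = wrap_angle(st$theta + dt / 2 * (k1$dtheta + k2$dtheta)),
              phi = (st$phi + dt / 2 * (k1$dphi + k2$dphi)) %% (2 * pi),
              A = st$A + dt / 2 * (k1$dA + k2$dA),
              L = st$L + dt / 2 * (kL1 + kL2) + sig * dW)
  out <- clamp_positions(out, geometry)
  bad <- which(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$theta) |
                 !is.finite(out$A) | !is.finite(out$L))
  if (length(bad))
    stop("non-finite agent state at index ", bad[1])
  out
}

# deterministic Heun step of a tracer twin (positions only; uses no RNG, so
# the active ensemble's noise stream is unaffected by the twin's presence)
twin_step <- function(tw, env_fn, params, dt, geometry) {
  z <- numeric(length(tw$x))
  rhs <- function(x, y) {
    e <- env_fn(x, y)
    positional_rhs(x, y, theta = z, phi = z, A = z,
                   Ux = e$Ux, Uy = e$Uy, Umag = e$Umag, geometry, params)
  }
  r1 <- rhs(tw$x, tw$y)
  pred <- clamp_positions(list(x = tw$x + dt * r1$vx, y = tw$y + dt * r1$vy),
                          geometry)
  r2 <- rhs(pred$x, pred$y)
  clamp_positions(list(x = tw$x + dt / 2 * (r1$vx + r2$vx),
                       y = tw$y + dt / 2 * (r1$vy + r2$vy)), geometry)
}

#' Run one simulation (active ensemble plus optional twin)
#'
#' Integrates the agent ensemble through time with [heun_step()],
#' recording state and the locally sampled environment at the configured
#' interval. When a twin mode is configured, a reduced ensemble (passive
#' or repulsive tracers) with identical initial positions is integrated
#' alongside the active one; its dynamics consumes no random numbers, so
#' active trajectories are unchanged by its presence.
#'
#' @param config a [run_config()].
#' @param env_fn optional environment sampler; when `NULL` one is built
#'   from the configuration (`"analytic"` flow: still water in the cavity
#'   scenarios, the Poiseuille profile in the channel).
#' @param flow,prey optional fields used when `config$flow == "frozen"`
#'   (`flow` may also be a live `flow_field` to be stepped when
#'   `config$flow == "live"`).
#' @param seed optional seed override (defaults to `config$seed`).
#' @return a list with `time`, record matrices (time x agent) under
#'   `active` (`x, y, theta, phi, A, vx, vy, Ux, Uy, absC, F`), the same
#'   positions under `twin` when enabled, and the echoed `config`.
#' @export
run_simulation <- function(config, env_fn = NULL, flow = NULL, prey = NULL,
                           seed = NULL) {
  g <- config$geometry
  set.seed(seed %||% config$seed)
  live <- config$flow == "live"
  if (is.null(env_fn)) {
    if (config$flow == "analytic") {
      env_fn <- if (config$scenario == "channel")
        env_analytic("poiseuille", g, config$fluid) else env_analytic("still")
    } else {
      if (is.null(flow) && is.null(prey))
        stop("frozen/live flow mode needs a flow and/or prey field")
      env_fn <- env_from_fields(flow, prey, g)
    }
  }
  params <- config$params
  st <- init_agents(config$N, g, params, config$init_region)
  twin_on <- config$twin != "none"
  tw_params <- switch(config$twin, passive = params_passive(R_w = params$R_w),
                      repulsive = params_repulsive(R_i = params$R_i,
                                                   R_w = params$R_w),
                      NULL)
  tw <- if (twin_on) st else NULL

  n_steps <- round(config$t_total / config$dt_agent)
  rec_stride <- max(1L, round(config$record_every / config$dt_agent))
  rec_idx <- seq(0L, n_steps, by = rec_stride)
  n_rec <- length(rec_idx)
  alloc <- function() matrix(NA_real_, n_rec, config$N)
  rec <- list(x = alloc(), y = alloc(), theta = alloc(), phi = alloc(),
              A = alloc(), vx = alloc(), vy = alloc(), Ux = alloc(),
              Uy = alloc(), absC = alloc(), F = alloc())
  trec <- if (twin_on) list(x = alloc(), y = alloc(), vx = alloc(),
                            vy = alloc(), Ux = alloc(), Uy = alloc(),
                            absC = alloc(), F = alloc()) else NULL
  times <- rec_idx * config$dt_agent

  record_at <- function(r, st, env_fn, params) {
    env <- env_fn(st$x, st$y)
    rhs <- agent_rhs(st, env, params, g)
    rec$x[r, ] <<- st$x; rec$y[r, ] <<- st$y
    rec$theta[r, ] <<- st$theta; rec$phi[r, ] <<- st$phi
    rec$A[r, ] <<- st$A
    rec$vx[r, ] <<- rhs$vx; rec$vy[r, ] <<- rhs$vy
    rec$Ux[r, ] <<- env$Ux; rec$Uy[r, ] <<- env$Uy
    rec$absC[r, ] <<- env$absC; rec$F[r, ] <<- env$F
  }

  record_twin_at <- function(r, tw, env_fn) {
    env <- env_fn(tw$x, tw$y)
    z <- numeric(length(tw$x))
    pos <- positional_rhs(tw$x, tw$y, z, z, z, env$Ux, env$Uy, env$Umag,
                          g, tw_params)
    trec$x[r, ] <<- tw$x; trec$y[r, ] <<- tw$y
    trec$vx[r, ] <<- pos$vx; trec$vy[r, ] <<- pos$vy
    trec$Ux[r, ] <<- env$Ux; trec$Uy[r, ] <<- env$Uy
    trec$absC[r, ] <<- env$absC; trec$F[r, ] <<- env$F
  }

  r <- 1L
  record_at(r, st, env_fn, params)
  if (twin_on) record_twin_at(1L, tw, env_fn)
  sub_per_agent <- if (live) max(1L, round(config$dt_agent / config$fluid$dt_fluid)) else 0L
  for (k in seq_len(n_steps)) {
    if (live) {
      for (s in seq_len(sub_per_agent)) flow <- step_flow(flow)
      if (!is.null(prey))
        prey <- step_prey(prey, flow, config$dt_agent)
      env_fn <- env_from_fields(flow, prey, g)
    } else if (!is.null(prey) && config$flow == "frozen") {
      prey <- step_prey(prey, flow, config$dt_agent)
      env_fn <- env_from_fields(flow, prey, g)
    }
    st <- heun_step(st, env_fn, params, config$dt_agent, g)
    if (twin_on) tw <- twin_step(tw, env_fn, tw_params, config$dt_agent, g)
    if (k %% rec_stride == 0L) {
      r <- r + 1L
      record_at(r, st, env_fn, params)
      if (twin_on) record_twin_at(r, tw, env_fn)
    }
  }
  list(time = times, active = rec, twin = trec, config = config,
       final_flow = if (live) flow else NULL, final_prey = prey)
}

#' Run a K-repetition ensemble
#'
#' Derives one sub-seed per repetition from the master seed and calls
#' [run_simulation()] for each, so repetitions are independent and the
#' whole ensemble is reproducible from `(config, seed)`.
#'
#' @param config a [run_config()].
#' @param ... passed on to [run_simulation()].
#' @return list of `K` run results.
#' @export
run_ensemble <- function(config, ...) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$K)
  lapply(seq_len(config$K), function(k)
    run_simulation(config, seed = seeds[k], ...))
}
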