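#' Standard parameter-scan grids
#'
#' The sweep grids used by the tank experiments: the two angular coupling
#' scans (nine log-spaced values from 0.005 doubling up to 0.64, plus 1),
#' the interaction radii, the noise correlation rates, the counter-current
#' decoupling slopes and a log-spaced prey-coupling grid covering
#' `[0.04, 0.64]` rad/s.
#'
#' @return named list of numeric grids.
#' @export
scan_grids <- function() {
  list(eps_U0 = c(0.005 * 2^(0:7), 1),
       eps_C0 = c(0.005 * 2^(0:7), 1),
       R_i = c(0.1, 0.5, 1),
       lambda_theta = c(0.2, 1, 5),
       f_U = c(0.025, 0.05, 0.075, 0.1, 0.5),
       eps_F0 = 0.04 * 2^(0:4))
}

# mean over the central two-thirds of a time series
central_two_thirds_mean <- function(x, time) {
  T <- max(time)
  keep <- time >= T / 6 & time <= 5 * T / 6 & is.finite(x)
  mean(x[keep])
}

#' Counter-current swimming experiment
#'
#' Runs the reduced rheotaxis model (advection, pulsed propulsion with
#' the flow-speed response, soft-core repulsion, walls, colored angular
#' noise and the single flow-alignment coupling) in the steady Poiseuille
#' channel and measures, for each coupling strength, the fraction of the
#' still-water swimming speed retained against the current: the time
#' average, over the central two-thirds of the run, of the magnitude of
#' the ensemble-mean velocity of the agents relative to their local flow,
#' divided by `reference_speed`.
#'
#' @param eps_U0 vector of coupling strengths (rad/s) to scan.
#' @param lambda_theta vector of noise correlation rates (1/s) to scan.
#' @param N,K,t_total,dt_agent,seed run configuration (defaults: 128
#'   agents, 4 repetitions, 300 s at 0.005 s).
#' @param reference_speed still-water swimming speed used for
#'   normalization (m/s); default 0.067.
#' @param record_every record interval (s).
#' @return data frame with one row per `(eps_U0, lambda_theta)`:
#'   `speed_fraction` (K-run mean) and `sd` (across repetitions).
#' @export
run_counter_current <- function(eps_U0 = 0.16, lambda_theta = 5,
                                N = 128, K = 4, t_total = 300,
                                dt_agent = 0.005, seed = 1L,
                                reference_speed = 0.067,
                                record_every = 0.1) {
  grid <- expand.grid(eps_U0 = eps_U0, lambda_theta = lambda_theta)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- run_config(
      scenario = "channel",
      params = params_counter_current(eps_U0 = grid$eps_U0[i],
                                      lambda_theta = grid$lambda_theta[i]),
      N = N, K = K, dt_agent = dt_agent, record_every = record_every,
      t_total = t_total, seed = seed, flow = "analytic", twin = "none")
    runs <- run_ensemble(cfg)
    fr <- vapply(runs, function(r) {
      relx <- rowMeans(r$active$vx - r$active$Ux)
      rely <- rowMeans(r$active$vy - r$active$Uy)
      central_two_thirds_mean(sqrt(relx^2 + rely^2), r$time) / reference_speed
    }, numeric(1))
    out[[i]] <- data.frame(eps_U0 = grid$eps_U0[i],
                           lambda_theta = grid$lambda_theta[i],
                           speed_fraction = mean(fr), sd = stats::sd(fr))
  }
  do.call(rbind, out)
}

# time-resolved metrics shared by the cavity experiments
series_metrics <- function(run, n_hex, stride = 1L) {
  idx <- seq(1L, length(run$time), by = stride)
  a <- run$active; p <- run$twin
  data.frame(
    time = run$time[idx],
    P = vapply(idx, function(r) turbulence_fraction(a$absC[r, ], p$absC[r, ]),
               numeric(1)),
    corr_a = vapply(idx, function(r)
      velocity_correlation(a$vx[r, ], a$vy[r, ], a$Ux[r, ], a$Uy[r, ]), numeric(1)),
    corr_p = vapply(idx, function(r)
      velocity_correlation(p$vx[r, ], p$vy[r, ], p$Ux[r, ], p$Uy[r, ]), numeric(1)),
    hex_a = vapply(idx, function(r) hex_order(a$x[r, ], a$y[r, ], n_hex), numeric(1)),
    hex_p = vapply(idx, function(r) hex_order(p$x[r, ], p$y[r, ], n_hex), numeric(1)),
    sig_a = vapply(idx, function(r)
      spread(a$x[r, ], a$y[r, ], a$x[1L, ], a$y[1L, ]), numeric(1)),
    sig_p = vapply(idx, function(r)
      spread(p$x[r, ], p$y[r, ], p$x[1L, ], p$y[1L, ]), numeric(1)))
}

#' Wall-effects experiment
#'
#' Compares repulsive and passive tracer ensembles (identical seeds and
#' initial positions) in a cavity flow and reports the time-averaged
#' differences in velocity-flow correlation and 6-neighbour hexatic order
#' after the initial transient. The wall interaction distance defaults to
#' 0.5 m for this experiment.
#'
#' @param N vector of ensemble sizes to scan (up to 512).
#' @param R_i vector of interaction radii (m) to scan.
#' @param env_fn environment sampler providing the cavity flow (e.g. from
#'   [env_from_fields()] on a spun-up cavity field).
#' @param geometry the tank geometry matching `env_fn`.
#' @param t_total,dt_agent,K,seed,record_every run configuration.
#' @param R_w wall interaction distance (m); default 0.5.
#' @param transient initial time discarded from averages (s); default 50.
#' @param metric_stride evaluate metrics every this many records.
#' @return data frame with `delta_corr` and `delta_hex6` per `(N, R_i)`.
#' @export
run_wall_effects <- function(N = 128, R_i = 0.1, env_fn, geometry,
                             t_total = 300, dt_agent = 0.005, K = 4,
                             seed = 1L, record_every = 0.5, R_w = 0.5,
                             transient = 50, metric_stride = 1L) {
  grid <- expand.grid(N = N, R_i = R_i)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- run_config(
      scenario = geometry$scenario,
      params = params_repulsive(R_i = grid$R_i[i], R_w = R_w),
      N = grid$N[i], K = K, dt_agent = dt_agent,
      record_every = record_every, t_total = t_total, seed = seed,
      flow = "frozen", twin = "passive", geometry = geometry)
    # the twin's wall radius matches the experiment's 0.5 m setting
    runs <- run_ensemble(cfg, env_fn = env_fn)
    dc <- dh <- numeric(K)
    for (k in seq_len(K)) {
      m <- series_metrics(runs[[k]], n_hex = 6, stride = metric_stride)
      keep <- m$time > transient
      dc[k] <- mean(m$corr_a[keep] - m$corr_p[keep], na.rm = TRUE)
      dh[k] <- mean(m$hex_a[keep] - m$hex_p[keep], na.rm = TRUE)
    }
    out[[i]] <- data.frame(N = grid$N[i], R_i = grid$R_i[i],
                           delta_corr = mean(dc), delta_hex6 = mean(dh))
  }
  do.call(rbind, out)
}

#' Turbulence-avoidance experiment
#'
#' Runs the two-coupling model (flow alignment plus vorticity avoidance)
#' against a passive twin and reports the spike-filtered baseline
#' turbulence fraction `P_min(|C|)` plus the structure metrics
#' `delta_hex12` and `delta_sigma` averaged over the final
#' `structure_window` seconds.
#'
#' @param eps_U0,eps_C0 coupling grids (rad/s) to scan.
#' @param env_fn environment sampler providing the cavity flow.
#' @param geometry matching [tank_geometry()].
#' @param N,K,t_total,dt_agent,seed,record_every run configuration
#'   (defaults scaled down from the 900 s reference runs).
#' @param burn_in burn-in of the baseline extraction (s); default 50.
#' @param structure_window trailing window for structure averages (s).
#' @param metric_stride evaluate metrics every this many records.
#' @return data frame per `(eps_U0, eps_C0)` with `P_min`, `delta_hex12`,
#'   `delta_sigma`.
#' @export
run_turbulence_avoidance <- function(eps_U0 = 0.16, eps_C0 = 0.08,
                                     env_fn, geometry,
                                     N = 128, K = 4, t_total = 900,
                                     dt_agent = 0.005, seed = 1L,
                                     record_every = 0.5, burn_in = 50,
                                     structure_window = 300,
                                     metric_stride = 1L) {
  grid <- expand.grid(eps_U0 = eps_U0, eps_C0 = eps_C0)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- run_config(
      scenario = geometry$scenario,
      params = params_turbulence(eps_U0 = grid$eps_U0[i],
                                 eps_C0 = grid$eps_C0[i]),
      N = N, K = K, dt_agent = dt_agent, record_every = record_every,
      t_total = t_total, seed = seed, flow = "frozen", twin = "passive",
      geometry = geometry)
    runs <- run_ensemble(cfg, env_fn = env_fn)
    pm <- dh <- ds <- numeric(K)
    for (k in seq_len(K)) {
      m <- series_metrics(runs[[k]], n_hex = 12, stride = metric_stride)
      pm[k] <- baseline_fraction(m$P, m$time, burn_in = burn_in)
      tail_keep <- m$time > t_total - structure_window
      dh[k] <- mean(m$hex_a[tail_keep] - m$hex_p[tail_keep], na.rm = TRUE)
      ds[k] <- mean(m$sig_a[tail_keep] - m$sig_p[tail_keep], na.rm = TRUE)
    }
    out[[i]] <- data.frame(eps_U0 = grid$eps_U0[i], eps_C0 = grid$eps_C0[i],
                           P_min = mean(pm), delta_hex12 = mean(dh),
                           delta_sigma = mean(ds))
  }
  do.call(rbind, out)
}

#' Foraging experiment
#'
#' Double-gyre scenario with prey initialized in the left gyre and agents
#' in the right gyre. Runs the requested response-mechanism subsets
#' (see [params_foraging()]) and reports the time-averaged crossing
#' fraction `P(x)` and the left-gyre spread `Sigma_0`.
#'
#' @param mechanisms list of mechanism subsets, e.g.
#'   `list("A", c("A","B"), c("A","B","C"), "D")`.
#' @param flow a (frozen) double-gyre `flow_field`.
#' @param prey initial `prey_field`; defaults to
#'   [init_double_gyre_prey()] on the flow's geometry.
#' @param N,K,t_total,dt_agent,seed,record_every run configuration.
#' @param eps_F0,f_U,f_F parameter overrides applied to every subset
#'   (used for the sweep figures).
#' @return data frame per mechanism subset with `P_x` and `sigma_0`.
#' @export
run_foraging <- function(mechanisms = list("D"), flow, prey = NULL,
                         N = 128, K = 4, t_total = 900, dt_agent = 0.005,
                         seed = 1L, record_every = 0.5,
                         eps_F0 = 0.16, f_U = 0.05, f_F = 0.2) {
  geometry <- flow$geometry
  prey <- prey %||% init_double_gyre_prey(geometry)
  out <- vector("list", length(mechanisms))
  for (i in seq_along(mechanisms)) {
    mech <- mechanisms[[i]]
    cfg <- run_config(
      scenario = geometry$scenario,
      params = params_foraging(mech, eps_F0 = eps_F0, f_U = f_U, f_F = f_F),
      N = N, K = K, dt_agent = dt_agent, record_every = record_every,
      t_total = t_total, seed = seed, flow = "frozen",
      init_region = "right_half", twin = "passive", geometry = geometry)
    runs <- run_ensemble(cfg, flow = flow, prey = prey)
    px <- s0 <- numeric(K)
    for (k in seq_len(K)) {
      r <- runs[[k]]
      P <- vapply(seq_along(r$time), function(t)
        crossing_fraction(r$active$x[t, ], r$twin$x[t, ]), numeric(1))
      px[k] <- mean(P, na.rm = TRUE)
      S0 <- vapply(seq_along(r$time), function(t)
        spread(r$active$x[t, ], r$active$y[t, ],
               r$active$x[1L, ], r$active$y[1L, ], region = "left"),
        numeric(1))
      s0[k] <- mean(S0, na.rm = TRUE)
    }
    out[[i]] <- data.frame(mechanisms = paste(mech, collapse = "+"),
                           eps_F0 = eps_F0, f_U = f_U, f_F = f_F,
                           P_x = mean(px), sigma_0 = mean(s0))
  }
  do.call(rbind, out)
}
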