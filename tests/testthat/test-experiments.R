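test_that("mechanism toggles reduce the full model exactly (shared seeds)", {
  # with no prey anywhere, the full response dynamics is bit-for-bit the
  # two-coupling turbulence-avoidance model
  f <- cavity_snapshot()
  g <- f$geometry
  mk <- function(params) run_config(scenario = "cavity", params = params,
                                    N = 12, K = 1, dt_agent = 0.01,
                                    record_every = 0.1, t_total = 3,
                                    seed = 21, flow = "frozen",
                                    twin = "none", geometry = g)
  r_full <- run_simulation(mk(model_params()), flow = f)
  r_turb <- run_simulation(mk(params_turbulence()), flow = f)
  expect_identical(r_full$active$x, r_turb$active$x)
  expect_identical(r_full$active$theta, r_turb$active$theta)
  # and disabling the vorticity term reduces it to the rheotaxis model
  r_cc <- run_simulation(mk(params_counter_current()), flow = f)
  expect_false(identical(r_cc$active$theta, r_turb$active$theta))
  r_turb0 <- run_simulation(mk(params_turbulence(eps_C0 = 0)), flow = f)
  expect_identical(r_cc$active$x, r_turb0$active$x)
})

test_that("repulsion-free twins give exactly zero wall-effect deltas", {
  g <- tank_geometry("cavity", nx = 21, ny = 21)
  env <- toy_env(g)
  # R_i so small that no pair ever interacts: repulsive == passive
  res <- run_wall_effects(N = 8, R_i = 1e-6, env_fn = env, geometry = g,
                          t_total = 20, dt_agent = 0.01, K = 2, seed = 5,
                          record_every = 0.5, transient = 5)
  expect_equal(res$delta_corr, 0)
  expect_equal(res$delta_hex6, 0)
})

test_that("tiny wall-effect runs agree with the metric oracles", {
  g <- tank_geometry("cavity", nx = 21, ny = 21)
  cfg <- run_config(scenario = "cavity", params = params_repulsive(R_i = 2),
                    N = 8, K = 1, dt_agent = 0.01, record_every = 0.5,
                    t_total = 5, seed = 8, flow = "frozen", twin = "passive",
                    geometry = g)
  r <- run_simulation(cfg, env_fn = toy_env(g))
  T <- nrow(r$active$x)
  a <- r$active
  expect_equal(velocity_correlation(a$vx[T, ], a$vy[T, ], a$Ux[T, ], a$Uy[T, ]),
               (oracle_pearson(a$vx[T, ], a$Ux[T, ]) +
                  oracle_pearson(a$vy[T, ], a$Uy[T, ])) / 2)
  expect_equal(hex_order(a$x[T, ], a$y[T, ], 3),
               oracle_hex(a$x[T, ], a$y[T, ], 3))
})

test_that("noise-free aligned swimmers retain the closed-form speed fraction", {
  # uniform flow, no angular noise, strong alignment: the relative speed is
  # the bell-averaged propulsion speed at |U| = 0.045
  g <- tank_geometry("channel", nx = 161, ny = 21, x_min = -10, x_max = 10,
                     y_min = 0, y_max = 2.5)
  cfg <- run_config(scenario = "channel",
                    params = params_counter_current(D_0 = 0, eps_U0 = 2,
                                                    enable_repulsion = FALSE),
                    N = 64, K = 1, dt_agent = 0.005, record_every = 0.1,
                    t_total = 60, seed = 12, flow = "analytic", twin = "none",
                    geometry = g)
  env <- env_analytic("uniform", Ux = -0.045, Uy = 0)
  r <- run_simulation(cfg, env_fn = env)
  relx <- rowMeans(r$active$vx - r$active$Ux)
  rely <- rowMeans(r$active$vy - r$active$Uy)
  keep <- r$time >= 20
  frac <- mean(sqrt(relx^2 + rely^2)[keep]) / 0.067
  expected <- (0.15 + response(0.5, 0.6, 0.045)) * bell_beta_mean(1) / 0.067
  expect_equal(frac, expected, tolerance = 0.02)
})

test_that("turbulence avoidance empties the prescribed turbulent band", {
  g <- tank_geometry("cavity", nx = 21, ny = 21)
  env <- band_env(g)
  mk <- function(eps_C0) run_config(
    scenario = "cavity",
    params = params_turbulence(eps_U0 = 0, eps_C0 = eps_C0,
                               enable_counter_current = FALSE),
    N = 24, K = 1, dt_agent = 0.01, record_every = 0.5, t_total = 60,
    seed = 44, flow = "frozen", twin = "passive", geometry = g)
  r_avoid <- run_simulation(mk(0.64), env_fn = env)
  T <- nrow(r_avoid$active$y)
  # avoiders end mostly below the midline, their passive twins do not
  expect_lt(mean(r_avoid$active$y[T, ] > 5), 0.2)
  expect_gt(mean(r_avoid$twin$y[T, ] > 5), 0.3)
  P_end <- turbulence_fraction(r_avoid$active$absC[T, ], r_avoid$twin$absC[T, ])
  expect_lt(P_end, 0.5)
})

test_that("baseline turbulence fraction decreases with the avoidance coupling", {
  f <- cavity_snapshot()
  g <- f$geometry
  env <- env_from_fields(f)
  res <- run_turbulence_avoidance(eps_U0 = 0.005, eps_C0 = c(0.01, 0.64),
                                  env_fn = env, geometry = g, N = 24, K = 2,
                                  t_total = 150, dt_agent = 0.01, seed = 9,
                                  record_every = 0.5, burn_in = 50,
                                  structure_window = 50, metric_stride = 2L)
  expect_lt(res$P_min[res$eps_C0 == 0.64], res$P_min[res$eps_C0 == 0.01])
  expect_true(all(res$P_min >= 0))
})

test_that("prey-blind response mechanisms do not cross the gyre barrier", {
  f <- double_gyre_snapshot(nx = 41, ny = 21, U0 = 0.15)
  res <- run_foraging(list("A"), flow = f, N = 16, K = 1, t_total = 60,
                      dt_agent = 0.01, seed = 6, record_every = 1)
  # without prey orientation and with full-strength turbulence avoidance,
  # agents remain essentially confined to the right gyre
  expect_gt(res$P_x, 0.6)
  expect_equal(res$mechanisms, "A")
})

test_that("the full response cascade promotes crossing towards the prey", {
  f <- double_gyre_snapshot(nx = 41, ny = 21, U0 = 0.15)
  res_A <- run_foraging(list("A"), flow = f, N = 16, K = 1, t_total = 120,
                        dt_agent = 0.01, seed = 61, record_every = 1)
  res_D <- run_foraging(list("D"), flow = f, N = 16, K = 1, t_total = 120,
                        dt_agent = 0.01, seed = 61, record_every = 1)
  expect_lt(res_D$P_x, res_A$P_x)
})

test_that("scan grids reproduce the printed sweep sets", {
  gr <- scan_grids()
  expect_equal(gr$eps_U0, c(0.005, 0.01, 0.02, 0.04, 0.08, 0.16, 0.32, 0.64, 1))
  expect_equal(gr$lambda_theta, c(0.2, 1, 5))
  expect_equal(gr$f_U, c(0.025, 0.05, 0.075, 0.1, 0.5))
  expect_equal(gr$R_i, c(0.1, 0.5, 1))
})
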