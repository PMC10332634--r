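test_that("response function matches its closed form and limits", {
  expect_equal(response(1, 0.05, 0.3), 0.3 / 0.35)
  expect_equal(response(1, 0.5, 0.3), 0.375)
  expect_equal(response(3, 0.2, 0), 0)
  expect_error(response(1, 0, 0.5), "positive")
  expect_error(response(1, 0.1, -1), "non-negative")
  # monotone in S, saturating at a
  S <- seq(0, 50, by = 0.5)
  r <- response(2, 0.3, S)
  expect_true(all(diff(r) > 0))
  expect_lt(max(r), 2)
  expect_equal(response(2, 0.3, 1e9), 2, tolerance = 1e-8)
})

test_that("counter-current decoupling reproduces the printed weakenings", {
  # percent reduction of eps_U at F = 0.3 F0 for the printed slopes
  weaken <- function(f_U) round(100 * response(1, f_U, 0.3), 6)
  expect_equal(round(weaken(0.05)), 86)
  expect_equal(round(weaken(0.01)), 97)
  expect_equal(round(weaken(0.1)), 75)
  expect_equal(round(weaken(0.5)), 38)  # 37.5 rounds up to the printed 38
  expect_equal(round(weaken(0.025)), 92)
  expect_equal(round(weaken(0.075)), 80)
})

test_that("bell factor, its closed-form average and quadrature agree", {
  expect_equal(bell_beta(0, 5), 1)
  expect_equal(bell_beta(pi, 5), exp(-10))
  for (J in c(0.5, 1, 5)) {
    quad <- stats::integrate(function(phi) bell_beta(phi, J) / (2 * pi),
                             0, 2 * pi, rel.tol = 1e-10)$value
    expect_equal(bell_beta_mean(J), quad, tolerance = 1e-6)
  }
  expect_equal(round(bell_beta_mean(1), 2), 0.47)
})

test_that("bell frequency and noise responses saturate correctly", {
  p <- model_params()
  expect_equal(bell_frequency(0, p), 1.2)
  expect_equal(bell_frequency(1e12, p), 1.2 * 1.75, tolerance = 1e-9)
  expect_equal(bell_frequency(p$f_phi, p), 1.2 * 1.375)  # R(f, f, f) = f/2
  expect_equal(noise_intensity(0, p), 0.1)
  expect_equal(noise_intensity(1e12, p) / noise_intensity(0, p), 1.75,
               tolerance = 1e-9)
  p_off <- model_params(enable_freq_response = FALSE)
  expect_equal(bell_frequency(100, p_off), 1.2)
})

test_that("colored noise has the stationary spread sqrt(D0/lambda)", {
  targets <- c("0.2" = 0.71, "1" = 0.32, "5" = 0.14)
  for (lam in c(0.2, 1, 5)) {
    expect_equal(round(sqrt(0.1 / lam), 2), unname(targets[as.character(lam)]))
  }
  # empirical check: many independent agents, Heun stepping
  set.seed(101)
  p <- model_params(lambda_theta = 5)
  n <- 512; dt <- 0.01
  L <- rnorm(n, sd = sqrt(0.1 / 5))
  keep <- c()
  for (k in 1:3000) {
    L <- angular_noise_step(L, 0, dt, p)
    if (k > 500 && k %% 10 == 0) keep <- c(keep, L)
  }
  expect_equal(sd(keep), sqrt(0.1 / 5), tolerance = 0.03)
  # zero drive: pure exponential decay at rate lambda_theta
  p0 <- model_params(D_0 = 0, lambda_theta = 2)
  L <- 1
  for (k in 1:100) L <- angular_noise_step(L, 0, 0.01, p0)
  expect_equal(L, exp(-2 * 1), tolerance = 1e-3)
})

test_that("activity is rectified, decays, and fixes at g/lambda_A", {
  p <- model_params()
  # swimming away from the gradient: pure decay
  expect_equal(activity_rhs(2, pi, 0, gradF_mag = 5, p), -p$lambda_A * 2)
  expect_equal(activity_rhs(0, 0, 0, gradF_mag = 0, p), 0)
  # steady state of the linear ODE under constant aligned input
  g <- 0.01
  expect_equal(activity_rhs(g / p$lambda_A, 0, 0, gradF_mag = g, p), 0)
  # degenerate gradient suppresses the input
  expect_equal(activity_rhs(1, 0, 0, gradF_mag = 1, p, degenerate = TRUE),
               -p$lambda_A)
})

test_that("parametric switches gate the couplings as specified", {
  p <- model_params()
  c0 <- coupling_strengths(A = 0, F = 0, p)
  expect_equal(c0$eps_U, p$eps_U0)
  expect_equal(c0$eps_C, p$eps_C0)
  expect_equal(c0$eps_F, 0)
  # 97% weakening of eps_U at F = 0.3 with f_U = 0.01
  p2 <- model_params(f_U = 0.01)
  expect_equal(coupling_strengths(0, 0.3, p2)$eps_U / p2$eps_U0, 1 - 0.3 / 0.31)
  # eps_F(A) rises from zero, peaks, then decays towards zero
  A <- 10^seq(-3, 6, length.out = 120)
  eF <- coupling_strengths(A, 0, p)$eps_F
  pk <- which.max(eF)
  expect_gt(pk, 5); expect_lt(pk, length(A) - 5)
  expect_true(all(diff(eF[1:pk]) > 0))
  expect_true(all(diff(eF[pk:length(A)]) < 0))
  expect_lt(eF[length(A)], 1e-3)
})

test_that("orientation dynamics converges to its analytic fixed points", {
  p <- model_params()
  integrate_theta <- function(theta0, cpl, dU, dC, dF, t_end = 200, dt = 0.01) {
    th <- theta0
    for (k in seq_len(t_end / dt)) {
      d1 <- orientation_rhs(th, 0, cpl, dU, dC, dF)
      d2 <- orientation_rhs(th + dt * d1, 0, cpl, dU, dC, dF)
      th <- th + dt / 2 * (d1 + d2)
    }
    atan2(sin(th), cos(th))
  }
  # single flow coupling: stable point is anti-parallel to the flow
  cpl <- list(eps_U = 0.8, eps_C = 0, eps_F = 0)
  dU <- pi / 8
  for (th0 in c(-2.5, -1, 0.5, 1.2, 3)) {
    thf <- integrate_theta(th0, cpl, dU, 0, 0)
    expect_equal(angle_diff(thf, dU + pi), 0, tolerance = 1e-6)
  }
  # single prey coupling: convergence to delta_F from any start
  cplF <- list(eps_U = 0, eps_C = 0, eps_F = 0.5)
  dF <- 1.1
  thf <- integrate_theta(2.9, cplF, 0, 0, dF)
  expect_equal(angle_diff(thf, dF), 0, tolerance = 1e-6)
  # the three-coupling configuration has a unique stable orientation near
  # delta_F; locate it independently by a dense root scan
  cpl3 <- list(eps_U = 0.1, eps_C = 0.2, eps_F = 0.7)
  dU <- pi / 8; dC <- 6 * pi / 5; dF <- 1.7 * pi
  roots <- oracle_stable_orientations(0.1, 0.2, 0.7, dU, dC, dF)
  expect_length(roots, 1)
  expect_lt(abs(angle_diff(roots, dF)), 0.5)
  for (th0 in c(-3, -1.5, 0, 1.5, 3)) {
    thf <- integrate_theta(th0, cpl3, dU, dC, dF)
    expect_equal(angle_diff(thf, roots), 0, tolerance = 1e-4)
  }
})

test_that("random single-coupling cases always settle anti-parallel", {
  p <- model_params()
  set.seed(77)
  for (case in 1:12) {
    eps <- runif(1, 0.05, 1); dU <- runif(1, -pi, pi)
    th <- runif(1, -pi, pi)
    # avoid starting exactly on the unstable point
    if (abs(angle_diff(th, dU)) < 1e-3) th <- th + 0.1
    cpl <- list(eps_U = eps, eps_C = 0, eps_F = 0)
    for (k in 1:40000) {
      d1 <- orientation_rhs(th, 0, cpl, dU, 0, 0)
      th <- th + 0.01 * d1
    }
    expect_lt(abs(angle_diff(th, dU + pi)), 1e-3)
  }
})

test_that("active velocity matches the calibrated closed forms", {
  p <- model_params()
  # ensemble/time average over the bell cycle at |U| = 0.045, A = 0
  phi <- seq(0, 2 * pi, length.out = 20001)[-1]
  v <- active_velocity(rep(0, length(phi)), phi, 0, 0.045, p)
  expect_equal(mean(v$speed),
               (0.15 + response(0.5, 0.6, 0.045)) * bell_beta_mean(1),
               tolerance = 1e-6)
  expect_equal(mean(v$speed), 0.087, tolerance = 0.02)
  # still water: V0 * exp(-J) I0(J)
  v0 <- active_velocity(rep(0, length(phi)), phi, 0, 0, p)
  expect_equal(mean(v0$speed), 0.15 * bell_beta_mean(1), tolerance = 1e-6)
  expect_equal(0.15 * bell_beta_mean(1), 0.0699, tolerance = 1e-3)
  # pure tracer limit
  pt <- model_params(V_0 = 0, V_a = 1e-12)
  vt <- active_velocity(0.3, 1, 0, 0.045, pt)
  expect_lt(abs(vt$speed), 1e-10)
  p_off <- params_passive()
  expect_equal(active_velocity(0.3, 1, 0, 0.045, p_off)$speed, 0)
})

test_that("soft-core repulsion follows the R_i/d law and caps safely", {
  p <- model_params(R_i = 0.4)
  # two agents exactly at the cutoff distance: unit magnitude, apart
  f <- pairwise_interaction(c(0, 0.4), c(0, 0), p)
  expect_equal(f[1, ], c(-1, 0), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(f[2, ], c(1, 0), tolerance = 1e-12, ignore_attr = TRUE)
  # half the cutoff: magnitude 2
  f2 <- pairwise_interaction(c(0, 0.2), c(0, 0), p)
  expect_equal(f2[1, 1], -2, tolerance = 1e-12)
  # isolated agent: zero
  expect_equal(pairwise_interaction(5, 5, p), matrix(0, 1, 2))
  # outward and decreasing in distance over (0, R_i]
  d <- seq(0.05, 0.4, by = 0.05)
  mags <- sapply(d, function(dd)
    -pairwise_interaction(c(0, dd), c(0, 0), p)[1, 1])
  expect_true(all(mags > 0))
  expect_true(all(diff(mags) < 0))
  # coincident agents: capped magnitude, pushed apart
  set.seed(5)
  fc <- pairwise_interaction(c(1, 1), c(2, 2), p)
  m <- sqrt(sum(fc[1, ]^2))
  expect_equal(m, 0.4 / 1e-9, tolerance = 1e-6)
  expect_equal(fc[1, ], -fc[2, ], ignore_attr = TRUE)
})

test_that("wall force is the per-axis soft-sphere law", {
  g <- tank_geometry("cavity")  # [0,10]^2
  # at distance R_w from the left wall: unit inward kick
  f <- wall_force(0.1, 5, g, R_w = 0.1)
  expect_equal(f[1, 1], 1)
  expect_equal(f[1, 2], 0)
  # center of the tank: zero
  expect_equal(wall_force(5, 5, g, 0.1), matrix(0, 1, 2), ignore_attr = TRUE)
  # corner: vector sum of the two per-axis contributions
  fc <- wall_force(0.05, 0.08, g, 0.1)
  expect_equal(fc[1, 1], 0.1 / 0.05)
  expect_equal(fc[1, 2], 0.1 / 0.08)
  expect_error(wall_force(-1, 5, g, 0.1), "outside")
})

test_that("positional reductions give tracer and stationary limits", {
  g <- tank_geometry("cavity")
  # passive mode in a uniform flow: exactly the advection velocity
  pp <- params_passive()
  r <- positional_rhs(5, 5, 0, 0, 0, Ux = 0.03, Uy = -0.01, Umag = sqrt(0.001),
                      geometry = g, params = pp)
  expect_equal(r$vx, 0.03)
  expect_equal(r$vy, -0.01)
  # everything off in still water: stationary agent
  r0 <- positional_rhs(5, 5, 0.3, 1, 0, 0, 0, 0, g, pp)
  expect_equal(r0$vx, 0)
  expect_equal(r0$vy, 0)
})
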