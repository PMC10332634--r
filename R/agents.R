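#' Saturating response function
#'
#' The Michaelis-Menten-type activation `R(a, b, S) = a S / (b + S)` used
#' for every behavioural response in the model: quasi-linear with slope
#' `a/b` for small stimuli and saturating at `a` for large ones.
#'
#' @param a response amplitude.
#' @param b half-saturation stimulus (> 0).
#' @param S stimulus, non-negative (vectorized).
#' @return response value(s) in `[0, a)` for `S >= 0`.
#' @examples
#' response(1, 0.05, 0.3)  # 86% of saturation
#' @export
response <- function(a, b, S) {
  if (any(b <= 0)) stop("response half-saturation b must be positive")
  if (any(S < 0)) stop("stimulus S must be non-negative")
  a * S / (b + S)
}

#' Bell pulsation factor
#'
#' `beta(phi) = exp[J (cos(phi) - 1)]`, the periodic modulation of the
#' propulsion speed by the bell stroke. Small `J` gives nearly continuous
#' propulsion (inertial rowers), large `J` a pulsed jet that stalls
#' between strokes.
#'
#' @param phi bell phase (rad), vectorized.
#' @param J shape parameter, `>= 0`.
#' @return factor in `(0, 1]`.
#' @seealso [bell_beta_mean()] for the closed-form period average.
#' @export
bell_beta <- function(phi, J) {
  if (any(J < 0)) stop("J must be non-negative")
  exp(J * (cos(phi) - 1))
}

#' Period average of the bell pulsation factor
#'
#' Closed form `exp(-J) I0(J)` with the modified Bessel function `I0`.
#' For `J = 1` this is 0.4658, the effective duty factor of the stroke.
#'
#' @param J shape parameter, `>= 0`.
#' @return mean of `bell_beta` over one phase period.
#' @export
bell_beta_mean <- function(J) {
  if (any(J < 0)) stop("J must be non-negative")
  exp(-J) * besselI(J, 0)
}

#' Bell frequency response to activity
#'
#' `omega(A) = omega_0 [1 + R(f_phi, f_phi, A)]`: the stroke frequency of
#' an inactive agent is `omega_0` and rises by at most the factor
#' `1 + f_phi` under high activity.
#'
#' @param A activity, `>= 0` (vectorized).
#' @param params a [model_params()].
#' @return bell frequency (rad/s).
#' @export
bell_frequency <- function(A, params) {
  if (!params$enable_freq_response) return(rep(params$omega_0, length(A)))
  params$omega_0 * (1 + response(params$f_phi, params$f_phi, A))
}

#' Angular noise intensity response to activity
#'
#' `D(A) = D_0 [1 + R(f_theta, f_theta, A)]`.
#'
#' @param A activity (vectorized).
#' @param params a [model_params()].
#' @return noise intensity (rad^2 s^-3).
#' @export
noise_intensity <- function(A, params) {
  if (!params$enable_noise_response) return(rep(params$D_0, length(A)))
  params$D_0 * (1 + response(params$f_theta, params$f_theta, A))
}

#' One step of the colored angular noise
#'
#' Heun update of the Ornstein-Uhlenbeck drift
#' `dL = -lambda_theta L dt + sqrt(2 D(A)) dW`, with the Wiener increment
#' shared between the predictor and corrector stages and `D(A)` evaluated
#' at the start of the step. The stationary standard deviation is
#' `sqrt(D(A)/lambda_theta)`.
#'
#' @param L angular drift (rad/s), vectorized.
#' @param A activity, same length as `L` (or scalar).
#' @param dt time step (s).
#' @param params a [model_params()].
#' @return the updated drift.
#' @export
angular_noise_step <- function(L, A, dt, params) {
  if (dt <= 0) stop("dt must be positive")
  lam <- params$lambda_theta
  sig <- sqrt(2 * noise_intensity(A, params))
  dW <- stats::rnorm(length(L), sd = sqrt(dt))
  k1 <- -lam * L
  Lp <- L + dt * k1 + sig * dW
  L + dt / 2 * (k1 - lam * Lp) + sig * dW
}

#' Activity-gated coupling strengths
#'
#' The parametric switches that re-weight the three angular couplings:
#' counter-current coupling is weakened by ambient prey concentration,
#' `eps_U(F) = eps_U0 [1 - R(1, f_U, F)]`; turbulence avoidance is
#' switched off by activity, `eps_C(A) = eps_C0 [1 - R(1, f_C, A)]`; prey
#' orientation switches on with activity and off again at very high
#' activity ("satiation"), `eps_F(A) = eps_F0 R(1, f_F, A) [1 - R(1, f_g, A)]`.
#' Disabled mechanisms return zero for their coupling.
#'
#' @param A activity (vectorized).
#' @param F prey concentration in units of `F_0` (vectorized).
#' @param params a [model_params()].
#' @return list with vectors `eps_U`, `eps_C`, `eps_F` (rad/s).
#' @export
coupling_strengths <- function(A, F, params) {
  n <- max(length(A), length(F))
  A <- rep_len(A, n); F <- rep_len(F, n)
  eps_U <- if (params$enable_counter_current)
    params$eps_U0 * (1 - response(1, params$f_U, F)) else numeric(n)
  eps_C <- if (params$enable_turbulence_avoidance)
    params$eps_C0 * (1 - response(1, params$f_C, A)) else numeric(n)
  eps_F <- if (params$enable_prey_orientation)
    params$eps_F0 * response(1, params$f_F, A) * (1 - response(1, params$f_g, A))
    else numeric(n)
  list(eps_U = eps_U, eps_C = eps_C, eps_F = eps_F)
}

#' Activity dynamics right-hand side
#'
#' `dA/dt = -lambda_A A + |grad F| (|cos(theta - delta_F)| +
#' cos(theta - delta_F)) / 2`: exponential decay plus a rectified input
#' that is positive only while the agent swims towards the prey gradient
#' (`|theta - delta_F| < pi/2`).
#'
#' @param A activity.
#' @param theta orientation (rad).
#' @param delta_F prey gradient direction (rad).
#' @param gradF_mag prey gradient magnitude (`F_0`/m); zero (or a
#'   degenerate flag) suppresses the input.
#' @param degenerate logical; where `TRUE` the input term is dropped.
#' @param params a [model_params()].
#' @return `dA/dt`.
#' @export
activity_rhs <- function(A, theta, delta_F, gradF_mag, params,
                         degenerate = FALSE) {
  if (!params$enable_activity) return(rep(0, length(A)))
  cs <- cos(theta - delta_F)
  input <- gradF_mag * 0.5 * (abs(cs) + cs)
  input[degenerate] <- 0
  -params$lambda_A * A + input
}

#' Orientation dynamics right-hand side
#'
#' `dtheta/dt = L + eps_U sin(theta - delta_U) + eps_C sin(theta -
#' delta_C) - eps_F sin(theta - delta_F)`. With only the flow term this
#' has a stable fixed point anti-parallel to the flow (`theta = delta_U +
#' pi`, counter-current swimming) and an unstable one parallel to it;
#' the vorticity term steers down-gradient of `|C|` and the prey term
#' towards `delta_F`. Degenerate direction angles (flagged by the
#' caller) drop their term for the step.
#'
#' @param theta orientation (rad).
#' @param L angular drift (rad/s).
#' @param couplings list from [coupling_strengths()].
#' @param delta_U,delta_C,delta_F direction angles (rad).
#' @param deg_U,deg_C,deg_F logical degeneracy flags.
#' @return `dtheta/dt` (rad/s).
#' @export
orientation_rhs <- function(theta, L, couplings, delta_U, delta_C, delta_F,
                            deg_U = FALSE, deg_C = FALSE, deg_F = FALSE) {
  tU <- couplings$eps_U * sin(theta - delta_U)
  tC <- couplings$eps_C * sin(theta - delta_C)
  tF <- couplings$eps_F * sin(theta - delta_F)
  tU[deg_U] <- 0; tC[deg_C] <- 0; tF[deg_F] <- 0
  L + tU + tC - tF
}

#' Active propulsion velocity
#'
#' `V = (V_0 + R(V_a, V_b, |U| + A)) beta(phi)` along the orientation
#' vector `(cos theta, sin theta)`. The activity enters the speed stimulus
#' additively with the flow speed (it is treated as numerically
#' commensurate with a speed); with the speed response disabled only `|U|`
#' drives the bilinear adaptation.
#'
#' @param theta orientation (rad).
#' @param phi bell phase (rad).
#' @param A activity.
#' @param Umag local flow speed (m/s).
#' @param params a [model_params()].
#' @return list with velocity components `vx`, `vy` and `speed` (m/s).
#' @export
active_velocity <- function(theta, phi, A, Umag, params) {
  n <- length(theta)
  if (!params$enable_propulsion)
    return(list(vx = numeric(n), vy = numeric(n), speed = numeric(n)))
  stim <- Umag + if (params$enable_speed_response) A else 0
  speed <- (params$V_0 + response(params$V_a, params$V_b, stim)) *
    bell_beta(phi, params$J)
  list(vx = speed * cos(theta), vy = speed * sin(theta), speed = speed)
}

#' Pairwise soft-core interaction
#'
#' For each agent the mean, over its neighbours within radius `R_i`, of
#' the fluid-like soft-core repulsion `I_rep = -R_i (x_k - x_j)/|x_k -
#' x_j|^2` (magnitude `R_i/d`, equal to 1 at the cutoff) plus, when
#' enabled, the unit attraction `I_attr = (x_k - x_j)/|x_k - x_j|`
#' (omitted by default). Agents closer than 1e-9 m are pushed apart at
#' the capped magnitude `R_i/1e-9` in a random direction.
#'
#' @param x,y agent positions (m).
#' @param params a [model_params()].
#' @return `N x 2` matrix of velocity contributions (m/s).
#' @export
pairwise_interaction <- function(x, y, params) {
  n <- length(x)
  if (n == 0) stop("pairwise interaction needs at least one agent")
  if (!params$enable_repulsion && !params$enable_attraction)
    return(matrix(0, n, 2))
  pairwise_forces_cpp(as.numeric(x), as.numeric(y), params$R_i,
                      params$enable_repulsion, params$enable_attraction)
}

#' Wall repulsion
#'
#' One-dimensional soft-sphere repulsion from each tank wall: a wall at
#' normal distance `d < R_w` contributes an inward velocity `R_w/d` along
#' its normal (per-axis, so a corner gives the vector sum of two
#' contributions). Distances are floored at 1e-9 m.
#'
#' @param x,y positions inside the tank.
#' @param geometry a [tank_geometry()].
#' @param R_w wall repulsion radius (m).
#' @return `N x 2` matrix of velocity contributions (m/s).
#' @export
wall_force <- function(x, y, geometry, R_w) {
  stopifnot_inside(x, y, geometry)
  kick <- function(d) {
    d <- pmax(d, 1e-9)
    ifelse(d <= R_w, R_w / d, 0)   # magnitude 1 at the cutoff distance
  }
  fx <- kick(x - geometry$x_min) - kick(geometry$x_max - x)
  fy <- kick(y - geometry$y_min) - kick(geometry$y_max - y)
  cbind(fx, fy, deparse.level = 0)
}

#' Positional dynamics right-hand side
#'
#' `dx/dt = U + V e(theta) + I(x) + F_wall`: advection, active
#' propulsion, the pairwise soft-core interaction and the wall force. The
#' passive-tracer reduction keeps only `U + F_wall`; the repulsive-tracer
#' reduction adds `I(x)`.
#'
#' @param x,y positions.
#' @param theta,phi,A agent state vectors.
#' @param Ux,Uy,Umag sampled flow velocity and its magnitude.
#' @param geometry a [tank_geometry()].
#' @param params a [model_params()].
#' @return list with `vx`, `vy` (m/s).
#' @export
positional_rhs <- function(x, y, theta, phi, A, Ux, Uy, Umag, geometry, params) {
  act <- active_velocity(theta, phi, A, Umag, params)
  pint <- pairwise_interaction(x, y, params)
  wf <- wall_force(x, y, geometry, params$R_w)
  list(vx = Ux + act$vx + pint[, 1] + wf[, 1],
       vy = Uy + act$vy + pint[, 2] + wf[, 2])
}

# wrap angles to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
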