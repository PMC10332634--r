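#' Agent model parameters
#'
#' All constants of the jellyfish agent model, with defaults set to the
#' calibrated values used throughout the study: soft-core interaction
#' radius, angular (colored) noise, swimming-speed response, the three
#' angular coupling strengths (counter-current, turbulence avoidance, prey
#' search), the bell oscillator, the activity dynamics, the parametric
#' switch slopes, and the wall repulsion radius. Behavioural mechanisms can
#' be toggled individually, which reduces the model exactly to the passive
#' tracer, repulsive tracer, counter-current and turbulence-avoidance
#' variants.
#'
#' @param R_i soft-core interaction radius (m).
#' @param lambda_theta inverse correlation time of the angular noise (1/s).
#' @param D_0 angular noise intensity in the inactive state (rad^2 s^-3).
#' @param V_0 propulsion speed amplitude in the inactive state (m/s).
#' @param V_a,V_b speed response amplitude (m/s) and half-saturation (m/s)
#'   of the bilinear speed adaptation to `|U| + A`.
#' @param J bell pulsation shape parameter (dimensionless).
#' @param eps_U0 counter-current angular coupling (rad/s).
#' @param eps_C0 turbulence-avoidance angular coupling (rad/s).
#' @param eps_F0 prey-search angular coupling (rad/s).
#' @param omega_0 natural bell frequency in the inactive state (rad/s).
#' @param lambda_A activity decay rate (1/s).
#' @param f_phi,f_theta response parameters of bell frequency and angular
#'   noise to activity (dimensionless).
#' @param f_U half-saturation of the counter-current decoupling by prey
#'   concentration (units of the prey saturation F_0).
#' @param f_C,f_F,f_g response parameters of the turbulence-avoidance
#'   switch-off, prey-coupling switch-on and "greediness" switch-off
#'   (dimensionless).
#' @param R_w wall repulsion radius (m).
#' @param enable_counter_current,enable_turbulence_avoidance,enable_prey_orientation
#'   toggles for the three angular coupling terms.
#' @param enable_activity toggle for the activity ODE (off keeps A at its
#'   initial value, normally 0).
#' @param enable_freq_response,enable_noise_response,enable_speed_response
#'   toggles for the activity responses of bell frequency omega(A), noise
#'   intensity D(A) and propulsion speed V(|U|+A).
#' @param enable_propulsion toggle for active swimming (off gives tracers).
#' @param enable_repulsion toggle for the pairwise soft-core repulsion.
#' @param enable_attraction toggle for the (by default omitted) attractive
#'   pairwise term.
#' @param enable_phase_coupling stub for direct bell-phase coupling between
#'   agents; the model sets this coupling to zero and the toggle must stay
#'   `FALSE` (reserved for future work).
#' @return an object of class `model_params` (a validated list).
#' @examples
#' p <- model_params()
#' p$eps_U0
#' @export
model_params <- function(R_i = 0.1,
                         lambda_theta = 5,
                         D_0 = 0.1,
                         V_0 = 0.15,
                         V_a = 0.5,
                         V_b = 0.6,
                         J = 1.0,
                         eps_U0 = 0.16,
                         eps_C0 = 0.08,
                         eps_F0 = 0.16,
                         omega_0 = 1.2,
                         lambda_A = 0.005,
                         f_phi = 0.75,
                         f_theta = 0.75,
                         f_U = 0.05,
                         f_C = 0.2,
                         f_F = 0.2,
                         f_g = 100,
                         R_w = 0.1,
                         enable_counter_current = TRUE,
                         enable_turbulence_avoidance = TRUE,
                         enable_prey_orientation = TRUE,
                         enable_activity = TRUE,
                         enable_freq_response = TRUE,
                         enable_noise_response = TRUE,
                         enable_speed_response = TRUE,
                         enable_propulsion = TRUE,
                         enable_repulsion = TRUE,
                         enable_attraction = FALSE,
                         enable_phase_coupling = FALSE) {
  p <- as.list(environment())
  num <- c("R_i", "lambda_theta", "D_0", "V_0", "V_a", "V_b", "J", "eps_U0",
           "eps_C0", "eps_F0", "omega_0", "lambda_A", "f_phi", "f_theta",
           "f_U", "f_C", "f_F", "f_g", "R_w")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite scalar")
    if (v < 0) stop("parameter '", nm, "' must be non-negative")
  }
  if (p$V_b <= 0) stop("V_b must be positive")
  if (p$lambda_theta <= 0) stop("lambda_theta must be positive")
  if (p$enable_phase_coupling)
    stop("direct bell-phase coupling between agents is not implemented; ",
         "the model sets it to zero (enable_phase_coupling must be FALSE)")
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  on <- names(x)[vapply(x, isTRUE, logical(1))]
  num <- x[!vapply(x, is.logical, logical(1))]
  cat("  ", paste(sprintf("%s=%g", names(num), unlist(num)), collapse = ", "), "\n")
  cat("  enabled:", paste(sub("^enable_", "", on), collapse = ", "), "\n")
  invisible(x)
}

#' Fluid solver parameters
#'
#' @param rho fluid density (kg/m^3).
#' @param mu effective dynamic viscosity (N s/m^2).
#' @param dt_fluid fluid time step (s).
#' @param wall_speed tangential speed of the driven walls (m/s): the top
#'   lid in the cavity, both side walls in the double gyre.
#' @param inflow_peak peak of the Poiseuille inflow profile in the channel
#'   (m/s); negative values drive flow towards -x.
#' @param sor_omega successive over-relaxation factor in (0, 2).
#' @param sor_tol relative residual tolerance of the pressure solve.
#' @param sor_max_iter iteration cap of the pressure solve.
#' @return an object of class `fluid_params`.
#' @examples
#' fluid_params()$mu
#' @export
fluid_params <- function(rho = 1000,
                         mu = 0.4,
                         dt_fluid = 0.001,
                         wall_speed = 0.4,
                         inflow_peak = -0.045,
                         sor_omega = 1.7,
                         sor_tol = 1e-4,
                         sor_max_iter = 10000) {
  if (rho <= 0 || mu <= 0 || dt_fluid <= 0) stop("rho, mu, dt_fluid must be positive")
  if (sor_omega <= 0 || sor_omega >= 2) stop("sor_omega must lie in (0, 2)")
  structure(list(rho = rho, mu = mu, dt_fluid = dt_fluid,
                 wall_speed = wall_speed, inflow_peak = inflow_peak,
                 sor_omega = sor_omega, sor_tol = sor_tol,
                 sor_max_iter = as.integer(sor_max_iter)),
            class = "fluid_params")
}

#' Reynolds number from fluid parameters and flow scales
#'
#' `Re = rho * U * L / mu`. With the default fluid parameters the channel
#' scenario (`U` = 0.045 m/s, `L` = 40 m) gives `Re = 4500`.
#'
#' @param params a [fluid_params()] object.
#' @param U_scale characteristic speed (m/s), non-negative.
#' @param L_scale characteristic length (m), positive.
#' @return dimensionless Reynolds number.
#' @examples
#' reynolds_number(fluid_params(), 0.045, 40)
#' @export
reynolds_number <- function(params, U_scale, L_scale) {
  if (!inherits(params, "fluid_params")) stop("params must be a fluid_params object")
  if (U_scale < 0) stop("U_scale must be non-negative")
  if (L_scale <= 0) stop("L_scale must be positive")
  params$rho * U_scale * L_scale / params$mu
}
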