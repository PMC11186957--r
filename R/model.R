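#' @importFrom stats approxfun dnorm integrate optim optimize quantile rnorm
#'   runif sd var setNames
#' @importFrom utils head tail read.csv write.csv
NULL

## Stable convolution kernel:
##   int_0^t e^{-gam (t-u)} e^{-k u} du = (e^{-k t} - e^{-gam t}) / (gam - k)
## with a series limit when gam ~ k.
.conv_exp <- function(k, gam, t) {
  d <- gam - k
  if (abs(d) < 1e-8) t * exp(-k * t) * (1 - d * t / 2)
  else (exp(-k * t) - exp(-gam * t)) / d
}

#' Closed-form step response of the excitation-adaptation subsystem
#'
#' For a Heaviside input \eqn{s(t) = H(t)} and zero initial conditions the
#' signal subsystem has the closed-form solution
#' \deqn{s_{\rm eff}(t) = \frac{\tau_a}{\tau_a-\tau_e}
#'   \left(e^{-t/\tau_a} - e^{-t/\tau_e}\right), \qquad
#'   I(t) = 1 - e^{-t/\tau_a},}
#' which is nonnegative for \eqn{\tau_a > \tau_e}: the effective signal rises
#' on the excitation timescale and wanes on the adaptation timescale, tending
#' to 0 as \eqn{t \to \infty} while the inhibitor tends to 1.
#'
#' @param tau_e,tau_a Excitation and adaptation timescales, h
#'   (\code{0 < tau_e < tau_a}).
#' @param t Times in hours (\code{t >= 0}).
#' @return A data frame with columns \code{t}, \code{s_eff} and \code{I}.
#' @examples
#' step_response(0.260, 2.038, c(0, 0.614, 10))
#' @export
step_response <- function(tau_e, tau_a, t) {
  if (!(tau_e > 0 && tau_a > 0 && tau_e < tau_a))
    stop("degenerate timescales: need 0 < tau_e < tau_a", call. = FALSE)
  if (any(t < 0)) stop("step response defined for t >= 0", call. = FALSE)
  pref <- tau_a / (tau_a - tau_e)
  data.frame(t = t,
             s_eff = pref * (exp(-t / tau_a) - exp(-t / tau_e)),
             I = 1 - exp(-t / tau_a))
}

#' Time of the peak step response
#'
#' The effective signal under a step input is maximal at
#' \deqn{\tau_{\max} = \frac{\log\tau_a - \log\tau_e}
#'   {\tau_e^{-1} - \tau_a^{-1}},}
#' the characteristic time for the bulk to reach its maximum velocity under
#' constant stimulation. It separates the two regimes of the windowed cruise
#' problem (see \code{\link{solve_cruise_window}}).
#'
#' @inheritParams step_response
#' @return The peak time in hours.
#' @examples
#' tau_max(0.260, 2.038) # ~0.614 h
#' @export
tau_max <- function(tau_e, tau_a) {
  if (!(tau_e > 0 && tau_a > 0 && tau_e < tau_a))
    stop("degenerate timescales: need 0 < tau_e < tau_a", call. = FALSE)
  (log(tau_a) - log(tau_e)) / (1 / tau_e - 1 / tau_a)
}

#' Steady state under constant stimulation
#'
#' For constant field strength \eqn{s} the unique steady state is
#' \eqn{(v^\ast, s_{\rm eff}^\ast, I^\ast) = (0, 0, s)}: the tissue fully
#' adapts and stops. The state is stable because the system matrix has
#' eigenvalues \eqn{\{-\gamma, -\tau_e^{-1}, -\tau_a^{-1}\}}, all negative.
#'
#' @param params A \code{\link{model_params}} object.
#' @param s Constant normalized field strength.
#' @return A list with the steady state \code{state = c(v, s_eff, I)} and the
#'   \code{eigenvalues} of the system matrix.
#' @export
steady_state <- function(params, s) {
  stopifnot(inherits(params, "model_params"))
  A <- .system_matrix(params)
  b <- c(0, s / params$tau_e, s / params$tau_a)
  list(state = setNames(solve(A, -b), c("v", "s_eff", "I")),
       eigenvalues = sort(eigen(A, only.values = TRUE)$values))
}

## System matrix of the linear model d/dt (v, s_eff, I) = A x + b(t)
.system_matrix <- function(params) {
  with(params, matrix(c(-gamma, alpha,      0,
                        0,     -1 / tau_e, -1 / tau_e,
                        0,      0,         -1 / tau_a),
                      nrow = 3, byrow = TRUE))
}

## internal integrator core: s given as a plain function of time
.simulate_fun <- function(params, sfun, t_grid, clamp = TRUE,
                          rtol = 1e-8, atol = 1e-10, with_distance = FALSE) {
  g <- params$gamma; al <- params$alpha
  te <- params$tau_e; ta <- params$tau_a
  rhs <- function(t, y, p) {
    s <- sfun(t)
    force_sig <- if (clamp) max(y[2], 0) else y[2]
    d <- c(-g * y[1] + al * force_sig,
           (s - y[2] - y[3]) / te,
           (s - y[3]) / ta)
    if (with_distance) d <- c(d, y[1])
    list(d)
  }
  y0 <- numeric(if (with_distance) 4L else 3L)
  out <- deSolve::lsoda(y0, t_grid, rhs, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed to reach the requested tolerance; ",
         "istate = ", attr(out, "istate")[1], call. = FALSE)
  out
}

#' Simulate the excitation-adaptation velocity model
#'
#' Integrates
#' \deqn{\dot v = -\gamma v + \alpha\,\max(s_{\rm eff}, 0), \quad
#'   \dot s_{\rm eff} = \frac{s - (s_{\rm eff} + I)}{\tau_e}, \quad
#'   \dot I = \frac{s - I}{\tau_a}}
#' from zero initial conditions with an adaptive-step integrator (relative
#' tolerance 1e-8, absolute 1e-10). The clamp \eqn{\max(s_{\rm eff},0)}
#' encodes that the monolayer does not reverse when the effective signal
#' undershoots zero after the field is switched off; set \code{clamp = FALSE}
#' for the plain linear system (used by the optimal-control calculus).
#'
#' @param params A \code{\link{model_params}} object.
#' @param protocol A \code{\link{protocol_constant}} object (or other
#'   \code{stimulus_protocol}) giving \eqn{s(t)}.
#' @param t_grid Increasing output times in hours; defaults to 301 uniform
#'   points on \code{[0, T]}.
#' @param clamp Clamp the force term at zero effective signal (default TRUE).
#' @param rtol,atol Integrator tolerances.
#' @return A \code{trajectory}: data frame with columns \code{time_h},
#'   \code{velocity_um_per_h}, \code{s_eff}, \code{inhibitor}, and attributes
#'   \code{clamped} (whether the clamp was active anywhere) and \code{params}.
#' @examples
#' traj <- simulate_model(calibrated_params(), protocol_constant(1, 3))
#' tail(traj, 1) # v(3 h) ~ 29.85 um/h
#' @export
simulate_model <- function(params, protocol, t_grid = NULL, clamp = TRUE,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "model_params"),
            inherits(protocol, "stimulus_protocol"))
  if (is.null(t_grid))
    t_grid <- seq(0, protocol$duration, length.out = 301L)
  if (length(t_grid) < 2L || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing with at least two points",
         call. = FALSE)
  if (min(t_grid) < 0)
    stop("t_grid must lie in [0, T] (simulation starts at rest at t = 0)",
         call. = FALSE)
  grid <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  out <- .simulate_fun(params, protocol$fun, grid, clamp = clamp,
                       rtol = rtol, atol = atol)
  keep <- if (t_grid[1] > 0) -1L else seq_len(nrow(out))
  out <- out[keep, , drop = FALSE]
  traj <- data.frame(time_h = out[, 1],
                     velocity_um_per_h = out[, 2],
                     s_eff = out[, 3],
                     inhibitor = out[, 4])
  structure(traj,
            clamped = clamp && any(out[, 3] < 0),
            params = params,
            class = c("trajectory", "data.frame"))
}

#' Total distance travelled along a trajectory
#'
#' Trapezoidal quadrature of the velocity column over the time grid.
#'
#' @param traj A trajectory (any data frame with \code{time_h} and
#'   \code{velocity_um_per_h} columns).
#' @return Distance in \eqn{\mu}m.
#' @export
distance_travelled <- function(traj) {
  if (!is.data.frame(traj) ||
      !all(c("time_h", "velocity_um_per_h") %in% names(traj)))
    stop("need a trajectory with time_h and velocity_um_per_h columns",
         call. = FALSE)
  if (nrow(traj) < 2L) stop("trajectory has fewer than two points", call. = FALSE)
  t <- traj$time_h; v <- traj$velocity_um_per_h
  sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)
}

#' Model velocity at given times (fast path)
#'
#' Evaluates the model velocity at arbitrary times. For a single-pulse
#' protocol (constant strength on \eqn{[0, T]}, zero after) the solution is
#' evaluated in closed form, including the clamped coasting phase after the
#' effective signal crosses zero post switch-off; this is the hot path of the
#' MCMC likelihood. Other protocols fall back to the adaptive integrator.
#'
#' @inheritParams simulate_model
#' @param times Times in hours (need not be sorted).
#' @param tail_h How long after the protocol horizon the model is still
#'   evaluated (field off). Times beyond \code{T + tail_h} are permitted; the
#'   argument only matters for the integrator fallback grid.
#' @return Velocities in \eqn{\mu}m/h at \code{times}.
#' @export
model_velocity <- function(params, protocol, times, clamp = TRUE,
                           tail_h = NULL) {
  stopifnot(inherits(params, "model_params"),
            inherits(protocol, "stimulus_protocol"))
  if (.is_pulse(protocol) && clamp) {
    return(.v_pulse(times, params, strength = protocol$segments$strength[1],
                    t_end = protocol$duration))
  }
  horizon <- max(c(times, protocol$duration, protocol$duration + (tail_h %||% 0)))
  grid <- sort(unique(c(0, pmax(times, 0), horizon)))
  out <- .simulate_fun(params, protocol$fun, grid, clamp = clamp)
  stats::approx(out[, 1], out[, 2], xout = times, rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Closed-form clamped velocity for a single constant pulse of given strength
## on [0, t_end] followed by s = 0. Piecewise exponential sums; the zero
## crossing of s_eff after switch-off is located analytically, after which the
## velocity coasts as pure exponential decay.
.v_pulse <- function(t, params, strength = 1, t_end = 3) {
  g <- params$gamma; al <- params$alpha * strength
  ke <- 1 / params$tau_e; ka <- 1 / params$tau_a
  K <- ke / (ke - ka)
  v1f <- function(tt) al * K * (.conv_exp(ka, g, tt) - .conv_exp(ke, g, tt))
  se1 <- K * (exp(-ka * t_end) - exp(-ke * t_end))
  I1 <- 1 - exp(-ka * t_end)
  v1 <- v1f(t_end)
  A <- se1 + I1 * K
  B <- I1 * K
  taustar <- if (A > B && B > 0) log(A / B) / (ke - ka) else 0
  v2 <- function(tau) {
    tau_c <- pmin(tau, taustar)
    vc <- exp(-g * tau_c) * v1 +
      al * (A * .conv_exp(ke, g, tau_c) - B * .conv_exp(ka, g, tau_c))
    ifelse(tau <= taustar, vc, vc * exp(-g * (tau - taustar)))
  }
  ifelse(t <= t_end, v1f(pmax(t, 0)), v2(t - t_end))
}
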