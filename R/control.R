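## Optimal control of the excitation-adaptation model.
##
## Two families of solvers:
##  * isoperimetric problems (maximum distance, maximum terminal velocity):
##    the Hamiltonian is quadratic in the control through the charge-budget
##    multiplier, the adjoint system is linear with constant coefficients and
##    solves in closed form as sums of exponentials; the multiplier is fixed
##    by the budget in closed form.
##  * cruise problems (constant velocity, windowed constant velocity): the
##    Hamiltonian is linear in the control, the continuum problem concentrates
##    an impulsive transient, and the solver uses direct convex transcription:
##    piecewise-linear control on a knot grid, exact (Van Loan) discretisation
##    of the linear dynamics, quadratic tracking objective, equality
##    constraints handled through the KKT system.

## ---- exponential-sum utilities -------------------------------------------

## An exponential sum sum_i coef_i e^{rate_i t} as a list; evaluation and the
## particular solution of q' = a1 q + e1 p with q(T) = 0 stay in closed form.
.esum_eval <- function(es, t) {
  out <- 0
  for (i in seq_along(es$rate)) out <- out + es$coef[i] * exp(es$rate[i] * t)
  out
}

## Solve q' = a q + c * p(t), q(T) = 0 for p an exponential sum.
## For each term A e^{kt}: contribution cA (e^{kt} - e^{kT} e^{a(t-T)})/(k-a).
.esum_linode <- function(es, a, c, T) {
  rates <- c(); coefs <- c()
  for (i in seq_along(es$rate)) {
    k <- es$rate[i]; A <- es$coef[i]
    if (abs(k - a) < 1e-10)
      stop("resonant rates in adjoint quadrature (k ~ a); ",
           "perturb the timescales slightly", call. = FALSE)
    w <- c * A / (k - a)
    rates <- c(rates, k, a)
    coefs <- c(coefs, w, -w * exp((k - a) * T))
  }
  list(rate = rates, coef = coefs)
}

## definite integral of an exponential sum over [0, T]
.esum_integral <- function(es, T) {
  out <- 0
  for (i in seq_along(es$rate)) {
    k <- es$rate[i]; A <- es$coef[i]
    out <- out + if (abs(k) < 1e-12) A * T else A * (exp(k * T) - 1) / k
  }
  out
}

## product of two exponential sums
.esum_prod <- function(a, b) {
  rate <- as.vector(outer(a$rate, b$rate, `+`))
  coef <- as.vector(outer(a$coef, b$coef, `*`))
  list(rate = rate, coef = coef)
}

## ---- adjoint systems for the isoperimetric problems ----------------------

## Adjoints for the maximum-distance objective int v dt:
##   lambda_v' = -1 + gamma lambda_v,          lambda_v(T) = 0
##   lambda_se' = -alpha lambda_v + lambda_se / tau_e,  lambda_se(T) = 0
##   lambda_I'  = lambda_se / tau_e + lambda_I / tau_a, lambda_I(T) = 0
## lambda_v = (1 - e^{gamma (t-T)}) / gamma  (positive before T: future
## distance gained per unit of present velocity).
.adjoints_distance <- function(params, T) {
  g <- params$gamma; al <- params$alpha
  e1 <- 1 / params$tau_e; a1 <- 1 / params$tau_a
  lam_v <- list(rate = c(0, g), coef = c(1 / g, -exp(-g * T) / g))
  ## p' - e1 p = -alpha lam_v = -alpha/g + (alpha/g) e^{g(t-T)}
  B <- al / (g * e1)
  C <- (al / g) * exp(-g * T) / (g - e1)
  A <- -exp(-e1 * T) * (B + (al / g) / (g - e1))
  lam_se <- list(rate = c(e1, 0, g), coef = c(A, B, C))
  lam_I <- .esum_linode(lam_se, a1, e1, T)
  list(lam_v = lam_v, lam_se = lam_se, lam_I = lam_I)
}

## Adjoints for the terminal-velocity objective v(T), in Mayer form:
##   lambda_v = e^{gamma (t-T)}  (sensitivity of v(T) to v(t))
##   lambda_se' = -alpha lambda_v + lambda_se / tau_e,  lambda_se(T) = 0
.adjoints_terminal <- function(params, T) {
  g <- params$gamma; al <- params$alpha
  e1 <- 1 / params$tau_e; a1 <- 1 / params$tau_a
  ## Lagrange-form costate lambda_v = e^{gamma(t-T)} - 1 (zero at T); the
  ## forcing of the lambda_seff equation is -alpha (1 + lambda_v), i.e. the
  ## Mayer-form sensitivity e^{gamma(t-T)} of v(T) to v(t).
  lam_v <- list(rate = c(g, 0), coef = c(exp(-g * T), -1))
  C <- -al * exp(-g * T) / (g - e1)
  A <- -C * exp((g - e1) * T)
  lam_se <- list(rate = c(e1, g), coef = c(A, C))
  lam_I <- .esum_linode(lam_se, a1, e1, T)
  list(lam_v = lam_v, lam_se = lam_se, lam_I = lam_I)
}

## switching function psi = lambda_se / tau_e + lambda_I / tau_a as an
## exponential sum
.switching_esum <- function(adj, params) {
  e1 <- 1 / params$tau_e; a1 <- 1 / params$tau_a
  list(rate = c(adj$lam_se$rate, adj$lam_I$rate),
       coef = c(e1 * adj$lam_se$coef, a1 * adj$lam_I$coef))
}

## ---- control solution container ------------------------------------------

.control_solution <- function(kind, times, s_star, traj, adjoints = NULL,
                              mu_star = NA_real_, objective = NA_real_,
                              objective_units = "", extras = list()) {
  sol <- c(list(kind = kind,
                times = times,
                s_star = s_star,
                s_star_V_per_cm = field_to_physical(s_star),
                state = traj,
                adjoints = adjoints,
                mu_star = mu_star,
                objective = objective,
                objective_units = objective_units),
           extras)
  class(sol) <- "control_solution"
  sol
}

#' @export
print.control_solution <- function(x, ...) {
  cat(sprintf("Optimal control solution: %s on [0, %.3g h]\n",
              x$kind, max(x$times)))
  cat(sprintf("  objective: %.6g %s\n", x$objective, x$objective_units))
  if (is.finite(x$mu_star))
    cat(sprintf("  isoperimetric multiplier mu* = %.6g\n", x$mu_star))
  cat(sprintf("  field range: [%.4g, %.4g] normalized ([%.4g, %.4g] V/cm)\n",
              min(x$s_star), max(x$s_star),
              min(x$s_star_V_per_cm), max(x$s_star_V_per_cm)))
  if (!is.null(x$feasibility)) {
    f <- x$feasibility
    cat(sprintf("  budget satisfied: %s; clamp violation: %s\n",
                format(f$budget_ok), format(f$clamp_violated)))
  }
  invisible(x)
}

## evaluate adjoints (exponential sums) on a grid into a data frame
.adjoint_frame <- function(adj, times) {
  data.frame(lambda_v = .esum_eval(adj$lam_v, times),
             lambda_seff = .esum_eval(adj$lam_se, times),
             lambda_I = .esum_eval(adj$lam_I, times))
}

## common closing step for the two isoperimetric solvers
.solve_isoperimetric <- function(params, T, s_budget, adj, kind,
                                 objective_fn, objective_units, n_grid) {
  psi <- .switching_esum(adj, params)
  int_psi2 <- .esum_integral(.esum_prod(psi, psi), T)
  if (int_psi2 <= 1e-14)
    stop("degenerate problem: switching function vanishes identically",
         call. = FALSE)
  ## s* = psi / (2 mu*); budget fixes the positive root
  ## int s*^2 = int psi^2 / (4 mu*^2) = s_budget
  mu_star <- sqrt(int_psi2 / (4 * s_budget))
  scale <- 1 / (2 * mu_star)
  times <- seq(0, T, length.out = n_grid)
  sfun <- function(t) scale * .esum_eval(psi, t)
  s_star <- sfun(times)
  out <- .simulate_fun(params, sfun, times, clamp = TRUE,
                       rtol = 1e-10, atol = 1e-12, with_distance = TRUE)
  traj <- data.frame(time_h = out[, 1], velocity_um_per_h = out[, 2],
                     s_eff = out[, 3], inhibitor = out[, 4])
  budget_used <- scale^2 * int_psi2
  .control_solution(kind, times, s_star, traj,
                    adjoints = .adjoint_frame(adj, times),
                    mu_star = mu_star,
                    objective = objective_fn(out),
                    objective_units = objective_units,
                    extras = list(
                      s_budget = s_budget,
                      budget_used = budget_used,
                      sfun = sfun,
                      feasibility = list(
                        budget_ok = abs(budget_used - s_budget) <=
                          1e-6 * s_budget,
                        clamp_violated = any(out[, 3] < -1e-9))))
}

#' Maximum-distance stimulation under a charge budget
#'
#' Finds the field \eqn{s^\ast(t)} maximising the total distance
#' \eqn{\int_0^T v\,dt} subject to the isoperimetric charge constraint
#' \eqn{\int_0^T s^2 dt = s_{\rm budget}}. By Pontryagin's principle the
#' optimal field is proportional to the switching function
#' \eqn{\psi = \tau_e^{-1}\lambda_{s_{\rm eff}} + \tau_a^{-1}\lambda_I},
#' \eqn{s^\ast = \psi/(2\mu^\ast)}, where the adjoints solve a linear system
#' with zero terminal conditions and are computed in closed form as sums of
#' exponentials, and the constant multiplier is fixed by the budget,
#' \eqn{\mu^\ast = \frac{1}{2}\sqrt{\int\psi^2 dt / s_{\rm budget}}}.
#' \eqn{\psi(t)} equals the sensitivity kernel of the distance to the field
#' (verified against a finite-difference oracle in the test suite), so the
#' solution is the exact optimum of the unclamped linear model. The state
#' trajectory is then simulated under the physical (clamped) model; the
#' effective signal can undershoot zero near \eqn{T}, which is recorded in
#' the feasibility flags.
#'
#' @param params A \code{\link{model_params}} object.
#' @param horizon Stimulation horizon \eqn{T} in hours (default 3, the
#'   duration for which a constant 3 V/cm field exhausts the canonical
#'   27 V^2 h/cm^2 budget).
#' @param s_budget Charge budget in normalized units squared times hours
#'   (default 3, i.e. 27 V^2 h/cm^2).
#' @param n_grid Reporting grid size (default 301).
#' @return A \code{control_solution} with the optimal field (normalized and
#'   V/cm), state trajectory, closed-form adjoints, multiplier
#'   \code{mu_star}, objective (distance, \eqn{\mu}m) and feasibility flags.
#' @examples
#' sol <- solve_max_distance(calibrated_params())
#' sol$objective # distance under s*, um
#' @export
solve_max_distance <- function(params, horizon = 3, s_budget = 3,
                               n_grid = 301L) {
  stopifnot(inherits(params, "model_params"))
  if (horizon <= 0 || s_budget <= 0)
    stop("horizon and s_budget must be positive", call. = FALSE)
  adj <- .adjoints_distance(params, horizon)
  .solve_isoperimetric(params, horizon, s_budget, adj, "max_distance",
                       objective_fn = function(out) tail(out[, 5], 1),
                       objective_units = "um", n_grid = n_grid)
}

#' Maximum terminal-velocity stimulation under a charge budget
#'
#' Maximises \eqn{v(T)} under the same charge budget as
#' \code{\link{solve_max_distance}}. The terminal-payoff adjoint is
#' \eqn{\lambda_v = e^{\gamma(t-T)}}, the sensitivity of the terminal
#' velocity to present velocity; the remaining adjoints and the budget
#' normalization are as in the maximum-distance problem. The optimal field
#' rises towards the end of stimulation but returns to zero at \eqn{t = T}:
#' field applied in the last instants cannot be transduced into velocity
#' before the horizon, so the true sensitivity of \eqn{v(T)} to the field
#' vanishes there.
#'
#' @inheritParams solve_max_distance
#' @return A \code{control_solution}; the objective is \eqn{v(T)} in
#'   \eqn{\mu}m/h.
#' @export
solve_max_terminal_velocity <- function(params, horizon = 3, s_budget = 3,
                                        n_grid = 301L) {
  stopifnot(inherits(params, "model_params"))
  if (horizon <= 0 || s_budget <= 0)
    stop("horizon and s_budget must be positive", call. = FALSE)
  adj <- .adjoints_terminal(params, horizon)
  .solve_isoperimetric(params, horizon, s_budget, adj, "max_terminal_velocity",
                       objective_fn = function(out) tail(out[, 2], 1),
                       objective_units = "um/h", n_grid = n_grid)
}

## ---- direct transcription machinery for the cruise problems --------------

## Exact discretisation of xdot = A x + b s(t) for piecewise-linear s on a
## uniform grid, via the Van Loan augmented exponential:
##   x_{k+1} = E x_k + (G1 - G2/h) s_k + (G2/h) s_{k+1}
## with E = e^{Ah}, G1 = int_0^h e^{A(h-u)} b du, G2 = int_0^h e^{A(h-u)} b u du.
.discrete_dynamics <- function(params, h) {
  A <- .system_matrix(params)
  b <- c(0, 1 / params$tau_e, 1 / params$tau_a)
  M <- rbind(cbind(A, b, rep(0, 3)), c(rep(0, 4), 1), rep(0, 5))
  EM <- as.matrix(Matrix::expm(M * h))
  list(E = EM[1:3, 1:3],
       Bk = EM[1:3, 4] - EM[1:3, 5] / h,
       Bk1 = EM[1:3, 5] / h)
}

## Linear map from control knots to the velocity at the knots: v = G s
.velocity_map <- function(params, knots) {
  N <- length(knots)
  h <- knots[2] - knots[1]
  dd <- .discrete_dynamics(params, h)
  G <- matrix(0, N, N)
  cur <- matrix(0, 3, N)
  for (k in seq_len(N - 1L)) {
    cur <- dd$E %*% cur
    cur[, k] <- cur[, k] + dd$Bk
    cur[, k + 1] <- cur[, k + 1] + dd$Bk1
    G[k + 1L, ] <- cur[1, ]
  }
  G
}

## trapezoid weights on a uniform grid
.trap_weights <- function(x) {
  h <- x[2] - x[1]
  w <- rep(h, length(x))
  w[1] <- w[length(x)] <- h / 2
  w
}

## Solve the discrete tracking problem:
##   min sum w Phi (v - v*)^2 + penalty * sum w s^2,  v = G s,
## optionally with terminal equality v_N = v*.
.solve_tracking_qp <- function(G, w, Phi, v_star, penalty, terminal) {
  N <- nrow(G)
  H <- crossprod(G, (w * Phi) * G) + diag(penalty * w, N)
  f <- crossprod(G, (w * Phi) * v_star)
  if (terminal) {
    gN <- G[N, ]
    K <- rbind(cbind(2 * H, gN), c(gN, 0))
    sol <- solve(K, c(2 * f, v_star))
    list(s = sol[seq_len(N)], nu = sol[N + 1L])
  } else {
    list(s = as.vector(solve(H, f)), nu = 0)
  }
}

## backward integration of the tracking-problem adjoints given the state:
##   lambda_v'    = -2 Phi (v - v*) + gamma lambda_v
##   lambda_seff' = -alpha lambda_v + lambda_seff / tau_e
##   lambda_I'    = lambda_seff / tau_e + lambda_I / tau_a
## terminal conditions lambda_seff(T) = lambda_I(T) = 0 and lambda_v(T) equal
## to the terminal-constraint multiplier (0 when unconstrained).
.tracking_adjoints <- function(params, times, vfun, Phifun, v_star, lam_vT) {
  g <- params$gamma; al <- params$alpha
  e1 <- 1 / params$tau_e; a1 <- 1 / params$tau_a
  rhs <- function(t, y, p) {
    list(c(-2 * Phifun(t) * (vfun(t) - v_star) + g * y[1],
           -al * y[1] + e1 * y[2],
           e1 * y[2] + a1 * y[3]))
  }
  ## integrate backwards in tau = T - t on the (uniform) reporting grid
  T <- max(times)
  tau_grid <- T - rev(times)
  out <- deSolve::lsoda(c(lam_vT, 0, 0), tau_grid, function(tau, y, p) {
    d <- rhs(T - tau, y, p)[[1]]
    list(-d)
  }, rtol = 1e-8, atol = 1e-10)
  lam <- out[rev(seq_len(nrow(out))), 2:4, drop = FALSE]
  data.frame(lambda_v = lam[, 1], lambda_seff = lam[, 2], lambda_I = lam[, 3])
}

## shared core for the two cruise solvers
.solve_cruise_core <- function(params, horizon, v_star, Phi_knots, Phifun,
                               knots, penalty, terminal, s_max, kind,
                               n_grid) {
  G <- .velocity_map(params, knots)
  w <- .trap_weights(knots)
  qp <- .solve_tracking_qp(G, w, Phi_knots, v_star, penalty, terminal)
  s_knots <- qp$s
  clipped <- FALSE
  if (!is.null(s_max)) {
    clipped <- any(s_knots > s_max)
    s_knots <- pmin(s_knots, s_max)
  }
  sfun <- approxfun(knots, s_knots, rule = 2)
  times <- seq(0, horizon, length.out = n_grid)
  out <- .simulate_fun(params, sfun, times, clamp = TRUE,
                       rtol = 1e-10, atol = 1e-12)
  traj <- data.frame(time_h = out[, 1], velocity_um_per_h = out[, 2],
                     s_eff = out[, 3], inhibitor = out[, 4])
  vfun <- approxfun(times, traj$velocity_um_per_h, rule = 2)
  ## fixed-grid trapezoid: the integrand is ~0 on the plateau and spiky at
  ## onset, which defeats adaptive quadrature
  tq <- seq(0, horizon, length.out = 4001L)
  fq <- Phifun(tq) * (vfun(tq) - v_star)^2
  obj <- sum(diff(tq) * (head(fq, -1) + tail(fq, -1)) / 2)
  adjoints <- .tracking_adjoints(params, times, vfun, Phifun, v_star,
                                 lam_vT = qp$nu)
  s_rep <- sfun(times)
  .control_solution(kind, times, s_rep, traj,
                    adjoints = adjoints,
                    objective = obj,
                    objective_units = "(um/h)^2 h",
                    extras = list(
                      v_star = v_star,
                      knots = knots,
                      s_knots = s_knots,
                      penalty = penalty,
                      peak_field_V_per_cm = field_to_physical(max(s_rep)),
                      terminal_velocity = tail(traj$velocity_um_per_h, 1),
                      terminal_error = abs(tail(traj$velocity_um_per_h, 1) -
                                             v_star),
                      feasibility = list(
                        budget_ok = NA,
                        clamp_violated = any(out[, 3] < -1e-9),
                        field_clipped = clipped)))
}

#' Cruise control: hold the bulk velocity at a target
#'
#' Designs the field so the bulk velocity reaches and holds a target
#' \eqn{v^\ast}, by minimising the tracking functional
#' \eqn{\int_0^T (v - v^\ast)^2 dt} with the terminal constraint
#' \eqn{v(T) = v^\ast}. Because the model is linear in the field and the
#' functional does not penalise the field itself, the continuum problem
#' concentrates an unbounded impulse at \eqn{t = 0} (the velocity is asked to
#' jump); the solver therefore parameterises the control as piecewise linear
#' on knots at the experimental acquisition cadence (10 min by default, the
#' timescale on which the stimulation hardware is programmed) and solves the
#' resulting convex problem exactly through its KKT system, with the linear
#' dynamics discretised exactly (matrix exponentials). The reported peak
#' field strength is therefore a property of the stated control cadence;
#' finer cadences grow the initial peak without bound (as the inverse square
#' of the knot spacing) and are deliberately not the default.
#'
#' With a field cap \code{s_max}, the physical control is
#' \eqn{\min(s^\ast, s_{\max})} and the state is re-simulated under the
#' clipped field; the terminal-velocity error it induces decreases
#' monotonically as the cap is raised.
#'
#' @param params A \code{\link{model_params}} object.
#' @param horizon Stimulation horizon \eqn{T} in hours.
#' @param v_star Target bulk velocity, \eqn{\mu}m/h (nonnegative).
#' @param s_max Optional cap on the normalized field strength.
#' @param knot_dt Control knot spacing in hours (default 1/6, the 10-min
#'   acquisition cadence).
#' @param penalty Tikhonov weight on \eqn{\int s^2 dt} that selects the
#'   minimum-field solution among near-optimal ones; default \code{1e-8},
#'   numerically negligible against the tracking term.
#' @param n_grid Reporting grid size (default 301).
#' @return A \code{control_solution}; extras include
#'   \code{peak_field_V_per_cm}, \code{terminal_velocity},
#'   \code{terminal_error} and the control knots.
#' @export
solve_cruise_bvp <- function(params, horizon = 3, v_star, s_max = NULL,
                             knot_dt = 1 / 6, penalty = 1e-8, n_grid = 301L) {
  stopifnot(inherits(params, "model_params"), v_star >= 0, horizon > 0)
  if (v_star == 0) {
    times <- seq(0, horizon, length.out = n_grid)
    traj <- data.frame(time_h = times, velocity_um_per_h = 0,
                       s_eff = 0, inhibitor = 0)
    return(.control_solution("cruise", times, rep(0, n_grid), traj,
                             adjoints = data.frame(lambda_v = numeric(n_grid),
                                                   lambda_seff = numeric(n_grid),
                                                   lambda_I = numeric(n_grid)),
                             objective = 0, objective_units = "(um/h)^2 h",
                             extras = list(v_star = 0,
                                           peak_field_V_per_cm = 0,
                                           terminal_velocity = 0,
                                           terminal_error = 0,
                                           feasibility = list(
                                             budget_ok = NA,
                                             clamp_violated = FALSE,
                                             field_clipped = FALSE))))
  }
  knots <- seq(0, horizon, by = knot_dt)
  if (abs(tail(knots, 1) - horizon) > 1e-9)
    stop("horizon must be a multiple of the knot spacing", call. = FALSE)
  .solve_cruise_core(params, horizon, v_star,
                     Phi_knots = rep(1, length(knots)),
                     Phifun = function(t) rep(1, length(t)),
                     knots = knots, penalty = penalty, terminal = TRUE,
                     s_max = s_max, kind = "cruise", n_grid = n_grid)
}

#' Smooth bump weight for windowed objectives
#'
#' Product of two logistic factors approximating the indicator of
#' \eqn{[t_1, t_2]}:
#' \deqn{\Phi(t) = \frac{1}{1 + e^{-(t - t_1)/\epsilon}} \cdot
#'   \frac{1}{1 + e^{-(t_2 - t)/\epsilon}}.}
#' \eqn{\epsilon} sets the transition length scale; \eqn{\Phi} is symmetric
#' under \eqn{t \mapsto t_1 + t_2 - t} and equals 1/2 at the window edges
#' when they are well separated.
#'
#' @param t Times in hours.
#' @param t1,t2 Window start and end, hours (\code{t1 < t2}).
#' @param epsilon Transition length scale in hours (positive).
#' @return Weights in \code{[0, 1]}.
#' @export
bump <- function(t, t1, t2, epsilon) {
  stopifnot(t1 < t2, epsilon > 0)
  1 / (1 + exp(-(t - t1) / epsilon)) / (1 + exp(-(t2 - t) / epsilon))
}

#' Windowed cruise control
#'
#' Holds the bulk velocity at \eqn{v^\ast} only inside a window
#' \eqn{[t_1, t_2]} with \eqn{t_2 = T - t_1}, by minimising
#' \eqn{\int_0^T \Phi(t)(v - v^\ast)^2 dt} with the smooth bump weight
#' \code{\link{bump}} and no terminal velocity constraint; the state starts
#' from rest. The control knots resolve the bump transition scale
#' (\code{knot_dt = epsilon} by default). The solution changes regime at
#' \eqn{\tau_{\max}} (see \code{\link{tau_max}}): for \eqn{t_1 > \tau_{\max}}
#' the field can ramp up gradually, the initial field strength is near zero
#' and the velocity approaches the target from below without overshoot; for
#' \eqn{t_1 < \tau_{\max}} the target must be reached faster than the natural
#' rise time, the initial field is large and the velocity overshoots before
#' settling. The peak field scales linearly with \eqn{v^\ast}.
#'
#' @inheritParams solve_cruise_bvp
#' @param t1 Window start in hours, \code{0 < t1 < horizon/2}; the window end
#'   is \code{horizon - t1}.
#' @param epsilon Bump transition scale in hours (default 1/50).
#' @param knot_dt Control knot spacing (default \code{epsilon}).
#' @return A \code{control_solution}; extras include \code{s0}
#'   (initial field strength), \code{plateau_error} (max deviation from
#'   \eqn{v^\ast} inside the window) and \code{overshoot} (max of
#'   \eqn{v - v^\ast} inside the window).
#' @export
solve_cruise_window <- function(params, horizon = 3, t1, v_star,
                                epsilon = 1 / 50, knot_dt = epsilon,
                                penalty = 1e-6, n_grid = 301L) {
  stopifnot(inherits(params, "model_params"), v_star >= 0, horizon > 0,
            epsilon > 0)
  if (!(t1 > 0 && t1 < horizon / 2))
    stop("need 0 < t1 < horizon/2 (window end is horizon - t1)", call. = FALSE)
  t2 <- horizon - t1
  n_knots <- ceiling(horizon / knot_dt) + 1L
  knots <- seq(0, horizon, length.out = n_knots)
  Phifun <- function(t) bump(t, t1, t2, epsilon)
  sol <- .solve_cruise_core(params, horizon, v_star,
                            Phi_knots = Phifun(knots), Phifun = Phifun,
                            knots = knots, penalty = penalty,
                            terminal = FALSE, s_max = NULL,
                            kind = "cruise_window", n_grid = n_grid)
  win <- sol$times >= t1 & sol$times <= t2
  v <- sol$state$velocity_um_per_h
  sol$t1 <- t1; sol$t2 <- t2; sol$epsilon <- epsilon
  sol$s0 <- sol$s_star[1]
  sol$plateau_error <- max(abs(v[win] - v_star))
  ## overshoot above the target anywhere (it occurs at the window edge when
  ## the waiting time is shorter than the natural rise time)
  sol$overshoot <- max(v - v_star)
  sol
}

#' Bang-bang stimulation policy
#'
#' When the charge budget is replaced by a bound \eqn{0 \le s \le s_{\max}}
#' the Hamiltonian of the distance problem is linear in the field and the
#' optimal policy is bang-bang: \eqn{s^\ast = s_{\max}} wherever the
#' switching function
#' \eqn{\psi = \tau_e^{-1}\lambda_{s_{\rm eff}} + \tau_a^{-1}\lambda_I}
#' (computed from the budget-free distance adjoints) is positive, 0
#' elsewhere. At the calibrated parameters \eqn{\psi > 0} on all of
#' \eqn{[0, T)}, so the optimal policy is the constant pulse at full
#' strength: the protocol practitioners converged on by iteration.
#'
#' @inheritParams solve_max_distance
#' @param s_max Upper bound on the normalized field strength.
#' @return A \code{control_solution}; extras include the switching function
#'   values and the switching times (sign changes), and the objective is the
#'   distance travelled.
#' @export
bang_bang_policy <- function(params, horizon = 3, s_max = 1, n_grid = 301L) {
  stopifnot(inherits(params, "model_params"), s_max > 0, horizon > 0)
  adj <- .adjoints_distance(params, horizon)
  psi <- .switching_esum(adj, params)
  times <- seq(0, horizon, length.out = n_grid)
  psi_t <- .esum_eval(psi, times)
  sfun <- function(t) ifelse(.esum_eval(psi, t) > 0, s_max, 0)
  out <- .simulate_fun(params, sfun, times, clamp = TRUE,
                       rtol = 1e-10, atol = 1e-12, with_distance = TRUE)
  traj <- data.frame(time_h = out[, 1], velocity_um_per_h = out[, 2],
                     s_eff = out[, 3], inhibitor = out[, 4])
  sign_change <- which(diff(sign(psi_t[-length(psi_t)])) != 0)
  .control_solution("bang_bang", times, ifelse(psi_t > 0, s_max, 0), traj,
                    adjoints = .adjoint_frame(adj, times),
                    objective = tail(out[, 5], 1),
                    objective_units = "um",
                    extras = list(
                      s_max = s_max,
                      switching_function = psi_t,
                      switching_times = times[sign_change],
                      feasibility = list(budget_ok = NA,
                                         clamp_violated = any(out[, 3] < -1e-9))))
}

## ---- finite-difference verification oracle -------------------------------

#' Finite-difference gradient oracle for control objectives
#'
#' Independent verification of the adjoint calculus: evaluates the objective
#' of a control problem for a piecewise-linear control on a uniform grid and
#' returns its central finite-difference gradient with respect to the control
#' values. For isoperimetric kinds the gradient of the budget functional
#' \eqn{\int s^2 dt} is returned as well, so first-order optimality can be
#' checked by projecting the objective gradient onto the tangent space of the
#' budget sphere. Objectives are evaluated on the unclamped (linear) model,
#' the system for which the adjoint solutions are exact.
#'
#' @param problem A list with \code{kind} (one of \code{"max_distance"},
#'   \code{"max_terminal_velocity"}, \code{"cruise"}, \code{"cruise_window"}),
#'   \code{horizon}, and the fields the kind requires (\code{s_budget},
#'   \code{v_star}, \code{t1}, \code{epsilon}).
#' @param params A \code{\link{model_params}} object.
#' @param s_grid Control values on a uniform grid over
#'   \code{[0, horizon]}.
#' @param step Finite-difference step (default 1e-4).
#' @return A list with \code{gradient}, \code{objective},
#'   \code{constraint_gradient} (isoperimetric kinds; otherwise NULL) and
#'   \code{projected_gradient} (gradient projected onto the budget-sphere
#'   tangent space, isoperimetric kinds only).
#' @export
gradient_oracle <- function(problem, params, s_grid, step = 1e-4) {
  stopifnot(is.list(problem), !is.null(problem$kind), !is.null(problem$horizon))
  if (step <= sqrt(.Machine$double.eps) / 100)
    stop("finite-difference step underflow", call. = FALSE)
  N <- length(s_grid)
  times <- seq(0, problem$horizon, length.out = N)
  w <- .trap_weights(times)
  objective <- function(s) {
    sfun <- approxfun(times, s, rule = 2)
    out <- .simulate_fun(params, sfun, times, clamp = FALSE,
                         rtol = 1e-10, atol = 1e-12, with_distance = TRUE)
    switch(problem$kind,
           max_distance = tail(out[, 5], 1),
           max_terminal_velocity = tail(out[, 2], 1),
           cruise = sum(w * (out[, 2] - problem$v_star)^2),
           cruise_window = {
             Phi <- bump(times, problem$t1,
                         problem$horizon - problem$t1,
                         problem$epsilon %||% 1 / 50)
             sum(w * Phi * (out[, 2] - problem$v_star)^2)
           },
           stop("unknown problem kind: ", problem$kind, call. = FALSE))
  }
  grad <- vapply(seq_len(N), function(i) {
    sp <- s_grid; sm <- s_grid
    sp[i] <- sp[i] + step
    sm[i] <- sm[i] - step
    (objective(sp) - objective(sm)) / (2 * step)
  }, 1)
  res <- list(gradient = grad, objective = objective(s_grid),
              constraint_gradient = NULL, projected_gradient = NULL)
  if (problem$kind %in% c("max_distance", "max_terminal_velocity")) {
    ## exact gradient of int (interp s)^2 dt for the piecewise-linear
    ## interpolant (hat-function quadrature, consistent with the objective's
    ## own discretisation)
    h <- times[2] - times[1]
    cg <- numeric(N)
    cg[1] <- h / 3 * (2 * s_grid[1] + s_grid[2])
    cg[N] <- h / 3 * (s_grid[N - 1] + 2 * s_grid[N])
    if (N > 2) {
      i <- 2:(N - 1)
      cg[i] <- h / 3 * (s_grid[i - 1] + 4 * s_grid[i] + s_grid[i + 1])
    }
    cg <- 2 * cg
    res$constraint_gradient <- cg
    res$projected_gradient <- grad - sum(grad * cg) / sum(cg * cg) * cg
  }
  res
}
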