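#' Configuration for synthetic bulk-velocity traces
#'
#' Describes the generator that stands in for the experimental PIV-derived
#' bulk-velocity data: the model and protocol to simulate, the sampling
#' cadence (10 min by default, matching the imaging interval), the additive
#' iid Gaussian observation noise, and the length of the post-stimulation
#' decay tail that is recorded with the field off (2.5 h by default, the
#' window used for the friction-rate fit).
#'
#' @param params A \code{\link{model_params}} object.
#' @param protocol A \code{stimulus_protocol}; default the canonical 3 h
#'   pulse at 3 V/cm (s = 1).
#' @param dt Sampling interval in hours (default 1/6, i.e. 10 min).
#' @param sigma Observation noise standard deviation, \eqn{\mu}m/h
#'   (default 3; nonnegative).
#' @param tail_h Post-stimulation tail duration in hours (default 2.5;
#'   nonnegative).
#' @param seed Integer seed for the noise draw.
#' @return A \code{synth_config} object.
#' @export
synth_config <- function(params, protocol = protocol_constant(1, 3),
                         dt = 1 / 6, sigma = 3, tail_h = 2.5, seed = NULL) {
  stopifnot(inherits(params, "model_params"),
            inherits(protocol, "stimulus_protocol"))
  if (!(dt > 0)) stop("sampling interval must be positive", call. = FALSE)
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  if (tail_h < 0) stop("tail duration must be nonnegative", call. = FALSE)
  structure(list(params = params, protocol = protocol, dt = dt,
                 sigma = sigma, tail_h = tail_h, seed = seed),
            class = "synth_config")
}

#' Generate a synthetic bulk-velocity trace
#'
#' Simulates the model under the configured protocol for \eqn{[0, T]} and
#' with the field off for the tail, samples the velocity at the configured
#' cadence, and adds iid Gaussian noise. The switch-off time recorded on the
#' trace is the protocol horizon \eqn{T}.
#'
#' @param config A \code{\link{synth_config}}.
#' @return A \code{\link{velocity_trace}} with attribute \code{sigma}.
#' @examples
#' cfg <- synth_config(calibrated_params(), sigma = 0)
#' tr <- generate_trace(cfg)
#' @export
generate_trace <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  T <- config$protocol$duration
  times <- seq(0, T + config$tail_h, by = config$dt)
  v <- model_velocity(config$params, config$protocol, times,
                      tail_h = config$tail_h)
  if (!is.null(config$seed)) set.seed(config$seed)
  noise <- if (config$sigma > 0) rnorm(length(v), 0, config$sigma) else 0
  tr <- velocity_trace(times, v + noise, t_end = T)
  attr(tr, "sigma") <- config$sigma
  tr
}

#' Generate a synthetic post-stimulation decay trace
#'
#' Pure exponential decay \eqn{v(t) = v_0 e^{-\gamma t}} sampled at the
#' given cadence with iid Gaussian noise; the switch-off time is 0, so the
#' whole trace is post-stimulation. This is the fixture for the
#' friction-rate fit (\code{\link{fit_gamma_decay}}).
#'
#' @param gamma Decay rate, 1/h (positive).
#' @param v0 Initial velocity, \eqn{\mu}m/h (positive).
#' @param sigma Noise standard deviation, \eqn{\mu}m/h (default 2).
#' @param duration Trace length in hours (default 2.5).
#' @param dt Sampling interval in hours (default 1/6).
#' @param seed Integer seed.
#' @return A \code{\link{velocity_trace}} with \code{t_end = 0}.
#' @export
generate_decay_trace <- function(gamma, v0, sigma = 2, duration = 2.5,
                                 dt = 1 / 6, seed = NULL) {
  stopifnot(gamma > 0, v0 > 0, sigma >= 0, duration > 0, dt > 0)
  times <- seq(0, duration, by = dt)
  v <- v0 * exp(-gamma * times)
  if (!is.null(seed)) set.seed(seed)
  noise <- if (sigma > 0) rnorm(length(v), 0, sigma) else 0
  tr <- velocity_trace(times, v + noise, t_end = 0)
  attr(tr, "sigma") <- sigma
  tr
}
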