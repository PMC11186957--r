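#' Kinetic parameters of the excitation-adaptation velocity model
#'
#' Bundles the four kinetic constants of the bulk-velocity model: the friction
#' rate \eqn{\gamma} (1/h), the force responsiveness \eqn{\alpha}
#' (\eqn{\mu}m/h\eqn{^2}), and the excitation and adaptation timescales
#' \eqn{\tau_e < \tau_a} (h). The model assumes excitation is much faster than
#' adaptation, so \code{tau_e < tau_a} is enforced.
#'
#' @param gamma Friction (velocity decay) rate, 1/h. Must be positive.
#' @param alpha Force responsiveness: active force per unit mass produced per
#'   unit of effective signal, \eqn{\mu}m/h\eqn{^2}. Must be positive.
#' @param tau_e Excitation timescale, h. Must be positive and smaller than
#'   \code{tau_a}.
#' @param tau_a Adaptation timescale, h. Must be positive.
#'
#' @return An object of class \code{model_params}.
#' @examples
#' model_params(gamma = 1.765, alpha = 149.92, tau_e = 0.260, tau_a = 2.038)
#' @export
model_params <- function(gamma, alpha, tau_e, tau_a) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L,
            is.numeric(alpha), length(alpha) == 1L,
            is.numeric(tau_e), length(tau_e) == 1L,
            is.numeric(tau_a), length(tau_a) == 1L)
  if (!all(is.finite(c(gamma, alpha, tau_e, tau_a))))
    stop("model parameters must be finite", call. = FALSE)
  if (gamma <= 0 || alpha <= 0 || tau_e <= 0 || tau_a <= 0)
    stop("model parameters must be strictly positive", call. = FALSE)
  if (tau_e >= tau_a)
    stop("excitation must be faster than adaptation: tau_e < tau_a required",
         call. = FALSE)
  structure(list(gamma = gamma, alpha = alpha, tau_e = tau_e, tau_a = tau_a),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Excitation-adaptation model parameters\n")
  cat(sprintf("  gamma (friction):        %.4g 1/h\n", x$gamma))
  cat(sprintf("  alpha (responsiveness):  %.4g um/h^2\n", x$alpha))
  cat(sprintf("  tau_e (excitation):      %.4g h\n", x$tau_e))
  cat(sprintf("  tau_a (adaptation):      %.4g h\n", x$tau_a))
  invisible(x)
}

#' Parameters at the published calibration point
#'
#' Convenience constructor for the posterior-mean parameter set obtained by
#' calibrating the model to bulk-velocity data from 3 V/cm pulse stimulation
#' of MDCK monolayers: \eqn{\gamma = 1.765} 1/h, \eqn{\alpha = 149.92}
#' \eqn{\mu}m/h\eqn{^2}, \eqn{\tau_e = 0.260} h, \eqn{\tau_a = 2.038} h.
#'
#' @return A \code{model_params} object.
#' @export
calibrated_params <- function() {
  model_params(gamma = 1.765, alpha = 149.92, tau_e = 0.260, tau_a = 2.038)
}

## Reference field strength: 1 normalized unit of s corresponds to 3 V/cm.
REFERENCE_FIELD_V_PER_CM <- 3

#' Convert between normalized and physical field strength
#'
#' The model works in normalized field units in which 1 corresponds to the
#' canonical experimental field strength of 3 V/cm. These helpers convert a
#' normalized strength to V/cm and back.
#'
#' @param s Normalized field strength (dimensionless).
#' @param E Physical field strength in V/cm.
#' @param reference Reference field in V/cm corresponding to 1 normalized
#'   unit. Default 3.
#' @return A numeric vector in the other unit system.
#' @examples
#' field_to_physical(1)    # 3 V/cm
#' field_to_normalized(9)  # 3
#' @export
field_to_physical <- function(s, reference = REFERENCE_FIELD_V_PER_CM) {
  s * reference
}

#' @rdname field_to_physical
#' @export
field_to_normalized <- function(E, reference = REFERENCE_FIELD_V_PER_CM) {
  E / reference
}

#' Stimulation protocols
#'
#' A stimulation protocol is the normalized field strength \eqn{s(t)} on a
#' horizon \eqn{[0, T]}. Protocols are represented either as an ordered set of
#' piecewise-constant/linear segments or as a dense grid with linear
#' interpolation; both evaluate to a vectorized function of time.
#' \code{protocol_constant} builds a single constant segment,
#' \code{protocol_segments} a general piecewise-constant protocol and
#' \code{protocol_grid} a densely sampled protocol.
#'
#' @param strength Normalized field strength (1 corresponds to 3 V/cm).
#' @param duration Horizon \eqn{T} in hours.
#' @param segments A data frame with columns \code{t0}, \code{t1},
#'   \code{strength} giving non-overlapping segments covering \code{[0, T]}.
#' @param times,values Dense time grid (h) and normalized strengths for
#'   \code{protocol_grid}; values are linearly interpolated and held constant
#'   beyond the last sample.
#'
#' @return An object of class \code{stimulus_protocol}: a list with
#'   \code{duration} (h) and \code{fun}, a vectorized function of time
#'   returning normalized strength (0 after the horizon).
#' @examples
#' p <- protocol_constant(1, duration = 3)
#' protocol_value(p, c(0, 1.5, 2.999, 3.5))
#' @export
protocol_constant <- function(strength = 1, duration = 3) {
  protocol_segments(data.frame(t0 = 0, t1 = duration, strength = strength))
}

#' @rdname protocol_constant
#' @export
protocol_segments <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("t0", "t1", "strength") %in% names(segments)))
  segments <- segments[order(segments$t0), , drop = FALSE]
  if (nrow(segments) == 0L) stop("protocol needs at least one segment", call. = FALSE)
  if (!all(is.finite(unlist(segments[c("t0", "t1", "strength")]))))
    stop("protocol segments must be finite", call. = FALSE)
  if (segments$t0[1] != 0)
    stop("protocol segments must start at t = 0", call. = FALSE)
  if (any(segments$t1 <= segments$t0))
    stop("each protocol segment needs t1 > t0", call. = FALSE)
  if (nrow(segments) > 1L &&
      any(abs(segments$t0[-1] - segments$t1[-nrow(segments)]) > 1e-12))
    stop("protocol segments must cover [0, T] without gaps or overlap",
         call. = FALSE)
  duration <- segments$t1[nrow(segments)]
  fun <- function(t) {
    idx <- findInterval(t, c(segments$t0, duration), rightmost.closed = TRUE)
    out <- numeric(length(t))
    inside <- t >= 0 & t <= duration & idx >= 1
    out[inside] <- segments$strength[pmin(idx[inside], nrow(segments))]
    out
  }
  structure(list(duration = duration, fun = fun, segments = segments,
                 kind = "segments"),
            class = "stimulus_protocol")
}

#' @rdname protocol_constant
#' @export
protocol_grid <- function(times, values, duration = max(times)) {
  stopifnot(length(times) == length(values), length(times) >= 2L)
  if (is.unsorted(times, strictly = TRUE))
    stop("protocol grid times must be strictly increasing", call. = FALSE)
  if (!all(is.finite(values))) stop("protocol strengths must be finite", call. = FALSE)
  f <- stats::approxfun(times, values, rule = 2)
  fun <- function(t) {
    out <- f(t)
    out[t > duration | t < 0] <- 0
    out
  }
  structure(list(duration = duration, fun = fun,
                 grid = list(times = times, values = values), kind = "grid"),
            class = "stimulus_protocol")
}

#' Evaluate a protocol
#'
#' @param protocol A \code{stimulus_protocol}.
#' @param t Times in hours.
#' @return Normalized field strength at \code{t} (0 outside \code{[0, T]}).
#' @export
protocol_value <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  protocol$fun(t)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("Stimulation protocol on [0, %.4g h] (%s)\n", x$duration, x$kind))
  if (x$kind == "segments") {
    for (i in seq_len(nrow(x$segments)))
      cat(sprintf("  [%.4g, %.4g] h: s = %.4g (%.4g V/cm)\n",
                  x$segments$t0[i], x$segments$t1[i], x$segments$strength[i],
                  field_to_physical(x$segments$strength[i])))
  } else {
    cat(sprintf("  %d grid points, strength range [%.4g, %.4g]\n",
                length(x$grid$times), min(x$grid$values), max(x$grid$values)))
  }
  invisible(x)
}

## internal: TRUE if protocol is a single constant-strength pulse starting at 0
.is_pulse <- function(protocol) {
  protocol$kind == "segments" && nrow(protocol$segments) == 1L
}
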