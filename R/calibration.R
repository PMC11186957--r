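#' Bulk-velocity trace
#'
#' A bulk-velocity time series as produced by spatially averaging particle
#' image velocimetry over the tissue centre: velocities at (nominally 10-min)
#' uniform spacing, a field switch-off time \code{t_end}, and a phase label
#' per sample (\code{"stimulation"} for \code{t <= t_end},
#' \code{"post"} after).
#'
#' @param time_h Sample times in hours, strictly increasing.
#' @param velocity_um_per_h Bulk velocities in \eqn{\mu}m/h.
#' @param t_end Field switch-off time in hours; must coincide with a sample
#'   time (within 1e-9 h) when any samples lie beyond it.
#' @return An object of classes \code{velocity_trace} and \code{data.frame}
#'   with columns \code{time_h}, \code{velocity_um_per_h}, \code{phase} and
#'   attribute \code{t_end}.
#' @export
velocity_trace <- function(time_h, velocity_um_per_h, t_end) {
  stopifnot(length(time_h) == length(velocity_um_per_h), length(time_h) >= 1L)
  if (is.unsorted(time_h, strictly = TRUE))
    stop("trace times must be strictly increasing", call. = FALSE)
  if (!all(is.finite(time_h)) || !all(is.finite(velocity_um_per_h)))
    stop("trace values must be finite", call. = FALSE)
  stopifnot(is.numeric(t_end), length(t_end) == 1L, t_end >= 0)
  if (any(time_h > t_end) && min(abs(time_h - t_end)) > 1e-9)
    stop("t_end must coincide with a sample time", call. = FALSE)
  structure(data.frame(time_h = time_h,
                       velocity_um_per_h = velocity_um_per_h,
                       phase = ifelse(time_h <= t_end + 1e-9,
                                      "stimulation", "post")),
            t_end = t_end,
            class = c("velocity_trace", "data.frame"))
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("Bulk-velocity trace: %d samples on [%.3g, %.3g] h, t_end = %.3g h\n",
              nrow(x), min(x$time_h), max(x$time_h), attr(x, "t_end")))
  NextMethod()
}

#' Estimate the friction rate from post-stimulation decay
#'
#' After the field is switched off the model predicts exponential decay of the
#' bulk velocity, \eqn{v(t) = C e^{-\gamma (t - t_{\rm end})}} with
#' \eqn{C = v(t_{\rm end})}. The amplitude is pinned to the observed velocity
#' at switch-off and the decay rate is found by one-dimensional least squares
#' over the post-stimulation window.
#'
#' @param trace A \code{\link{velocity_trace}} containing post-stimulation
#'   samples.
#' @param window Length of the post-stimulation fitting window in hours
#'   (default 2.5).
#' @return A list with \code{gamma} (1/h), \code{C} (\eqn{\mu}m/h),
#'   \code{residual} (residual norm) and \code{n} (points used).
#' @examples
#' tr <- generate_decay_trace(gamma = 1.765, v0 = 50, sigma = 0)
#' fit_gamma_decay(tr)$gamma # 1.765
#' @export
fit_gamma_decay <- function(trace, window = 2.5) {
  stopifnot(inherits(trace, "velocity_trace"))
  t_end <- attr(trace, "t_end")
  idx <- trace$time_h >= t_end - 1e-9 & trace$time_h <= t_end + window + 1e-9
  tt <- trace$time_h[idx] - t_end
  vv <- trace$velocity_um_per_h[idx]
  if (length(tt) < 3L)
    stop("need at least 3 post-stimulation samples in the window", call. = FALSE)
  C <- vv[which.min(abs(tt))]
  if (all(abs(vv) < 1e-12) || abs(C) < 1e-12)
    stop("degenerate fit: post-stimulation velocities are all (near) zero",
         call. = FALSE)
  sse <- function(g) sum((vv - C * exp(-g * tt))^2)
  opt <- optimize(sse, interval = c(1e-4, 100), tol = 1e-10)
  list(gamma = opt$minimum, C = C, residual = sqrt(opt$objective),
       n = length(tt))
}

#' Gaussian log-likelihood of a trace under the model
#'
#' Independent Gaussian observation errors around the (clamped) model velocity
#' evaluated at the sample times of the trace.
#'
#' @param params A \code{\link{model_params}} object (the friction rate
#'   \code{gamma} is part of it and held fixed during calibration).
#' @param sigma Observation noise standard deviation, \eqn{\mu}m/h
#'   (positive).
#' @param trace A \code{\link{velocity_trace}}.
#' @param protocol The \code{stimulus_protocol} under which the trace was
#'   recorded.
#' @return The scalar log-likelihood.
#' @export
log_likelihood_velocity <- function(params, sigma, trace, protocol) {
  stopifnot(inherits(trace, "velocity_trace"))
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  mu <- model_velocity(params, protocol, trace$time_h)
  sum(dnorm(trace$velocity_um_per_h, mean = mu, sd = sigma, log = TRUE))
}

#' Default priors for MCMC calibration
#'
#' Independent uniform priors, weakly informative and wide enough to cover
#' the posterior comfortably: \eqn{\alpha \in [0, 1000]} \eqn{\mu}m/h\eqn{^2},
#' \eqn{\tau_e \in [0.01, 2]} h, \eqn{\tau_a \in [0.1, 20]} h,
#' \eqn{\sigma \in [0.1, 50]} \eqn{\mu}m/h, with support restricted to
#' \eqn{\tau_e < \tau_a}.
#'
#' @return A matrix with rows \code{alpha}, \code{tau_e}, \code{tau_a},
#'   \code{sigma} and columns \code{lower}, \code{upper}.
#' @export
default_priors <- function() {
  m <- rbind(alpha = c(0, 1000),
             tau_e = c(0.01, 2),
             tau_a = c(0.1, 20),
             sigma = c(0.1, 50))
  colnames(m) <- c("lower", "upper")
  m
}

## log prior density (uniform box + tau_e < tau_a ordering); -Inf off support
.log_prior <- function(theta, priors) {
  if (any(theta < priors[, "lower"]) || any(theta > priors[, "upper"]))
    return(-Inf)
  if (theta[2] >= theta[3]) return(-Inf)
  0
}

#' Gelman-Rubin convergence statistic
#'
#' Classic potential scale reduction factor
#' \eqn{\hat R = \sqrt{((n-1)/n\, W + B/n) / W}} built from the between-chain
#' variance \eqn{B} and mean within-chain variance \eqn{W}. Values near 1
#' indicate mixing and stationarity; the conventional convergence threshold
#' used throughout the package is 1.05. A split variant (each chain halved
#' before the computation, more sensitive to trends) is available.
#'
#' @param chains A list of at least two equal-length numeric matrices
#'   (iterations x parameters) or vectors.
#' @param split Split each chain in half first (default FALSE).
#' @return A named vector of \eqn{\hat R} values, one per parameter.
#' @export
rhat <- function(chains, split = FALSE) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least two chains", call. = FALSE)
  chains <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1) else as.matrix(ch)
  })
  n <- unique(vapply(chains, nrow, 1L))
  if (length(n) != 1L) stop("chains must have equal lengths", call. = FALSE)
  if (split) {
    h <- floor(n / 2)
    chains <- c(lapply(chains, function(ch) ch[seq_len(h), , drop = FALSE]),
                lapply(chains, function(ch) ch[(n - h + 1):n, , drop = FALSE]))
    n <- h
  }
  d <- ncol(chains[[1]])
  out <- vapply(seq_len(d), function(j) {
    means <- vapply(chains, function(ch) mean(ch[, j]), 1)
    vars <- vapply(chains, function(ch) var(ch[, j]), 1)
    W <- mean(vars)
    B <- n * var(means)
    if (W <= 0) return(if (B <= 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 1)
  names(out) <- colnames(chains[[1]]) %||%
    paste0("par", seq_len(d))
  out
}

## crude multi-start maximum-likelihood initializer for the sampler
.ml_start <- function(logpost, priors, n_starts = 32L) {
  d <- nrow(priors)
  starts <- matrix(runif(n_starts * d, priors[, "lower"], priors[, "upper"]),
                   ncol = d, byrow = TRUE)
  ## enforce ordering tau_e < tau_a on the draws
  swap <- starts[, 2] >= starts[, 3]
  if (any(swap)) {
    tmp <- starts[swap, 2]
    starts[swap, 2] <- pmin(tmp, starts[swap, 3]) * 0.5
  }
  lps <- apply(starts, 1, logpost)
  best <- starts[order(lps, decreasing = TRUE)[seq_len(3L)], , drop = FALSE]
  refined <- lapply(seq_len(nrow(best)), function(i) {
    optim(best[i, ], function(th) -logpost(th), method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-10))
  })
  vals <- vapply(refined, `[[`, 1, "value")
  refined[[which.min(vals)]]$par
}

## one Haario-Bardenet adaptive-covariance random-walk chain
.am_chain <- function(logpost, start, n_iter, warmup = 200L,
                      target_accept = 0.234) {
  d <- length(start)
  th <- start
  lp <- logpost(th)
  if (!is.finite(lp)) stop("chain started off prior support", call. = FALSE)
  mu <- th
  Sig <- diag((pmax(abs(th), 1e-3) * 0.02)^2, d)
  eta <- 0
  out <- matrix(NA_real_, n_iter, d)
  accepted <- 0L
  scale <- 2.38^2 / d
  for (i in seq_len(n_iter)) {
    Sc <- scale * exp(eta) * Sig + 1e-12 * diag(d)
    prop <- as.vector(th + t(chol(Sc)) %*% rnorm(d))
    lpp <- logpost(prop)
    acc <- is.finite(lpp) && log(runif(1)) < lpp - lp
    if (acc) {
      th <- prop; lp <- lpp; accepted <- accepted + 1L
    }
    if (i > warmup) {
      gma <- (i - warmup)^-0.6
      dth <- th - mu
      mu <- mu + gma * dth
      Sig <- Sig + gma * (outer(dth, dth) - Sig)
      eta <- eta + gma * (as.numeric(acc) - target_accept)
    }
    out[i, ] <- th
  }
  attr(out, "acceptance") <- accepted / n_iter
  out
}

#' Calibrate the model by adaptive-covariance MCMC
#'
#' Samples the posterior of \eqn{(\alpha, \tau_e, \tau_a, \sigma)} under a
#' Gaussian observation model with the friction rate \eqn{\gamma} held fixed
#' (estimated beforehand from a post-stimulation decay, see
#' \code{\link{fit_gamma_decay}}). The sampler is an adaptive-covariance
#' random-walk Metropolis of the Haario-Bardenet flavour: the proposal
#' covariance tracks the running chain covariance, and a global log-scale is
#' adapted towards an acceptance rate of 0.234. Chains start from a
#' multi-start maximum-likelihood point with small multiplicative jitter; the
#' first half of every chain is discarded as burn-in before summaries.
#'
#' @param trace A \code{\link{velocity_trace}}.
#' @param protocol The protocol that generated the trace.
#' @param gamma Fixed friction rate in 1/h.
#' @param priors Prior bounds as returned by \code{\link{default_priors}}.
#' @param n_chains Number of chains (default 4).
#' @param max_iter Iterations per chain (default 2e4).
#' @param burn_in Fraction of each chain discarded (default 0.5).
#' @param seed Integer seed for reproducibility (chain j uses
#'   \code{seed + j}).
#' @param prior_only Sample the prior instead of the posterior (sampler
#'   sanity checks).
#' @return A \code{model_posterior} object: list with per-chain sample
#'   matrices (\code{chains}, post burn-in), \code{rhat}, \code{means},
#'   \code{quantiles} (5/25/50/75/95%), \code{converged}
#'   (all \eqn{\hat R \le 1.05}), \code{gamma}, and acceptance rates. If any
#'   \eqn{\hat R} exceeds 1.05 a warning flags non-convergence.
#' @export
run_mcmc <- function(trace, protocol, gamma, priors = default_priors(),
                     n_chains = 4L, max_iter = 2e4L, burn_in = 0.5,
                     seed = NULL, prior_only = FALSE) {
  stopifnot(inherits(trace, "velocity_trace"),
            inherits(protocol, "stimulus_protocol"),
            is.numeric(gamma), gamma > 0, n_chains >= 2L, max_iter >= 100L,
            burn_in > 0, burn_in < 1)
  par_names <- rownames(priors)
  loglik <- if (prior_only) {
    function(theta) 0
  } else {
    function(theta) {
      p <- tryCatch(model_params(gamma, theta[1], theta[2], theta[3]),
                    error = function(e) NULL)
      if (is.null(p)) return(-Inf)
      log_likelihood_velocity(p, theta[4], trace, protocol)
    }
  }
  logpost <- function(theta) {
    lp <- .log_prior(theta, priors)
    if (!is.finite(lp)) return(-Inf)
    lp + loglik(theta)
  }
  if (!is.null(seed)) set.seed(seed)
  start <- if (prior_only) {
    (priors[, "lower"] + priors[, "upper"]) / 2 * c(1, 0.5, 1, 1)
  } else {
    .ml_start(logpost, priors)
  }
  chains <- vector("list", n_chains)
  acc <- numeric(n_chains)
  for (j in seq_len(n_chains)) {
    if (!is.null(seed)) set.seed(seed + j)
    st <- start * exp(rnorm(length(start), 0, 0.05))
    st <- pmin(pmax(st, priors[, "lower"] + 1e-8), priors[, "upper"] - 1e-8)
    if (st[2] >= st[3]) st[2] <- st[3] / 2
    ch <- .am_chain(logpost, st, n_iter = max_iter)
    acc[j] <- attr(ch, "acceptance")
    colnames(ch) <- par_names
    chains[[j]] <- ch
  }
  keep <- (floor(max_iter * burn_in) + 1L):max_iter
  post <- lapply(chains, function(ch) ch[keep, , drop = FALSE])
  rh <- rhat(post)
  pooled <- do.call(rbind, post)
  qs <- apply(pooled, 2, quantile, probs = c(0.05, 0.25, 0.5, 0.75, 0.95))
  converged <- all(rh <= 1.05)
  if (!converged)
    warning("MCMC not converged: max Rhat = ", signif(max(rh), 4),
            " > 1.05 at max_iter = ", max_iter, call. = FALSE)
  structure(list(chains = post, rhat = rh, means = colMeans(pooled),
                 quantiles = qs, converged = converged, gamma = gamma,
                 acceptance = acc, n_iter = max_iter, burn_in = burn_in,
                 priors = priors),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat(sprintf("Posterior (%d chains x %d kept iterations, gamma fixed at %.4g 1/h)\n",
              length(x$chains), nrow(x$chains[[1]]), x$gamma))
  tab <- rbind(mean = x$means, x$quantiles, rhat = x$rhat)
  print(signif(tab, 4))
  cat(if (x$converged) "All Rhat <= 1.05: converged.\n"
      else "WARNING: not converged (some Rhat > 1.05).\n")
  invisible(x)
}

#' Posterior predictive velocity band
#'
#' Simulates the model at parameter draws from the posterior and returns the
#' pointwise 5% and 95% quantiles and mean of the predicted velocity, the
#' band used to assess predictive capability against data.
#'
#' @param posterior A \code{model_posterior} from \code{\link{run_mcmc}}.
#' @param protocol Stimulation protocol to predict under.
#' @param t_grid Output times in hours.
#' @param n_draws Number of posterior draws (default 200; must not exceed the
#'   number of retained samples).
#' @param seed Integer seed for the draw selection.
#' @param include_noise Add observation noise \eqn{\sigma} to the band
#'   (default FALSE: band reflects parameter uncertainty only).
#' @return Data frame with columns \code{time_h}, \code{mean}, \code{lower}
#'   (5%), \code{upper} (95%).
#' @export
posterior_predictive <- function(posterior, protocol, t_grid, n_draws = 200L,
                                 seed = NULL, include_noise = FALSE) {
  stopifnot(inherits(posterior, "model_posterior"),
            inherits(protocol, "stimulus_protocol"))
  pooled <- do.call(rbind, posterior$chains)
  if (n_draws > nrow(pooled))
    stop("n_draws exceeds the number of retained posterior samples",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(pooled), n_draws)
  sims <- vapply(idx, function(i) {
    th <- pooled[i, ]
    p <- model_params(posterior$gamma, th[1], th[2], th[3])
    v <- model_velocity(p, protocol, t_grid)
    if (include_noise) v <- v + rnorm(length(v), 0, th[4])
    v
  }, numeric(length(t_grid)))
  data.frame(time_h = t_grid,
             mean = rowMeans(sims),
             lower = apply(sims, 1, quantile, probs = 0.05),
             upper = apply(sims, 1, quantile, probs = 0.95))
}
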