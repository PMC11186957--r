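## Shared fixtures, built once per test run.

fx <- new.env()

fx_params <- function() calibrated_params()

## a cheap, deterministic posterior-like object for predictive-band tests
fake_posterior <- function(center = c(alpha = 149.92, tau_e = 0.26,
                                      tau_a = 2.038, sigma = 3),
                           spread = 0, n = 200L, gamma = 1.765,
                           seed = 99L) {
  set.seed(seed)
  chains <- lapply(1:2, function(j) {
    m <- sapply(seq_along(center), function(k) {
      center[k] * exp(rnorm(n, 0, spread))
    })
    colnames(m) <- names(center)
    m
  })
  structure(list(chains = chains,
                 rhat = setNames(rep(1, 4), names(center)),
                 means = center, quantiles = NULL, converged = TRUE,
                 gamma = gamma, acceptance = c(0.3, 0.3),
                 n_iter = n, burn_in = 0.5, priors = default_priors()),
            class = "model_posterior")
}

## memoised full calibration run on a synthetic pulse trace (used by the
## acceptance criterion on parameter recovery and by convergence checks)
fx_calibration <- function() {
  if (!is.null(fx$calibration)) return(fx$calibration)
  cfg <- synth_config(fx_params(), protocol_constant(1, 3),
                      sigma = 3, tail_h = 2.5, seed = 1L)
  trace <- generate_trace(cfg)
  post <- run_mcmc(trace, protocol_constant(1, 3), gamma = 1.765,
                   n_chains = 4L, max_iter = 2e4L, seed = 1L)
  fx$calibration <- list(trace = trace, posterior = post)
  fx$calibration
}
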