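test_that("decay fit recovers gamma exactly on noiseless data", {
  tr <- generate_decay_trace(gamma = 1.765, v0 = 50, sigma = 0)
  fit <- fit_gamma_decay(tr)
  expect_equal(fit$gamma, 1.765, tolerance = 1e-6)
  expect_equal(fit$C, 50)
  expect_lt(fit$residual, 1e-6)
})

test_that("decay fit is unbiased to first order under noise", {
  set.seed(31)
  est <- replicate(200, {
    tr <- generate_decay_trace(gamma = 1.765, v0 = 50, sigma = 2)
    fit_gamma_decay(tr)$gamma
  })
  expect_lt(abs(mean(est) / 1.765 - 1), 0.02)
  expect_lt(abs(mean(est) / 1.765 - 1), 0.05) # acceptance-level bound too
})

test_that("decay fit rejects degenerate inputs", {
  tr <- velocity_trace(seq(0, 2.5, by = 1 / 6), rep(0, 16), t_end = 0)
  expect_error(fit_gamma_decay(tr), "degenerate")
  short <- velocity_trace(c(0, 1 / 6), c(50, 40), t_end = 0)
  expect_error(fit_gamma_decay(short), "at least 3")
})

test_that("log-likelihood has Gaussian structure", {
  p <- fx_params()
  prot <- protocol_constant(1, 3)
  times <- seq(0, 3, by = 1 / 6)
  mu <- model_velocity(p, prot, times)
  tr <- velocity_trace(times, mu, t_end = 3)
  n <- length(times)
  ## zero residuals: doubling sigma lowers the log-likelihood by n log 2
  l1 <- log_likelihood_velocity(p, 2, tr, prot)
  l2 <- log_likelihood_velocity(p, 4, tr, prot)
  expect_equal(l1 - l2, n * log(2), tolerance = 1e-9)
  ## iid: permuting observations leaves the likelihood unchanged
  set.seed(5)
  noisy <- mu + rnorm(n, 0, 3)
  idx <- sample(n)
  tr_a <- velocity_trace(times, noisy, t_end = 3)
  ## same pairs in a different order: likelihood is a sum over pairs
  ll_terms <- dnorm(noisy, mu, 3, log = TRUE)
  expect_equal(log_likelihood_velocity(p, 3, tr_a, prot), sum(ll_terms[idx]))
})

test_that("likelihood is maximised at the generating parameters (grid oracle)", {
  p <- fx_params()
  prot <- protocol_constant(1, 3)
  times <- seq(0, 5.5, by = 1 / 6)
  tr <- velocity_trace(times, model_velocity(p, prot, times, tail_h = 2.5),
                       t_end = 3)
  ref <- log_likelihood_velocity(p, 1, tr, prot)
  for (f in c(0.8, 0.9, 1.1, 1.25)) {
    expect_lt(log_likelihood_velocity(
      model_params(p$gamma, p$alpha * f, p$tau_e, p$tau_a), 1, tr, prot), ref)
    expect_lt(log_likelihood_velocity(
      model_params(p$gamma, p$alpha, p$tau_e * f, p$tau_a), 1, tr, prot), ref)
    expect_lt(log_likelihood_velocity(
      model_params(p$gamma, p$alpha, p$tau_e, p$tau_a * f), 1, tr, prot), ref)
  }
})

test_that("rhat behaves at its limits", {
  set.seed(8)
  ch <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  ## identical chains: at the lower bound sqrt((n-1)/n) ~ 1
  r_id <- rhat(list(ch, ch, ch, ch))
  expect_equal(unname(r_id), c(1, 1), tolerance = 1e-3)
  expect_true(all(r_id <= 1))
  ## disjoint supports: far above the 1.05 threshold
  r_dis <- rhat(list(ch, ch + 50))
  expect_true(all(r_dis > 5))
  ## independent well-mixed chains on the same target stay below 1.05
  chains <- lapply(1:4, function(j) matrix(rnorm(4000), ncol = 2))
  expect_true(all(rhat(chains) <= 1.05))
  expect_error(rhat(list(ch)), "two chains")
  expect_error(rhat(list(ch, ch[1:10, ])), "equal lengths")
})

test_that("mcmc is deterministic under a fixed seed", {
  cfg <- synth_config(fx_params(), protocol_constant(1, 3), sigma = 3,
                      seed = 7L)
  tr <- generate_trace(cfg)
  prot <- protocol_constant(1, 3)
  ## runs this short may legitimately warn about convergence
  p1 <- suppressWarnings(
    run_mcmc(tr, prot, gamma = 1.765, n_chains = 2L, max_iter = 600L,
             seed = 3L))
  p2 <- suppressWarnings(
    run_mcmc(tr, prot, gamma = 1.765, n_chains = 2L, max_iter = 600L,
             seed = 3L))
  expect_identical(p1$chains, p2$chains)
  suppressWarnings({
    p3 <- run_mcmc(tr, prot, gamma = 1.765, n_chains = 2L, max_iter = 600L,
                   seed = 4L)
  })
  expect_false(identical(p1$chains, p3$chains))
})

test_that("prior-only sampling reproduces the prior", {
  tr <- generate_decay_trace(1.765, 50, sigma = 2, seed = 2L)
  prot <- protocol_constant(1, 3)
  post <- suppressWarnings(
    run_mcmc(tr, prot, gamma = 1.765, n_chains = 2L, max_iter = 6000L,
             seed = 12L, prior_only = TRUE))
  pooled <- do.call(rbind, post$chains)
  ## alpha is unconstrained by the ordering: uniform on [0, 1000]
  expect_equal(mean(pooled[, "alpha"]), 500, tolerance = 0.12)
  expect_equal(unname(quantile(pooled[, "alpha"], 0.5)), 500,
               tolerance = 0.15)
  ## ordering support respected
  expect_true(all(pooled[, "tau_e"] < pooled[, "tau_a"]))
  expect_true(all(pooled[, "sigma"] >= 0.1 & pooled[, "sigma"] <= 50))
})

test_that("posterior samples respect positivity and ordering", {
  cal <- fx_calibration()
  pooled <- do.call(rbind, cal$posterior$chains)
  expect_true(all(pooled > 0))
  expect_true(all(pooled[, "tau_e"] < pooled[, "tau_a"]))
})

test_that("posterior predictive band behaves", {
  prot <- protocol_constant(1, 3)
  tg <- seq(0, 3, by = 0.25)
  ## degenerate posterior: zero-width band equal to the model curve
  post0 <- fake_posterior(spread = 0)
  pp0 <- posterior_predictive(post0, prot, tg, n_draws = 50, seed = 1)
  expect_equal(pp0$lower, pp0$upper, tolerance = 1e-12)
  expect_equal(pp0$mean,
               model_velocity(model_params(1.765, 149.92, 0.26, 2.038),
                              prot, tg), tolerance = 1e-9)
  ## band contains the central trajectory at (almost) all time points
  post1 <- fake_posterior(spread = 0.05)
  pp1 <- posterior_predictive(post1, prot, tg, n_draws = 150, seed = 2)
  inside <- pp0$mean >= pp1$lower - 1e-9 & pp0$mean <= pp1$upper + 1e-9
  expect_gte(mean(inside), 0.9)
  ## inflating the posterior spread widens the band pointwise
  post2 <- fake_posterior(spread = 0.15)
  pp2 <- posterior_predictive(post2, prot, tg, n_draws = 150, seed = 2)
  w1 <- pp1$upper - pp1$lower
  w2 <- pp2$upper - pp2$lower
  expect_true(all(w2[-1] > w1[-1])) # t = 0 is pinned at rest
  expect_error(posterior_predictive(post1, prot, tg, n_draws = 1e6),
               "exceeds")
})
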