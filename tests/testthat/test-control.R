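test_that("closed-form adjoints solve the adjoint ODEs (backward oracle)", {
  p <- fx_params()
  T <- 3
  g <- p$gamma; al <- p$alpha; e1 <- 1 / p$tau_e; a1 <- 1 / p$tau_a
  sol <- solve_max_distance(p, T, 3)
  ## independent backward integration of the adjoint system from lambda(T)=0
  bw <- deSolve::lsoda(c(0, 0, 0), seq(0, T, length.out = 301),
                       function(tau, y, parms) {
                         t <- T - tau
                         list(-c(-1 + g * y[1],
                                 -al * y[1] + e1 * y[2],
                                 e1 * y[2] + a1 * y[3]))
                       }, rtol = 1e-11, atol = 1e-13)
  lam <- bw[rev(seq_len(nrow(bw))), 2:4]
  expect_lt(max(abs(sol$adjoints$lambda_v - lam[, 1])), 1e-6)
  expect_lt(max(abs(sol$adjoints$lambda_seff - lam[, 2])), 1e-6)
  expect_lt(max(abs(sol$adjoints$lambda_I - lam[, 3])), 1e-6)
})

test_that("adjoints satisfy the transversality conditions", {
  p <- fx_params()
  for (sol in list(solve_max_distance(p), solve_max_terminal_velocity(p),
                   bang_bang_policy(p, s_max = 1))) {
    last <- nrow(sol$adjoints)
    expect_lt(abs(sol$adjoints$lambda_v[last]), 1e-8)
    expect_lt(abs(sol$adjoints$lambda_seff[last]), 1e-8)
    expect_lt(abs(sol$adjoints$lambda_I[last]), 1e-8)
  }
  ## cruise problems: lambda_seff and lambda_I vanish at T (lambda_v pairs
  ## with the terminal velocity constraint in the constrained problem)
  solc <- solve_cruise_bvp(p, 3, v_star = 20)
  solw <- solve_cruise_window(p, 3, t1 = 0.8, v_star = 20)
  for (s in list(solc, solw)) {
    last <- nrow(s$adjoints)
    expect_lt(abs(s$adjoints$lambda_seff[last]), 1e-8)
    expect_lt(abs(s$adjoints$lambda_I[last]), 1e-8)
  }
  expect_lt(abs(solw$adjoints$lambda_v[nrow(solw$adjoints)]), 1e-8)
})

test_that("the distance adjoint lambda_v is positive before T and zero at T", {
  sol <- solve_max_distance(fx_params())
  lv <- sol$adjoints$lambda_v
  expect_true(all(lv[-length(lv)] > 0))
  expect_lt(abs(lv[length(lv)]), 1e-10)
})

test_that("isoperimetric solutions exhaust the charge budget to 1e-6", {
  p <- fx_params()
  for (budget in c(3, 1.5)) {
    for (sol in list(solve_max_distance(p, 3, budget),
                     solve_max_terminal_velocity(p, 3, budget))) {
      ## independent quadrature of the reported control
      sfun <- stats::splinefun(sol$times, sol$s_star)
      got <- integrate(function(t) sfun(t)^2, 0, 3, rel.tol = 1e-10,
                       subdivisions = 1000L)$value
      expect_lt(abs(got - budget) / budget, 1e-6)
      expect_lt(abs(sol$budget_used - budget) / budget, 1e-6)
      expect_true(sol$feasibility$budget_ok)
      expect_gt(sol$mu_star, 0)
    }
  }
  expect_error(solve_max_distance(p, 3, -1), "positive")
})

test_that("optimal distance beats the constant field with the same budget", {
  p <- fx_params()
  sol <- solve_max_distance(p, 3, 3)
  const <- simulate_model(p, protocol_constant(1, 3),
                          seq(0, 3, length.out = 2001))
  d_const <- distance_travelled(const)
  expect_gt(sol$objective, d_const)
  ## strict but modest improvement (a few percent at these parameters)
  expect_lt((sol$objective - d_const) / d_const, 0.2)
})

test_that("terminal-velocity control beats the constant field at T", {
  p <- fx_params()
  sol <- solve_max_terminal_velocity(p, 3, 3)
  const <- simulate_model(p, protocol_constant(1, 3))
  vT_const <- tail(const$velocity_um_per_h, 1)
  expect_gt(sol$objective, vT_const)
  ## the control cannot help at the very end: sensitivity of v(T) to the
  ## field vanishes at t = T, so s*(T) = 0
  expect_lt(abs(sol$s_star[length(sol$s_star)]), 1e-8)
})

test_that("projected finite-difference gradient vanishes at the optimum", {
  p <- fx_params()
  ## the bound reflects the O(h^2) gap between the continuum optimum and the
  ## 60-point discretisation; the terminal-velocity kernel has the larger
  ## curvature relative to its scale, hence the looser bound
  bounds <- c(max_distance = 1e-3, max_terminal_velocity = 1e-2)
  for (kind in names(bounds)) {
    sol <- if (kind == "max_distance") solve_max_distance(p)
           else solve_max_terminal_velocity(p)
    grid <- seq(0, 3, length.out = 60)
    s_grid <- sol$sfun(grid)
    orc <- gradient_oracle(list(kind = kind, horizon = 3, s_budget = 3),
                           p, s_grid)
    ratio <- sqrt(sum(orc$projected_gradient^2)) / sqrt(sum(orc$gradient^2))
    expect_lt(ratio, bounds[[kind]])
  }
})

test_that("gradient of a linear-in-control objective is control-independent", {
  p <- fx_params()
  set.seed(21)
  prob <- list(kind = "max_distance", horizon = 3, s_budget = 3)
  g1 <- gradient_oracle(prob, p, rep(1, 25))$gradient
  g2 <- gradient_oracle(prob, p, runif(25, 0, 2))$gradient
  expect_equal(g1, g2, tolerance = 1e-4)
})

test_that("cruise objective gradient vanishes on the target trajectory", {
  p <- fx_params()
  ## v == v_star == 0 is reached by s == 0: the zero control is a minimum
  orc <- gradient_oracle(list(kind = "cruise", horizon = 3, v_star = 0),
                         p, rep(0, 25))
  expect_lt(max(abs(orc$gradient)), 1e-6)
  expect_equal(orc$objective, 0, tolerance = 1e-12)
})

test_that("bump weight matches its closed form and symmetry", {
  expect_equal(bump(1.5, 0.75, 2.25, 0.02), 1, tolerance = 1e-10)
  expect_equal(bump(0.75, 0.75, 2.25, 0.02), 0.5, tolerance = 1e-10)
  for (d in c(0.1, 0.3, 0.7))
    expect_equal(bump(0.75 + d, 0.75, 2.25, 0.05),
                 bump(2.25 - d, 0.75, 2.25, 0.05), tolerance = 1e-12)
  expect_error(bump(1, 2, 1, 0.02))
})

test_that("bang-bang switching function is positive before T: pulse is optimal", {
  p <- fx_params()
  sol <- bang_bang_policy(p, 3, s_max = 1)
  psi <- sol$switching_function
  n <- length(psi)
  expect_true(all(psi[-n] > 0))
  expect_lt(abs(psi[n]), 1e-9)
  expect_equal(sol$s_star[-n], rep(1, n - 1))
  expect_length(sol$switching_times, 0)
})

test_that("bang-bang policy beats random feasible controls (search oracle)", {
  p <- fx_params()
  s_max <- 1
  sol <- bang_bang_policy(p, 3, s_max = s_max)
  tg <- seq(0, 3, length.out = 301)
  set.seed(17)
  for (i in 1:100) {
    brk <- sort(runif(3, 0, 3))
    lev <- runif(4, 0, s_max)
    prot <- protocol_segments(data.frame(t0 = c(0, brk), t1 = c(brk, 3),
                                         strength = lev))
    d <- distance_travelled(simulate_model(p, prot, tg, clamp = FALSE))
    expect_lte(d, sol$objective + 1e-6)
  }
})

test_that("cruise solver hits the target and degenerates gracefully", {
  p <- fx_params()
  sol0 <- solve_cruise_bvp(p, 3, v_star = 0)
  expect_equal(max(abs(sol0$s_star)), 0)
  expect_equal(max(abs(sol0$state$velocity_um_per_h)), 0)
  sol <- solve_cruise_bvp(p, 3, v_star = 20)
  expect_lt(sol$terminal_error, 1e-6)
  v <- sol$state$velocity_um_per_h
  ## plateau: within 2% of target over the second half of stimulation
  late <- sol$times >= 1.5
  expect_lt(max(abs(v[late] - 20)) / 20, 0.02)
})

test_that("field caps trade terminal accuracy for feasibility, monotonically", {
  p <- fx_params()
  v_star <- 20
  caps <- c(1, 1.5, 2, 2.5, 3)
  errs <- vapply(caps, function(sm) {
    solve_cruise_bvp(p, 3, v_star, s_max = sm)$terminal_error
  }, 1)
  expect_true(all(diff(errs) < 1e-9))
  ## as the cap is lifted the clipped solution converges to the unclipped one
  free <- solve_cruise_bvp(p, 3, v_star)
  capped <- solve_cruise_bvp(p, 3, v_star, s_max = 2 * max(free$s_star))
  expect_equal(capped$terminal_error, free$terminal_error, tolerance = 1e-9)
  expect_false(capped$feasibility$field_clipped)
  expect_true(solve_cruise_bvp(p, 3, v_star,
                               s_max = 1)$feasibility$field_clipped)
})

test_that("windowed cruise changes regime at tau_max", {
  p <- fx_params()
  tm <- tau_max(p$tau_e, p$tau_a) # ~0.614 h
  v_star <- 20
  early <- solve_cruise_window(p, 3, t1 = 0.3, v_star = v_star)
  late <- solve_cruise_window(p, 3, t1 = 0.9, v_star = v_star)
  ## waiting time shorter than the natural rise time: the field must be on
  ## at t = 0; longer waiting time: near-zero initial field
  expect_gt(early$s0 / max(early$s_star), 0.5)
  expect_gt(early$s0, 20 * late$s0)
  ## overshoot only in the fast-start regime
  expect_gt(early$overshoot, 1e-3 * v_star)
  expect_lt(late$overshoot, 1e-3 * v_star)
  ## both hold the plateau
  expect_lt(late$plateau_error / v_star, 0.05)
})

test_that("windowed cruise field scales linearly with the target velocity", {
  p <- fx_params()
  s1 <- solve_cruise_window(p, 3, t1 = 0.8, v_star = 10)
  s2 <- solve_cruise_window(p, 3, t1 = 0.8, v_star = 20)
  expect_equal(2 * max(s1$s_star), max(s2$s_star), tolerance = 1e-8)
  expect_equal(2 * s1$s_star, s2$s_star, tolerance = 1e-6)
})
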