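test_that("collocation points follow (2j - 1) / (2^k M)", {
  expect_equal(collocation_points(1, 6), (2 * (1:6) - 1) / 12)
  expect_equal(collocation_points(1, 2), c(1 / 4, 3 / 4))
  expect_equal(collocation_points(2, 3), (2 * (1:6) - 1) / 12)
  pts <- collocation_points(3, 4)
  expect_length(pts, 16)
  expect_true(all(diff(pts) > 0) && all(pts > 0 & pts < 1))
})

test_that("state evaluators return init + coefficients on integrated basis", {
  prob <- default_problem()
  S <- state_evaluator(rep(0, 6), 620, prob)
  expect_equal(S(c(0, 0.3, 1)), c(620, 620, 620))
  e1 <- state_evaluator(c(1, 0, 0, 0, 0, 0), 0, prob)
  expect_equal(e1(0.5), 0.5, tolerance = 1e-15)   # integral of psi_{1,0} = 1
  expect_identical(S(0), 620)
  expect_error(S(1.5), "0, 1")
})

test_that("the disease-free equilibrium solves the system exactly", {
  prob <- collocation_problem(sir_parameters(I0 = 0, gamma = 0.6))
  expect_equal(assemble_residual(rep(0, 18), prob), rep(0, 18))
  res <- newton_solve(prob)
  expect_equal(res$solution$A, rep(0, 6))
  expect_equal(res$solution$B, rep(0, 6))
  expect_equal(res$solution$C, rep(0, 6))
  expect_lte(res$report$iterations, 2)
})

test_that("summed residual blocks reduce to (A + B + C) . Q", {
  set.seed(19)
  prob <- default_problem(gamma = 0.8)
  u <- rnorm(18)
  r <- assemble_residual(u, prob)
  summed <- r[1:6] + r[7:12] + r[13:18]
  ABC <- u[1:6] + u[7:12] + u[13:18]
  expect_equal(summed, drop(prob$Q %*% ABC), tolerance = 1e-12)
})

test_that("the analytic Jacobian matches central finite differences", {
  set.seed(5)
  prob <- default_problem(gamma = 0.7)
  u <- rnorm(18, sd = 0.5)
  J <- residual_jacobian(u, prob)
  h <- 1e-6
  Jfd <- matrix(0, 18, 18)
  for (j in 1:18) {
    up <- u; um <- u
    up[j] <- up[j] + h; um[j] <- um[j] - h
    Jfd[, j] <- (assemble_residual(up, prob) - assemble_residual(um, prob)) / (2 * h)
  }
  scale <- max(abs(J))
  expect_lt(max(abs(J - Jfd)) / scale, 1e-6)
  # linear-in-C block is exactly the Q matrix; A-block of r3 is zero
  expect_equal(J[13:18, 13:18], prob$Q)
  expect_equal(J[13:18, 1:6], matrix(0, 6, 6))
})

test_that("at gamma = 1 the Q matrix is the basis evaluation matrix", {
  prob <- default_problem(gamma = 1)
  psi <- t(evaluate_basis(prob$basis, prob$points))
  expect_equal(prob$Q, psi, tolerance = 1e-12)
})

test_that("the gamma = 1 solve reproduces the benchmark trajectory", {
  fit <- solve_sir(sir_parameters(gamma = 1))
  expect_true(fit$report$converged)
  expect_lt(fit$report$iterations, 10)
  expect_equal(fit$solution$S(1), 611.8969507254561, tolerance = 1e-5)
  expect_equal(fit$solution$I(1), 17.148094608528900, tolerance = 1e-5)
  expect_equal(fit$solution$R(1), 70.95495466601488, tolerance = 1e-5)
  # initial conditions honoured exactly
  expect_equal(c(fit$solution$S(0), fit$solution$I(0), fit$solution$R(0)),
               c(620, 10, 70), tolerance = 1e-10)
  # initial-condition vectors encode the constants on the order-0 slots
  expect_equal(fit$solution$D, c(620, 0, 0, 0, 0, 0))
  expect_equal(fit$solution$E, c(10, 0, 0, 0, 0, 0))
})

test_that("the published coefficient vectors nearly solve the system", {
  # the 6-decimal published vectors are not a converged root (their residual
  # is ~1.2e-4 and they deviate from the converged coefficients by ~2e-4),
  # but they satisfy the conservation identity to printing precision
  prob <- default_problem(gamma = 1)
  pub <- published_coefficients()
  u <- c(pub$A, pub$B, pub$C)
  expect_lt(max(abs(assemble_residual(u, prob))), 2e-4)
  expect_lte(max(abs(pub$A + pub$B + pub$C)), 2e-6)
  fit <- solve_sir(sir_parameters(gamma = 1))
  expect_lt(max(abs(c(fit$solution$A - pub$A, fit$solution$B - pub$B,
                      fit$solution$C - pub$C))), 5e-4)
})

test_that("converged solutions conserve the total population", {
  grid <- seq(0, 1, 0.1)
  for (g in c(0.3, 0.7, 1)) {
    fit <- solve_sir(sir_parameters(gamma = g))
    expect_lt(max(abs(fit$solution$A + fit$solution$B + fit$solution$C)),
              10 * 1e-12)
    tr <- sir_trajectory(fit, grid)
    expect_lt(max(abs(tr$S + tr$I + tr$R - 700)), 1e-10)
  }
})

test_that("gamma = 1 trajectories are monotone and positive", {
  tr <- sir_trajectory(solve_sir(sir_parameters(gamma = 1)))
  expect_true(all(diff(tr$S) < 0))
  expect_true(all(diff(tr$I) > 0))
  expect_true(all(diff(tr$R) > 0))
  expect_true(all(as.matrix(tr[, 2:4]) >= 0))
})

test_that("the solution is converged in M and continuous in gamma", {
  t6 <- sir_trajectory(solve_sir(sir_parameters(gamma = 1), M = 6))
  t8 <- sir_trajectory(solve_sir(sir_parameters(gamma = 1), M = 8))
  expect_lt(max(abs(as.matrix(t8[, 2:4]) - as.matrix(t6[, 2:4])) /
                  as.matrix(t6[, 2:4])), 1e-6)
  t99 <- sir_trajectory(solve_sir(sir_parameters(gamma = 0.99)))
  expect_lt(max(abs(as.matrix(t99[, 2:4]) - as.matrix(t6[, 2:4])) /
                  as.matrix(t6[, 2:4])), 0.02)
})

test_that("Newton failures carry an iteration report", {
  prob <- default_problem(gamma = 1)
  err <- tryCatch(newton_solve(prob, maxiter = 1), error = identity)
  expect_s3_class(err, "gwcm_newton_failure")
  expect_false(err$report$converged)
  expect_equal(err$report$iterations, 1)
  expect_length(err$report$residual_history, 2)
  expect_error(newton_solve(prob, tol = -1))
})
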