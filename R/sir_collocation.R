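#' Parameters of the fractional-order SIR model
#'
#' The model, under the Caputo derivative of order \eqn{\gamma \in (0, 1]},
#' is
#' \deqn{D^\gamma S = -p_1 S I + p_3 I, \quad
#'       D^\gamma I = p_1 S I - p_3 I - p_2 I, \quad
#'       D^\gamma R = p_2 I,}
#' with infection rate `p1` (per individual per unit time), removal rate
#' `p2` (per unit time), recovery-to-susceptible return rate `p3` (per unit
#' time), and initial compartment sizes `S0`, `I0`, `R0` (individuals).
#' Defaults describe a short-term influenza outbreak in a closed population
#' of 700.
#'
#' @param p1,p2,p3 nonnegative rates.
#' @param S0,I0,R0 nonnegative initial compartment sizes.
#' @param gamma fractional order in `(0, 1]`; 1 recovers the classical model.
#' @return an object of class `sir_parameters`.
#' @export
sir_parameters <- function(p1 = 0.001, p2 = 0.072, p3 = 0.005,
                           S0 = 620, I0 = 10, R0 = 70, gamma = 1) {
  if (any(c(p1, p2, p3) < 0)) stop("rates must be nonnegative")
  if (any(c(S0, I0, R0) < 0)) stop("initial sizes must be nonnegative")
  if (length(gamma) != 1 || gamma <= 0 || gamma > 1) {
    stop("'gamma' must lie in (0, 1]")
  }
  structure(list(p1 = p1, p2 = p2, p3 = p3, S0 = S0, I0 = I0, R0 = R0,
                 gamma = gamma), class = "sir_parameters")
}

#' @export
print.sir_parameters <- function(x, ...) {
  cat(sprintf("SIR parameters: p1 = %g, p2 = %g, p3 = %g; S0 = %g, I0 = %g, R0 = %g; gamma = %g\n",
              x$p1, x$p2, x$p3, x$S0, x$I0, x$R0, x$gamma))
  invisible(x)
}

#' Collocation points of the Genocchi wavelet method
#'
#' \eqn{\tau_j = (2j - 1) / (2^k M)} for \eqn{j = 1, \dots, 2^{k-1} M}:
#' the midpoints of \eqn{N} equal sub-intervals of \[0, 1\].
#'
#' @param k resolution level.
#' @param M polynomials per block.
#' @return strictly increasing numeric vector of length \eqn{N = 2^{k-1} M}.
#' @export
collocation_points <- function(k, M) {
  N <- 2^(k - 1) * M
  (2 * seq_len(N) - 1) / (2^k * M)
}

#' Assemble a collocation problem for the fractional SIR model
#'
#' Precomputes the wavelet basis, its operational matrix of integration, the
#' exact basis antiderivatives, the collocation points, and the matrices
#' `W[j, i]` \eqn{= \int_0^{\tau_j}\psi_i} and
#' `Q[j, i]` \eqn{= D^\gamma[\int_0^\cdot \psi_i](\tau_j)} used by the
#' residual and Jacobian.
#'
#' @param params a [sir_parameters()].
#' @param k,M wavelet resolution and order (defaults `k = 1`, `M = 6`).
#' @return an object of class `sir_collocation_problem`.
#' @export
collocation_problem <- function(params, k = 1, M = 6) {
  stopifnot(inherits(params, "sir_parameters"))
  basis <- genocchi_basis(k, M)
  antider <- basis_antiderivative(basis)
  pts <- collocation_points(k, M)
  Qfun <- caputo_basis_image(basis, params$gamma, antider)
  W <- t(vapply(pts, function(t) .antider_eval(antider, t), numeric(basis$N)))
  Q <- t(vapply(pts, Qfun, numeric(basis$N)))
  structure(list(params = params, basis = basis,
                 opmatrix = integration_matrix(basis),
                 antider = antider, points = pts, W = W, Q = Q),
            class = "sir_collocation_problem")
}

#' Evaluator of one state variable from its coefficient vector
#'
#' Implements \eqn{S(\tau) = S_0 + A^\top (P\psi(\tau) + \bar\psi(\tau))}:
#' the initial value plus the expansion coefficients applied to the
#' integrated basis. At `tau = 0` the initial value is returned exactly.
#'
#' @param coeffs numeric vector of length `N`.
#' @param init initial value of the state.
#' @param problem a [collocation_problem()] (or a [basis_antiderivative()]).
#' @return a vectorized function of `tau` on \[0, 1\].
#' @export
state_evaluator <- function(coeffs, init, problem) {
  antider <- if (inherits(problem, "basis_antiderivative")) problem else problem$antider
  stopifnot(length(coeffs) == antider$basis$N)
  function(tau) {
    if (any(tau < 0 | tau > 1)) stop("'tau' must lie in [0, 1]")
    vapply(tau, function(t) init + sum(coeffs * .antider_eval(antider, t)), 0)
  }
}

#' Collocation residual of the fractional SIR system
#'
#' For the stacked unknowns `u = c(A, B, C)` (expansion coefficients of the
#' \eqn{\gamma}-derivatives of S, I, R), returns the residual of the three
#' model equations at every collocation point:
#' \deqn{r_{1j} = A Q_j + p_1 S_j I_j - p_3 I_j,\quad
#'       r_{2j} = B Q_j - p_1 S_j I_j + (p_3 + p_2) I_j,\quad
#'       r_{3j} = C Q_j - p_2 I_j.}
#' Summing the three blocks cancels all model terms, leaving
#' \eqn{(A + B + C) Q_j}; this drives the discrete conservation of
#' \eqn{S + I + R}.
#'
#' @param u numeric vector of length `3N`.
#' @param problem a [collocation_problem()].
#' @return numeric vector of length `3N`.
#' @export
assemble_residual <- function(u, problem) {
  N <- problem$basis$N
  stopifnot(length(u) == 3 * N)
  p <- problem$params
  A <- u[1:N]; B <- u[N + 1:N]; C <- u[2 * N + 1:N]
  S <- p$S0 + problem$W %*% A
  I <- p$I0 + problem$W %*% B
  QA <- problem$Q %*% A; QB <- problem$Q %*% B; QC <- problem$Q %*% C
  c(QA + p$p1 * S * I - p$p3 * I,
    QB - p$p1 * S * I + (p$p3 + p$p2) * I,
    QC - p$p2 * I)
}

#' Analytic Jacobian of the collocation residual
#'
#' Exact derivative of [assemble_residual()] with respect to the stacked
#' unknowns; the only nonlinearity is the bilinear \eqn{S I} term, whose
#' derivative contributes \eqn{p_1 I_j w(\tau_j)} and
#' \eqn{p_1 S_j w(\tau_j)} blocks with \eqn{w = P\psi + \bar\psi}.
#'
#' @param u numeric vector of length `3N`.
#' @param problem a [collocation_problem()].
#' @return a `3N x 3N` matrix.
#' @export
residual_jacobian <- function(u, problem) {
  N <- problem$basis$N
  stopifnot(length(u) == 3 * N)
  p <- problem$params
  A <- u[1:N]; B <- u[N + 1:N]
  S <- drop(p$S0 + problem$W %*% A)
  I <- drop(p$I0 + problem$W %*% B)
  W <- problem$W; Q <- problem$Q
  J <- matrix(0, 3 * N, 3 * N)
  J[1:N, 1:N] <- Q + p$p1 * I * W
  J[1:N, N + 1:N] <- p$p1 * S * W - p$p3 * W
  J[N + 1:N, 1:N] <- -p$p1 * I * W
  J[N + 1:N, N + 1:N] <- Q - p$p1 * S * W + (p$p3 + p$p2) * W
  J[2 * N + 1:N, N + 1:N] <- -p$p2 * W
  J[2 * N + 1:N, 2 * N + 1:N] <- Q
  J
}

#' Newton-Raphson solve of the collocation system
#'
#' Undamped Newton iteration from `guess` (default: the zero vector) until
#' the residual infinity-norm drops below `tol`. Failures (non-convergence,
#' singular Jacobian) raise a condition of class `gwcm_newton_failure`
#' carrying the iteration report.
#'
#' @param problem a [collocation_problem()].
#' @param guess numeric start vector of length `3N`; default zero.
#' @param tol residual infinity-norm tolerance (`> 0`).
#' @param maxiter maximum number of Newton steps.
#' @return a list with `solution` (class `sir_gwcm_solution`: coefficient
#'   vectors `A`, `B`, `C`, initial-condition vectors `D`, `E`, `F`, and
#'   state evaluators `S`, `I`, `R`) and `report` (class `newton_report`:
#'   `iterations`, `residual_history`, `converged`).
#' @export
newton_solve <- function(problem, guess = NULL, tol = 1e-12, maxiter = 50) {
  stopifnot(inherits(problem, "sir_collocation_problem"), tol > 0)
  N <- problem$basis$N
  u <- if (is.null(guess)) rep(0, 3 * N) else guess
  stopifnot(length(u) == 3 * N)
  history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    r <- assemble_residual(u, problem)
    rn <- max(abs(r))
    history <- c(history, rn)
    if (rn <= tol) { converged <- TRUE; break }
    if (iter >= maxiter) break
    J <- residual_jacobian(u, problem)
    step <- tryCatch(solve(J, r), error = function(e) e)
    if (inherits(step, "error")) {
      report <- structure(list(iterations = iter, residual_history = history,
                               converged = FALSE), class = "newton_report")
      stop(errorCondition(paste("singular Jacobian in Newton iteration:",
                                conditionMessage(step)),
                          report = report, class = "gwcm_newton_failure"))
    }
    u <- u - step
    iter <- iter + 1L
  }
  report <- structure(list(iterations = iter, residual_history = history,
                           converged = converged), class = "newton_report")
  if (!converged) {
    stop(errorCondition(sprintf(
      "Newton iteration did not converge in %d steps (residual %.3e)",
      maxiter, history[length(history)]),
      report = report, class = "gwcm_newton_failure"))
  }
  p <- problem$params
  A <- u[1:N]; B <- u[N + 1:N]; C <- u[2 * N + 1:N]
  # initial-condition vectors: the constant function on the order-0 slot of
  # each block (psi_{n,0} = 2^((k-1)/2) there), so D.psi == S0 identically
  nb <- 2^(problem$basis$k - 1)
  unitv <- numeric(N)
  unitv[(seq_len(nb) - 1) * problem$basis$M + 1] <- 1 / sqrt(nb)
  solution <- structure(list(
    A = A, B = B, C = C,
    D = p$S0 * unitv, E = p$I0 * unitv, F = p$R0 * unitv,
    S = state_evaluator(A, p$S0, problem),
    I = state_evaluator(B, p$I0, problem),
    R = state_evaluator(C, p$R0, problem),
    params = p, k = problem$basis$k, M = problem$basis$M),
    class = "sir_gwcm_solution")
  list(solution = solution, report = report)
}

#' @export
print.newton_report <- function(x, ...) {
  cat(sprintf("Newton-Raphson: %d iteration%s, %s, final residual %.3e\n",
              x$iterations, if (x$iterations == 1) "" else "s",
              if (x$converged) "converged" else "NOT converged",
              x$residual_history[length(x$residual_history)]))
  invisible(x)
}

#' Solve the fractional SIR model by Genocchi wavelet collocation
#'
#' End-to-end driver: builds the wavelet basis and operational matrix,
#' collocates the Caputo-fractional SIR system at the wavelet points, and
#' solves the resulting nonlinear algebraic system by Newton-Raphson.
#'
#' @param params a [sir_parameters()].
#' @param k,M wavelet resolution level and order (defaults 1 and 6).
#' @param tol,maxiter,guess Newton options, see [newton_solve()].
#' @return an object of class `sir_gwcm_fit`: the `solution`
#'   (coefficient vectors and state evaluators), the Newton `report`, and
#'   the underlying `problem`.
#' @examples
#' fit <- solve_sir(sir_parameters(gamma = 1))
#' sir_trajectory(fit, seq(0, 1, 0.5))
#' @export
solve_sir <- function(params = sir_parameters(), k = 1, M = 6,
                      tol = 1e-12, maxiter = 50, guess = NULL) {
  problem <- collocation_problem(params, k, M)
  res <- newton_solve(problem, guess = guess, tol = tol, maxiter = maxiter)
  structure(list(solution = res$solution, report = res$report,
                 problem = problem), class = "sir_gwcm_fit")
}

#' @export
print.sir_gwcm_fit <- function(x, ...) {
  cat("Genocchi wavelet collocation fit of the fractional SIR model\n")
  print(x$problem$params)
  cat(sprintf("k = %d, M = %d (N = %d)\n", x$problem$basis$k,
              x$problem$basis$M, x$problem$basis$N))
  print(x$report)
  cat("A:", format(x$solution$A, digits = 7), "\n")
  cat("B:", format(x$solution$B, digits = 7), "\n")
  cat("C:", format(x$solution$C, digits = 7), "\n")
  invisible(x)
}

#' Evaluate a solved SIR trajectory on a time grid
#'
#' @param fit a [solve_sir()] result.
#' @param tau numeric grid in \[0, 1\] (default the 0.1-spaced grid).
#' @return a data frame with columns `tau`, `S`, `I`, `R`.
#' @export
sir_trajectory <- function(fit, tau = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(fit, "sir_gwcm_fit"))
  data.frame(tau = tau, S = fit$solution$S(tau), I = fit$solution$I(tau),
             R = fit$solution$R(tau))
}
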