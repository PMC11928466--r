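#' Power functions: finite sums of c * tau^e
#'
#' Container for functions of the form \eqn{\sum_i c_i \tau^{e_i}} with real
#' exponents \eqn{e_i \ge 0}. The class is closed under Caputo fractional
#' differentiation and Riemann-Liouville fractional integration, which act
#' termwise through the power rule.
#'
#' @param coef numeric coefficients.
#' @param expo numeric exponents, all `>= 0`.
#' @return an object of class `powerfun`.
#' @examples
#' f <- power_function(c(1, 2), c(0, 1))  # 1 + 2*tau
#' caputo_derivative(f, 0.5)
#' @export
power_function <- function(coef, expo) {
  stopifnot(length(coef) == length(expo))
  if (any(expo < 0)) stop("exponents must be nonnegative")
  # canonicalize: merge duplicate exponents, drop zero terms
  if (length(coef)) {
    u <- sort(unique(expo))
    coef <- vapply(u, function(e) sum(coef[expo == e]), 0)
    keep <- coef != 0
    coef <- coef[keep]; expo <- u[keep]
  }
  structure(list(coef = coef, expo = expo), class = "powerfun")
}

#' @export
print.powerfun <- function(x, ...) {
  if (!length(x$coef)) {
    cat("0\n")
  } else {
    cat(paste(sprintf("%g*tau^%g", x$coef, x$expo), collapse = " + "), "\n")
  }
  invisible(x)
}

#' Evaluate a power function
#'
#' At `tau = 0` a term with positive exponent contributes 0 and an
#' exponent-zero term contributes its coefficient.
#'
#' @param f a [power_function()].
#' @param tau numeric vector of nonnegative points.
#' @return numeric vector.
#' @export
evaluate_power <- function(f, tau) {
  stopifnot(inherits(f, "powerfun"), all(tau >= 0))
  vapply(tau, function(t) {
    if (t == 0) return(sum(f$coef[f$expo == 0]))
    sum(f$coef * t^f$expo)
  }, 0)
}

#' Caputo fractional derivative of a power function
#'
#' Termwise power rule for order \eqn{\gamma \in (0, 1]}: constants map to 0
#' and \eqn{c\,\tau^e \mapsto c\,\Gamma(e+1)/\Gamma(e+1-\gamma)\,
#' \tau^{e-\gamma}} for \eqn{e > 0}. At \eqn{\gamma = 1} this is exactly the
#' ordinary derivative.
#'
#' @param f a [power_function()].
#' @param gamma fractional order in `(0, 1]`.
#' @return a `powerfun`.
#' @export
caputo_derivative <- function(f, gamma) {
  stopifnot(inherits(f, "powerfun"))
  if (length(gamma) != 1 || gamma <= 0 || gamma > 1) {
    stop("'gamma' must lie in (0, 1]")
  }
  keep <- f$expo > 0
  coef <- f$coef[keep]; expo <- f$expo[keep]
  if (gamma == 1) {
    power_function(coef * expo, expo - 1)
  } else {
    power_function(coef * gamma(expo + 1) / gamma(expo + 1 - gamma),
                   expo - gamma)
  }
}

#' Riemann-Liouville fractional integral of a power function
#'
#' Termwise power rule for order \eqn{\gamma > 0}:
#' \eqn{c\,\tau^e \mapsto c\,\Gamma(e+1)/\Gamma(e+1+\gamma)\,
#' \tau^{e+\gamma}}. For integer \eqn{\gamma} this is the repeated ordinary
#' antiderivative.
#'
#' @param f a [power_function()].
#' @param gamma order, `> 0`.
#' @return a `powerfun`.
#' @export
rl_integral <- function(f, gamma) {
  stopifnot(inherits(f, "powerfun"))
  if (length(gamma) != 1 || gamma <= 0) stop("'gamma' must be positive")
  power_function(f$coef * gamma(f$expo + 1) / gamma(f$expo + 1 + gamma),
                 f$expo + gamma)
}

#' Exact antiderivatives of a wavelet basis as global polynomials
#'
#' For each basis function, the running integral \eqn{w_i(\tau) =
#' \int_0^\tau \psi_i} is zero before the function's block, a polynomial in
#' the global variable \eqn{\tau} on the block, and a constant after it.
#' The block polynomial is computed exactly and equals, by construction, the
#' operational-matrix representation \eqn{(P\psi + \bar\psi)_i}.
#'
#' @param basis a [genocchi_basis()].
#' @return an object of class `basis_antiderivative`: per function, the
#'   support, the numeric coefficients (ascending degree in \eqn{\tau}) of
#'   the block polynomial, and the constant tail value.
#' @export
basis_antiderivative <- function(basis) {
  stopifnot(inherits(basis, "genocchi_basis"))
  nb <- 2^(basis$k - 1)
  items <- lapply(basis$functions, function(f) {
    aloc <- .local_antiderivative(f$m)
    # compose with the block map x = 2^(k-1) tau - (n - 1), still exact
    aglob <- gp_compose_affine(aloc, nb, 1, -(f$n - 1), 1)
    mult <- f$scale / nb
    list(support = f$support,
         coef = mult * aglob$num / aglob$den,
         tail = mult * rat_num(gp_eval_rat(aloc, 1)))
  })
  structure(list(basis = basis, items = items), class = "basis_antiderivative")
}

# w(tau): N-vector of running integrals of the basis
.antider_eval <- function(antider, tau) {
  basis <- antider$basis
  out <- numeric(basis$N)
  for (i in seq_len(basis$N)) {
    it <- antider$items[[i]]
    if (tau < it$support[1]) next
    if (tau >= it$support[2] && !(tau == 1 && it$support[2] == 1)) {
      out[i] <- it$tail
    } else {
      out[i] <- sum(it$coef * tau^(seq_along(it$coef) - 1))
    }
  }
  out
}

#' Caputo derivative of the integrated wavelet representation
#'
#' Returns an evaluator \eqn{Q(\tau)} with
#' \eqn{Q_i(\tau) = D^\gamma[(P\psi + \bar\psi)_i](\tau)}, obtained by
#' applying the Caputo power rule termwise to the exact block polynomials of
#' the basis antiderivatives. At \eqn{\gamma = 1}, \eqn{Q(\tau) = \psi(\tau)}
#' at every interior point of a block.
#'
#' @param basis a [genocchi_basis()].
#' @param gamma fractional order in `(0, 1]`.
#' @param antider optionally a precomputed [basis_antiderivative()].
#' @return a function mapping a scalar `tau` in \[0, 1\] to a numeric vector
#'   of length `N`.
#' @export
caputo_basis_image <- function(basis, gamma, antider = NULL) {
  stopifnot(inherits(basis, "genocchi_basis"))
  if (length(gamma) != 1 || gamma <= 0 || gamma > 1) {
    stop("'gamma' must lie in (0, 1]")
  }
  if (is.null(antider)) antider <- basis_antiderivative(basis)
  # precompute the Caputo image of each block polynomial
  images <- lapply(antider$items, function(it) {
    f <- power_function(it$coef, seq_along(it$coef) - 1)
    caputo_derivative(f, gamma)
  })
  function(tau) {
    if (length(tau) != 1 || tau < 0 || tau > 1) {
      stop("'tau' must be a single value in [0, 1]")
    }
    out <- numeric(basis$N)
    for (i in seq_len(basis$N)) {
      it <- antider$items[[i]]
      inblock <- tau >= it$support[1] &&
        (tau < it$support[2] || (tau == 1 && it$support[2] == 1))
      if (inblock) out[i] <- evaluate_power(images[[i]], tau)
    }
    out
  }
}
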