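.genocchi_cache <- new.env(parent = emptyenv())

#' Genocchi polynomials
#'
#' Computes the Genocchi polynomial \eqn{G_m(x)} with exact rational (in fact
#' integer) coefficients, via the Appell-type recurrence
#' \deqn{2 G_n(x) = 2n x^{n-1} - \sum_{j=0}^{n-1} \binom{n}{j} G_j(x),}
#' with \eqn{G_0 = 0}. These are the polynomials generated by
#' \eqn{2t e^{xt}/(e^t + 1)}; the first few are \eqn{G_1 = 1},
#' \eqn{G_2 = 2x - 1}, \eqn{G_3 = 3x^2 - 3x}, \eqn{G_4 = 4x^3 - 6x^2 + 1}.
#'
#' @param m integer order, `m >= 0`.
#' @return a [gpoly()] holding \eqn{G_m}.
#' @seealso [genocchi_number()], [normalization_constant()]
#' @export
genocchi_polynomial <- function(m) {
  if (length(m) != 1 || is.na(m) || m < 0 || m != round(m)) {
    stop("'m' must be a single nonnegative integer")
  }
  m <- as.integer(m)
  key <- as.character(m)
  if (!is.null(.genocchi_cache[[key]])) return(.genocchi_cache[[key]])
  if (m == 0) {
    g <- gp_zero()
  } else {
    # 2 G_m = 2m x^(m-1) - sum_{j<m} C(m,j) G_j
    acc <- gpoly(c(rep(0, m - 1), 2 * m))
    for (j in 0:(m - 1)) {
      acc <- gp_sub(acc, poly_scale(genocchi_polynomial(j), choose(m, j)))
    }
    g <- poly_scale(acc, 1, 2)
  }
  .genocchi_cache[[key]] <- g
  g
}

#' Genocchi numbers
#'
#' The Genocchi number \eqn{g_m = G_m(0)}, the constant term of the
#' Genocchi polynomial. These are integers: 0, 1, -1, 0, 1, 0, -3, 0, 17, ...
#'
#' @param m integer order, `m >= 0`.
#' @return numeric (integer-valued, exact).
#' @export
genocchi_number <- function(m) {
  g <- genocchi_polynomial(m)
  g$num[1] / g$den[1]
}

#' Normalization constant of a Genocchi polynomial on \[0, 1\]
#'
#' Returns \eqn{1 / \lVert G_m \rVert_{L^2[0,1]}}, where the squared norm
#' \eqn{\int_0^1 G_m(x)^2\,dx} is computed by exact polynomial integration.
#' For example the constant is \eqn{\sqrt 3} for \eqn{G_2} and
#' \eqn{\sqrt{35/17}} for \eqn{G_4}. The exact square of the constant is
#' attached as attribute `exact_sq` (numerator, denominator).
#'
#' @param m integer order, `m >= 1` (\eqn{G_0 \equiv 0} has no normalization).
#' @return numeric scalar with attribute `exact_sq = c(num, den)` such that
#'   the returned value equals `sqrt(num/den)` exactly.
#' @export
normalization_constant <- function(m) {
  if (length(m) != 1 || is.na(m) || m < 1 || m != round(m)) {
    stop("'m' must be a single integer >= 1")
  }
  g <- genocchi_polynomial(m)
  n2 <- gp_int01(poly_mul(g, g))   # ||G_m||^2 = num/den > 0
  structure(sqrt(n2$den / n2$num), exact_sq = c(num = n2$den, den = n2$num))
}

#' Construct a Genocchi wavelet basis on \[0, 1)
#'
#' Builds the \eqn{N = 2^{k-1} M} block-wavelet basis
#' \deqn{\psi_{n,m}(\tau) = 2^{(k-1)/2}\, \tilde G_{m+1}(2^{k-1}\tau - n + 1)}
#' on the support \eqn{[(n-1)/2^{k-1}, n/2^{k-1})}, where
#' \eqn{\tilde G_{m+1} = G_{m+1} / \lVert G_{m+1}\rVert_{L^2[0,1]}} is the
#' unit-norm Genocchi polynomial. Functions are ordered with block index
#' \eqn{n = 1..2^{k-1}} outer and polynomial order \eqn{m = 0..M-1} inner.
#'
#' @param k resolution level, positive integer; `k = 1` gives a single block.
#' @param M polynomials per block, integer `>= 2`.
#' @return an object of class `genocchi_basis`: a list with elements `k`,
#'   `M`, `N` and `functions`, each function carrying its block `n`, order
#'   `m`, exact local polynomial (`poly`, a [gpoly()] in the block-local
#'   variable), `support`, numeric `scale` and its exact square `scale_sq`.
#' @examples
#' b <- genocchi_basis(1, 6)
#' evaluate_basis(b, 0.5)
#' @export
genocchi_basis <- function(k, M) {
  if (length(k) != 1 || k < 1 || k != round(k)) stop("'k' must be a positive integer")
  if (length(M) != 1 || M < 2 || M != round(M)) stop("'M' must be an integer >= 2")
  k <- as.integer(k); M <- as.integer(M)
  nblocks <- 2^(k - 1)
  funs <- vector("list", nblocks * M)
  idx <- 0L
  for (n in seq_len(nblocks)) {
    for (m in 0:(M - 1)) {
      idx <- idx + 1L
      nu <- normalization_constant(m + 1)
      sq <- attr(nu, "exact_sq")
      funs[[idx]] <- list(
        n = n, m = m,
        poly = genocchi_polynomial(m + 1),
        support = c((n - 1) / nblocks, n / nblocks),
        scale = sqrt(nblocks) * as.numeric(nu),
        # scale^2 = 2^(k-1) * exact_sq, kept exact for symbolic checks
        scale_sq = rat(nblocks * sq[["num"]], sq[["den"]])
      )
    }
  }
  structure(list(k = k, M = M, N = nblocks * M, functions = funs),
            class = "genocchi_basis")
}

#' @export
print.genocchi_basis <- function(x, ...) {
  cat(sprintf("Genocchi wavelet basis: k = %d, M = %d (%d functions on %d block%s)\n",
              x$k, x$M, x$N, 2^(x$k - 1), if (x$k > 1) "s" else ""))
  invisible(x)
}

# block containing tau; tau = 1 belongs to the last block (closed right end,
# so that the full time grid including tau = 1 is evaluable)
.block_of <- function(basis, tau) {
  nb <- 2^(basis$k - 1)
  pmin(floor(tau * nb) + 1, nb)
}

#' Evaluate a Genocchi wavelet basis
#'
#' @param basis a [genocchi_basis()].
#' @param tau numeric vector of points in \[0, 1\]; at most one block is
#'   active at each point, and `tau = 1` evaluates the last block's
#'   polynomials (closed right endpoint of the domain).
#' @return for a single point, a numeric vector of length `N`; otherwise an
#'   `N x length(tau)` matrix.
#' @export
evaluate_basis <- function(basis, tau) {
  stopifnot(inherits(basis, "genocchi_basis"))
  if (any(tau < 0 | tau > 1)) stop("'tau' must lie in [0, 1]")
  nb <- 2^(basis$k - 1)
  out <- matrix(0, basis$N, length(tau))
  blocks <- .block_of(basis, tau)
  for (j in seq_along(tau)) {
    n <- blocks[j]
    x <- nb * tau[j] - n + 1
    rows <- (n - 1) * basis$M + seq_len(basis$M)
    out[rows, j] <- vapply(basis$functions[rows], function(f) {
      f$scale * poly_eval(f$poly, x)
    }, 0)
  }
  if (length(tau) == 1) drop(out) else out
}

#' Wavelet approximation error bound
#'
#' Upper bound on the \eqn{L^2} error of approximating an \eqn{(n+1)}-times
#' continuously differentiable function on a sub-interval of width `h` by its
#' degree-`n` Genocchi expansion:
#' \deqn{\frac{h^{(2n+3)/2}\, R}{(n+1)!\,\sqrt{2n+3}},}
#' with `R` a bound on the \eqn{(n+1)}-st derivative over the interval.
#'
#' @param h sub-interval width, `> 0`.
#' @param n polynomial degree of the expansion, integer `>= 0`.
#' @param R nonnegative bound on the \eqn{(n+1)}-st derivative.
#' @return nonnegative numeric.
#' @export
approximation_error_bound <- function(h, n, R) {
  if (any(h <= 0)) stop("'h' must be positive")
  if (any(n < 0 | n != round(n))) stop("'n' must be a nonnegative integer")
  if (any(R < 0)) stop("'R' must be nonnegative")
  h^((2 * n + 3) / 2) * R / (factorial(n + 1) * sqrt(2 * n + 3))
}
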