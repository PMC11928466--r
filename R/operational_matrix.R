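# Expansion of an exact polynomial (degree <= maxdeg) in the Genocchi
# polynomials G_1..G_{maxdeg+1}. G_j has degree j-1 and leading coefficient j,
# so back-substitution from the top degree is triangular and exact.
genocchi_expand <- function(p, maxdeg) {
  alphas <- vector("list", maxdeg + 1)
  rem <- .gp_trim(p)
  for (j in rev(seq_len(maxdeg + 1))) {
    if (length(rem$num) >= j && rem$num[j] != 0) {
      a <- rat_div(rat(rem$num[j], rem$den[j]), rat(j))
      g <- genocchi_polynomial(j)
      rem <- gp_sub(rem, .gp_trim(structure(
        rat_mul(list(num = g$num, den = g$den),
                list(num = rep(a$num, length(g$num)),
                     den = rep(a$den, length(g$num)))), class = "gpoly")))
    } else {
      a <- rat(0)
    }
    alphas[[j]] <- a
  }
  if (!gp_equal(rem, gp_zero())) stop("Genocchi expansion did not terminate")
  alphas
}

# exact antiderivative of the block-local unnormalized polynomial:
# integral of G_{m+1} is (G_{m+2}(x) - g_{m+2}) / (m + 2)
.local_antiderivative <- function(m) {
  g <- genocchi_polynomial(m + 2)
  poly_scale(gp_sub(g, gpoly(g$num[1], g$den[1])), 1, m + 2)
}

#' Integrate one Genocchi wavelet on the basis
#'
#' Expands the running integral \eqn{\int_0^\tau \psi_i(s)\,ds} of basis
#' function `i` exactly on the wavelet basis: within its own block the
#' antiderivative is a combination of the block's functions plus a remainder
#' carried by the block's order-`M` function (the one degree the truncated
#' basis cannot represent); past the block it is the constant full-block
#' integral, expressed through the order-0 functions of later blocks.
#'
#' @param basis a [genocchi_basis()].
#' @param i function index in `1..N`.
#' @return a list with `row` (numeric length `N`), `remainder` (coefficient
#'   on the order-`M` function of the block), `tail_constant` (value of the
#'   integral past the block), and exact signed squares `row_sq` /
#'   `remainder_sq` (each a num/den pair; the numerator carries the sign).
#' @export
integrate_basis_function <- function(basis, i) {
  stopifnot(inherits(basis, "genocchi_basis"), i >= 1, i <= basis$N)
  f <- basis$functions[[i]]
  M <- basis$M
  nb <- 2^(basis$k - 1)
  aloc <- .local_antiderivative(f$m)
  alphas <- genocchi_expand(aloc, M)
  inv_sq_i <- attr(normalization_constant(f$m + 1), "exact_sq")

  row <- numeric(basis$N)
  row_sq_num <- numeric(basis$N)
  row_sq_den <- rep(1, basis$N)
  remainder <- 0
  remainder_sq <- c(0, 1)
  for (j in 0:M) {
    a <- alphas[[j + 1]]
    if (a$num == 0) next
    inv_sq_j <- attr(normalization_constant(j + 1), "exact_sq")
    # coefficient on psi_{n,j}: (alpha / 2^(k-1)) * nu_{m+1} / nu_{j+1}
    ratio <- rat(inv_sq_i[["num"]] * inv_sq_j[["den"]],
                 inv_sq_i[["den"]] * inv_sq_j[["num"]])
    val <- rat_num(a) / nb * sqrt(rat_num(ratio))
    sq <- rat_mul(rat(sign(a$num) * a$num^2, (a$den * nb)^2), ratio)
    if (j < M) {
      col <- (f$n - 1) * M + j + 1
      row[col] <- val
      row_sq_num[col] <- sq$num
      row_sq_den[col] <- sq$den
    } else {
      remainder <- val
      remainder_sq <- c(sq$num, sq$den)
    }
  }

  # constant value of the integral for tau past the block
  a1 <- gp_eval_rat(aloc, 1)
  tail_constant <- f$scale / nb * rat_num(a1)
  if (f$n < nb) {
    # express the constant on the order-0 (constant) function of each later
    # block: psi_{n',0} = 2^((k-1)/2) there, so the coefficient is
    # tail / 2^((k-1)/2) = nu_{m+1} * A(1) / 2^(k-1)
    coef <- rat_num(a1) / nb * sqrt(inv_sq_i[["num"]] / inv_sq_i[["den"]])
    sq <- rat_mul(rat(sign(a1$num) * a1$num^2, (a1$den * nb)^2),
                  rat(inv_sq_i[["num"]], inv_sq_i[["den"]]))
    for (np in (f$n + 1):nb) {
      col <- (np - 1) * M + 1
      row[col] <- coef
      row_sq_num[col] <- sq$num
      row_sq_den[col] <- sq$den
    }
  }
  list(row = row, remainder = remainder, tail_constant = tail_constant,
       row_sq = list(num = row_sq_num, den = row_sq_den),
       remainder_sq = c(num = remainder_sq[1], den = remainder_sq[2]))
}

#' Genocchi wavelet operational matrix of integration
#'
#' Assembles the \eqn{N \times N} matrix \eqn{P} and correction term
#' \eqn{\bar\psi} such that
#' \deqn{\int_0^\tau \psi(s)\,ds = P\,\psi(\tau) + \bar\psi(\tau)}
#' holds as an exact polynomial identity on every block. The correction
#' carries, per block, one function of order `M` (degree-`M` polynomial)
#' that the truncated basis cannot represent.
#'
#' @param basis a [genocchi_basis()].
#' @return an object of class `genocchi_opmatrix` with elements `P` (numeric
#'   matrix), `P_sq` (exact signed squares of the entries, num/den matrices),
#'   `correction` (numeric vector of order-`M` coefficients, one slot per
#'   basis function, plus exact squares), `extra` (the order-`M` function of
#'   each block) and `basis`.
#' @examples
#' b <- genocchi_basis(1, 6)
#' op <- integration_matrix(b)
#' op$P[1, 1:2]   # 1/2, 1/(2*sqrt(3))
#' @export
integration_matrix <- function(basis) {
  stopifnot(inherits(basis, "genocchi_basis"))
  N <- basis$N
  P <- matrix(0, N, N)
  P2n <- matrix(0, N, N)
  P2d <- matrix(1, N, N)
  corr <- numeric(N)
  c2n <- numeric(N); c2d <- rep(1, N)
  for (i in seq_len(N)) {
    r <- integrate_basis_function(basis, i)
    P[i, ] <- r$row
    P2n[i, ] <- r$row_sq$num
    P2d[i, ] <- r$row_sq$den
    corr[i] <- r$remainder
    c2n[i] <- r$remainder_sq[["num"]]
    c2d[i] <- r$remainder_sq[["den"]]
  }
  nb <- 2^(basis$k - 1)
  nuM <- normalization_constant(basis$M + 1)
  extra <- lapply(seq_len(nb), function(n) {
    list(n = n, m = basis$M,
         poly = genocchi_polynomial(basis$M + 1),
         support = c((n - 1) / nb, n / nb),
         scale = sqrt(nb) * as.numeric(nuM))
  })
  structure(list(P = P, P_sq = list(num = P2n, den = P2d),
                 correction = corr, correction_sq = list(num = c2n, den = c2d),
                 extra = extra, basis = basis),
            class = "genocchi_opmatrix")
}

#' @export
print.genocchi_opmatrix <- function(x, ...) {
  cat(sprintf("Genocchi operational matrix of integration: %d x %d (k = %d, M = %d)\n",
              nrow(x$P), ncol(x$P), x$basis$k, x$basis$M))
  invisible(x)
}

#' Evaluate the integral representation P psi(tau) + psi-bar(tau)
#'
#' @param opmat a [integration_matrix()] result.
#' @param tau numeric vector of points in \[0, 1\].
#' @return for a single point, a numeric vector of length `N` whose `i`-th
#'   entry equals \eqn{\int_0^\tau \psi_i}; otherwise an `N x length(tau)`
#'   matrix.
#' @export
opmatrix_apply <- function(opmat, tau) {
  stopifnot(inherits(opmat, "genocchi_opmatrix"))
  basis <- opmat$basis
  psi <- evaluate_basis(basis, tau)
  if (length(tau) == 1) psi <- matrix(psi, ncol = 1)
  out <- opmat$P %*% psi
  nb <- 2^(basis$k - 1)
  blocks <- .block_of(basis, tau)
  for (j in seq_along(tau)) {
    n <- blocks[j]
    ex <- opmat$extra[[n]]
    x <- nb * tau[j] - n + 1
    exval <- ex$scale * poly_eval(ex$poly, x)
    rows <- which(vapply(basis$functions, `[[`, 0L, "n") == n)
    out[rows, j] <- out[rows, j] + opmat$correction[rows] * exval
  }
  if (length(tau) == 1) drop(out) else out
}

#' Export an operational matrix (or basis) to CSV
#'
#' Writes the float view plus the exact signed-square representation of each
#' entry, for inspection and debugging.
#'
#' @param opmat a [integration_matrix()] result.
#' @param file path of the CSV to write.
#' @return the written data frame, invisibly.
#' @export
opmatrix_to_csv <- function(opmat, file) {
  N <- nrow(opmat$P)
  df <- data.frame(
    row = rep(seq_len(N), each = N),
    col = rep(seq_len(N), N),
    value = as.vector(t(opmat$P)),
    signed_sq_num = as.vector(t(opmat$P_sq$num)),
    sq_den = as.vector(t(opmat$P_sq$den))
  )
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
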