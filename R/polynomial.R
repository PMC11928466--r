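#' Exact rational polynomials
#'
#' A `gpoly` is a univariate polynomial with exact rational coefficients,
#' stored ascending in degree as parallel integer-valued numerator and
#' denominator vectors. All construction of the Genocchi basis and its
#' operational matrix of integration is done in this exact arithmetic;
#' floating point enters only at evaluation/solve time.
#'
#' @param num numeric vector of integer numerators, ascending degree.
#' @param den numeric vector of integer denominators (recycled if length 1).
#' @return an object of class `gpoly`.
#' @examples
#' p <- gpoly(c(-1, 2))        # 2x - 1
#' poly_eval(p, 0.25)
#' @export
gpoly <- function(num, den = 1) {
  if (length(den) == 1) den <- rep(den, length(num))
  stopifnot(length(num) == length(den))
  if (length(num) == 0) num <- den <- numeric(0)
  r <- rat_reduce(num, den)
  structure(list(num = r$num, den = r$den), class = "gpoly")
}

.gp_trim <- function(p) {
  n <- length(p$num)
  while (n > 1 && p$num[n] == 0) n <- n - 1
  structure(list(num = p$num[seq_len(n)], den = p$den[seq_len(n)]),
            class = "gpoly")
}

#' @export
print.gpoly <- function(x, ...) {
  x <- .gp_trim(x)
  terms <- character(0)
  for (i in seq_along(x$num)) {
    if (x$num[i] == 0 && length(x$num) > 1) next
    c0 <- if (x$den[i] == 1) format(x$num[i]) else
      paste0(format(x$num[i]), "/", format(x$den[i]))
    terms <- c(terms, if (i == 1) c0 else paste0(c0, "*x^", i - 1))
  }
  cat(paste(terms, collapse = " + "), "\n")
  invisible(x)
}

gp_zero <- function() gpoly(0)

gp_degree <- function(p) length(.gp_trim(p)$num) - 1L

gp_add <- function(p, q) {
  n <- max(length(p$num), length(q$num))
  pad <- function(v, fill) c(v, rep(fill, n - length(v)))
  r <- rat_add(list(num = pad(p$num, 0), den = pad(p$den, 1)),
               list(num = pad(q$num, 0), den = pad(q$den, 1)))
  .gp_trim(structure(r, class = "gpoly"))
}

gp_neg <- function(p) structure(list(num = -p$num, den = p$den), class = "gpoly")

gp_sub <- function(p, q) gp_add(p, gp_neg(q))

#' Scale a polynomial by an exact rational
#' @param p a [gpoly()].
#' @param num,den integer numerator and denominator of the scalar.
#' @return a `gpoly`.
#' @export
poly_scale <- function(p, num, den = 1) {
  r <- rat_mul(list(num = p$num, den = p$den),
               list(num = rep(num, length(p$num)),
                    den = rep(den, length(p$num))))
  .gp_trim(structure(r, class = "gpoly"))
}

#' Exact product of two rational polynomials
#' @param p,q objects created by [gpoly()].
#' @return a `gpoly`.
#' @export
poly_mul <- function(p, q) {
  p <- .gp_trim(p); q <- .gp_trim(q)
  dp <- length(p$num); dq <- length(q$num)
  acc <- lapply(seq_len(dp + dq - 1), function(i) rat(0))
  for (i in seq_len(dp)) {
    if (p$num[i] == 0) next
    for (j in seq_len(dq)) {
      if (q$num[j] == 0) next
      term <- rat_mul(list(num = p$num[i], den = p$den[i]),
                      list(num = q$num[j], den = q$den[j]))
      acc[[i + j - 1]] <- rat_add(acc[[i + j - 1]], term)
    }
  }
  gpoly(vapply(acc, `[[`, 0, "num"), vapply(acc, `[[`, 0, "den"))
}

# p(a*x + b) with rational a = an/ad, b = bn/bd, by Horner in gpoly arithmetic
gp_compose_affine <- function(p, an, ad, bn, bd) {
  lin <- gpoly(c(bn * ad, an * bd), c(bd * ad, ad * bd))
  out <- gp_zero()
  for (i in rev(seq_along(p$num))) {
    out <- gp_add(poly_mul(out, lin), gpoly(p$num[i], p$den[i]))
  }
  out
}

# exact antiderivative with zero constant term
gp_antiderivative <- function(p) {
  r <- rat_reduce(c(0, p$num), c(1, p$den * seq_along(p$num)))
  .gp_trim(structure(r, class = "gpoly"))
}

# exact rational value of integral over [0, 1]
gp_int01 <- function(p) {
  acc <- rat(0)
  for (i in seq_along(p$num)) {
    acc <- rat_add(acc, rat(p$num[i], p$den[i] * i))
  }
  acc
}

#' Exact integral of a rational polynomial over [0, 1]
#' @param p a [gpoly()].
#' @return numeric; the attribute `exact` holds the numerator/denominator pair.
#' @export
poly_int01 <- function(p) {
  r <- gp_int01(p)
  structure(rat_num(r), exact = c(num = r$num, den = r$den))
}

# exact evaluation at rational x = xn/xd (Horner)
gp_eval_rat <- function(p, xn, xd = 1) {
  x <- rat(xn, xd)
  acc <- rat(0)
  for (i in rev(seq_along(p$num))) {
    acc <- rat_add(rat_mul(acc, x), rat(p$num[i], p$den[i]))
  }
  acc
}

#' Evaluate a rational polynomial in floating point
#' @param p a [gpoly()].
#' @param x numeric vector of evaluation points.
#' @return numeric vector.
#' @export
poly_eval <- function(p, x) {
  acc <- rep(0, length(x))
  for (i in rev(seq_along(p$num))) {
    acc <- acc * x + p$num[i] / p$den[i]
  }
  acc
}

#' Exact coefficients of a rational polynomial
#' @param p a [gpoly()].
#' @return a data frame with columns `degree`, `num`, `den`, `value`.
#' @export
poly_coefficients <- function(p) {
  data.frame(degree = seq_along(p$num) - 1L, num = p$num, den = p$den,
             value = p$num / p$den)
}

gp_equal <- function(p, q) {
  p <- .gp_trim(p); q <- .gp_trim(q)
  length(p$num) == length(q$num) &&
    all(p$num == q$num) && all(p$den == q$den)
}
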