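test_that("Genocchi recurrence produces the classical polynomials exactly", {
  expect_true(poly_exact_equal(genocchi_polynomial(1), gpoly(1)))
  expect_true(poly_exact_equal(genocchi_polynomial(2), gpoly(c(-1, 2))))
  expect_true(poly_exact_equal(genocchi_polynomial(3), gpoly(c(0, -3, 3))))
  expect_true(poly_exact_equal(genocchi_polynomial(4), gpoly(c(1, 0, -6, 4))))
  expect_true(poly_exact_equal(genocchi_polynomial(0), gpoly(0)))
  expect_error(genocchi_polynomial(-1), "nonnegative")
})

test_that("Genocchi numbers are the constant terms of the polynomials", {
  known <- c(1, -1, 0, 1, 0, -3, 0, 17)   # g_1..g_8
  expect_equal(vapply(1:8, genocchi_number, 0), known)
  for (m in 0:14) {
    p <- genocchi_polynomial(m)
    expect_identical(genocchi_number(m), p$num[1] / p$den[1])
  }
  expect_error(genocchi_number(-2), "nonnegative")
})

test_that("polynomials match the generating function 2t*exp(xt)/(exp(t)+1)", {
  for (xv in c(0, 0.3, 0.77, 1)) {
    for (tv in c(0.1, 0.25, 0.4)) {
      partial <- sum(vapply(1:12, function(m) {
        poly_eval(genocchi_polynomial(m), xv) * tv^m / factorial(m)
      }, 0))
      target <- 2 * tv * exp(xv * tv) / (exp(tv) + 1)
      # truncation error of the order-12 partial sum is far below 1e-9
      expect_equal(partial, target, tolerance = 1e-9)
    }
  }
})

test_that("normalization constants carry exact squares with unit product", {
  expect_identical(attr(normalization_constant(2), "exact_sq"),
                   c(num = 3, den = 1))
  expect_identical(attr(normalization_constant(3), "exact_sq"),
                   c(num = 10, den = 3))           # sqrt(10/3) = sqrt(30)/3
  expect_identical(attr(normalization_constant(4), "exact_sq"),
                   c(num = 35, den = 17))
  for (m in 1:8) {
    sq <- attr(normalization_constant(m), "exact_sq")
    g <- genocchi_polynomial(m)
    n2 <- attr(poly_int01(poly_mul(g, g)), "exact")
    # constant^2 * ||G_m||^2 == 1 in exact rational arithmetic
    expect_identical(sq[["num"]] * n2[["num"]], sq[["den"]] * n2[["den"]])
  }
  expect_error(normalization_constant(0), ">= 1")
})

test_that("the k = 1 basis reproduces the eight closed forms symbolically", {
  basis <- genocchi_basis(1, 8)
  forms <- printed_wavelet_forms()
  for (m in 0:7) {
    f <- basis$functions[[m + 1]]
    form <- forms[[m + 1]]
    # compare scale^2 * G^2 with sq * q^2 as exact rational polynomials,
    # plus the sign of the leading coefficient (radicals are positive)
    lhs <- poly_scale(poly_mul(f$poly, f$poly),
                      f$scale_sq$num, f$scale_sq$den)
    rhs <- poly_scale(poly_mul(form$poly, form$poly),
                      form$sq[1], form$sq[2])
    expect_true(poly_exact_equal(lhs, rhs), label = paste("form m =", m))
    cf <- poly_coefficients(f$poly); cq <- poly_coefficients(form$poly)
    expect_identical(sign(cf$value[nrow(cf)]), sign(cq$value[nrow(cq)]))
  }
})

test_that("each k = 1 wavelet has unit L2 norm by quadrature", {
  basis <- genocchi_basis(1, 8)
  for (m in 0:7) {
    nrm <- stats::integrate(function(t) evaluate_basis(basis, t)[m + 1, ]^2,
                            0, 1, rel.tol = 1e-12, abs.tol = 1e-13)$value
    expect_equal(nrm, 1, tolerance = 1e-12)
  }
})

test_that("basis evaluation matches the closed forms pointwise", {
  b6 <- genocchi_basis(1, 6)
  expect_equal(evaluate_basis(b6, 0),
               c(1, -sqrt(3), 0, sqrt(35 / 17), 0, -3 * sqrt(154 / 691)),
               tolerance = 1e-14)
  expect_equal(evaluate_basis(b6, 0.37)[1], 1)
  expect_equal(evaluate_basis(b6, 0.5)[2], 0)
  expect_equal(evaluate_basis(b6, 0.5)[3], -sqrt(30) / 4, tolerance = 1e-15)
  expect_error(evaluate_basis(b6, 1.2), "0, 1")
  expect_error(genocchi_basis(0, 6))
  expect_error(genocchi_basis(1, 1))
})

test_that("blocks partition [0, 1) and the right endpoint uses the last block", {
  b23 <- genocchi_basis(2, 3)
  expect_equal(b23$N, 6)
  # function (2, 0) is the constant sqrt(2) on [0.5, 1)
  expect_equal(evaluate_basis(b23, 0.25)[4], 0)
  expect_equal(evaluate_basis(b23, 0.75)[4], sqrt(2))
  b22 <- genocchi_basis(2, 2)
  expect_equal(evaluate_basis(b22, 0.1)[3:4], c(0, 0))
  for (b in list(b23, genocchi_basis(3, 2))) {
    nb <- 2^(b$k - 1)
    blockof <- vapply(b$functions, `[[`, 0L, "n")
    for (tau in c(0, 0.123, 0.499, 0.5, 0.87, 0.999)) {
      v <- evaluate_basis(b, tau)
      active <- unique(blockof[v != 0])
      expect_length(active, 1)
      # order-0 function of the active block is a nonzero constant, so
      # exactly one block is active
      expect_equal(active, min(floor(tau * nb) + 1, nb))
    }
    # tau = 1 evaluates the last block rather than returning zero
    expect_true(any(evaluate_basis(b, 1) != 0))
  }
})

test_that("the approximation error bound evaluates the stated formula", {
  expect_equal(approximation_error_bound(1, 0, 0), 0)
  expect_equal(approximation_error_bound(1, 0, 1), 1 / sqrt(3))
  expect_equal(approximation_error_bound(0.25, 1, 2),
               0.25^2.5 * 2 / (2 * sqrt(5)))
  expect_error(approximation_error_bound(0, 1, 1), "positive")
  expect_error(approximation_error_bound(1, -1, 1))
  expect_error(approximation_error_bound(1, 1, -1))
})
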