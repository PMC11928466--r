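# Independent numerical oracles used across the suite.

# integral of basis function i from 0 to tau by adaptive quadrature,
# split at block boundaries (the integrand is discontinuous there)
quad_int_basis <- function(basis, i, tau) {
  f <- function(t) {
    vapply(t, function(tt) evaluate_basis(basis, tt)[i], 0)
  }
  cuts <- sort(unique(c(0, (1:2^(basis$k - 1)) / 2^(basis$k - 1), tau)))
  cuts <- cuts[cuts <= tau + 1e-15]
  total <- 0
  for (j in seq_len(length(cuts) - 1)) {
    total <- total + stats::integrate(f, cuts[j], cuts[j + 1],
                                      rel.tol = 1e-12, abs.tol = 1e-13)$value
  }
  total
}

# Caputo derivative of a power function by direct quadrature of the
# defining integral (order gamma in (0,1)); the kernel singularity at
# theta = tau is removed by the substitution u = (tau - theta)^(1 - gamma)
quad_caputo <- function(f, gam, tau) {
  stopifnot(gam > 0, gam < 1)
  fprime <- function(th) {
    vapply(th, function(t) {
      keep <- f$expo > 0
      if (t == 0) {
        sum((f$coef * f$expo)[keep & f$expo == 1])
      } else {
        sum((f$coef * f$expo)[keep] * t^(f$expo[keep] - 1))
      }
    }, 0)
  }
  g <- function(u) fprime(tau - u^(1 / (1 - gam)))
  val <- stats::integrate(g, 0, tau^(1 - gam),
                          rel.tol = 1e-12, abs.tol = 1e-14)$value
  val / (1 - gam) / gamma(1 - gam)
}

# Riemann-Liouville integral by quadrature, substitution u = (tau - theta)^gamma
quad_rl <- function(f, gam, tau) {
  stopifnot(gam > 0)
  fv <- function(th) evaluate_power(f, th)
  g <- function(u) fv(tau - u^(1 / gam))
  stats::integrate(g, 0, tau^gam,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value / gam / gamma(gam)
}

# exact (rational) comparison helpers for gpoly objects
poly_exact_equal <- function(p, q) {
  cp <- poly_coefficients(p); cq <- poly_coefficients(q)
  n <- max(nrow(cp), nrow(cq))
  pad <- function(df) {
    if (nrow(df) < n) {
      rbind(df, data.frame(degree = nrow(df):(n - 1), num = 0, den = 1,
                           value = 0))
    } else df
  }
  cp <- pad(cp); cq <- pad(cq)
  all(cp$num == cq$num) && all(cp$den == cq$den)
}

# the closed forms of the first eight k = 1 wavelets, as (square of the
# radical prefactor, integer polynomial); built here with exact
# polynomial arithmetic and used to check the generated basis symbolically
printed_wavelet_forms <- function() {
  lin <- gpoly(c(-1, 2))           # -1 + 2 tau
  quad <- gpoly(c(1, 1, -1))       # 1 + tau - tau^2
  list(
    list(sq = c(1, 1),           poly = gpoly(1)),
    list(sq = c(3, 1),           poly = lin),
    list(sq = c(30, 1),          poly = gpoly(c(0, -1, 1))),
    list(sq = c(35, 17),         poly = gpoly(c(1, 0, -6, 4))),
    list(sq = c(630, 31),        poly = gpoly(c(0, 1, 0, -2, 1))),
    list(sq = c(1386, 691),      poly = poly_mul(lin, poly_mul(quad, quad))),
    list(sq = c(12012, 5461),    poly = gpoly(c(0, -3, 0, 5, 0, -3, 1))),
    list(sq = c(6435, 929569),   poly = gpoly(c(17, 0, -84, 0, 70, 0, -28, 8)))
  )
}

# the published gamma = 1 coefficient vectors (6-decimal precision)
published_coefficients <- function() {
  list(A = c(-8.278493, -1.250779, -0.194440, -0.026018, -0.002154, 0.000415),
       B = c(7.301170, 1.099036, 0.169430, 0.022155, 0.001655, -0.000443),
       C = c(0.977323, 0.151743, 0.025011, 0.003863, 0.000499, 0.000027))
}

default_problem <- function(gamma = 1, k = 1, M = 6) {
  collocation_problem(sir_parameters(gamma = gamma), k = k, M = M)
}
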