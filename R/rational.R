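# Internal exact rational arithmetic on doubles holding integers.
# Every value is kept reduced with a positive denominator; magnitudes are
# guarded against leaving the exactly-representable integer range (2^53).

.RAT_MAX <- 2^53

.rat_guard <- function(x) {
  if (any(abs(x) >= .RAT_MAX)) {
    stop("exact rational arithmetic overflow (integer magnitude >= 2^53)")
  }
  x
}

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    keep <- b > 0
    r <- a
    r[keep] <- a[keep] %% b[keep]
    a[keep] <- b[keep]
    b <- r * 0
    b[keep] <- r[keep]
    # loop again only where remainder nonzero
    if (all(b == 0)) break
  }
  pmax(a, 1)
}

# elementwise reduce; dens must be nonzero
rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- .gcd2(num, den)
  list(num = .rat_guard(num / g), den = .rat_guard(den / g))
}

rat_add <- function(a, b) rat_reduce(a$num * b$den + b$num * a$den, a$den * b$den)

rat_sub <- function(a, b) rat_reduce(a$num * b$den - b$num * a$den, a$den * b$den)

rat_mul <- function(a, b) {
  # cross-reduce first to keep intermediates small
  g1 <- .gcd2(a$num, b$den)
  g2 <- .gcd2(b$num, a$den)
  rat_reduce((a$num / g1) * (b$num / g2), (a$den / g2) * (b$den / g1))
}

rat_div <- function(a, b) {
  stopifnot(all(b$num != 0))
  rat_mul(a, list(num = b$den, den = b$num))
}

rat <- function(num, den = rep(1, length(num))) rat_reduce(num, den)

rat_num <- function(a) a$num / a$den

rat_eq <- function(a, b) a$num == b$num & a$den == b$den

rat_is_zero <- function(a) a$num == 0
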