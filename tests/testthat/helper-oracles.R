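# Independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dirichlet eta by direct alternating summation with the half-term tail
# correction (error O(k N^{-(k+1)})); independent of the package's
# closed-form constants.
eta_series <- function(k, N = 1e5L) {
  n <- seq_len(N)
  sum((-1)^(n - 1) / n^k) + (-1)^N / (2 * (N + 1)^k)
}

# Raw moment of the standard half-logistic variable via the series
# identity E[U^p] = 2 p! eta(p).
hl_raw_moment_series <- function(p) 2 * factorial(p) * eta_series(p)

# Invert the closed-form cdf by bisection, never touching qhltexp().
bisect_quantile <- function(p, a = 0, theta = 1, tol = 1e-13) {
  lo <- a
  hi <- a + 1 / theta
  while (phltexp(hi, a, theta) < p) hi <- a + 2 * (hi - a)
  while (hi - lo > tol * max(1, abs(hi))) {
    mid <- (lo + hi) / 2
    if (phltexp(mid, a, theta) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Central-difference derivative.
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# Shannon entropy by adaptive quadrature of -g log g.
entropy_quadrature <- function(a = 0, theta = 1) {
  f <- function(x) {
    g <- dhltexp(x, a, theta)
    ifelse(g > 0, -g * log(g), 0)
  }
  integrate(f, a, Inf, rel.tol = 1e-10)$value
}

# Agreement with a printed figure: within one unit in the last printed
# digit (the source tables mix rounding and truncation).
expect_printed <- function(value, printed, digits) {
  expect_lt(abs(value - printed), 10^-digits)
}
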