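settings <- list(c(0, 1), c(2, 0.5), c(17.88, 0.026), c(0.025, 0.735),
                 c(-3, 4))

test_that("density has its stated closed form, peak theta/2 and unit mass", {
  expect_equal(dhltexp(0, 0, 1), 0.5)
  expect_equal(dhltexp(log(3), 0, 1), 0.375, tolerance = 1e-15)
  expect_equal(dhltexp(1, a = 2, theta = 1), 0)
  for (s in settings) {
    a <- s[1]; th <- s[2]
    expect_equal(integrate(dhltexp, a, Inf, a = a, theta = th,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
    expect_equal(dhltexp(a, a, th), th / 2)
  }
})

test_that("distribution and survival functions complement each other", {
  expect_equal(phltexp(0, 0, 1), 0)
  expect_equal(phltexp(log(3), 0, 1), 0.5, tolerance = 1e-15)
  expect_equal(phltexp(1e6, 0.025, 0.735), 1)
  expect_equal(phltexp(0 - 5, 0, 1, lower.tail = FALSE), 1)
  x <- seq(0.1, 20, length.out = 50)
  expect_equal(phltexp(x) + phltexp(x, lower.tail = FALSE), rep(1, 50),
               tolerance = 1e-15)
})

test_that("hazard equals pdf/survival, rises from theta/2 and is bounded by theta", {
  expect_equal(hhltexp(0, 0, 1), 0.5)
  expect_equal(hhltexp(1e4, 0, 1), 1)
  t <- seq(2, 20, length.out = 200)
  h <- hhltexp(t, a = 0.08, theta = 0.869)
  expect_equal(h, dhltexp(t, 0.08, 0.869) /
                 phltexp(t, 0.08, 0.869, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(all(diff(h) > 0))
  expect_true(all(h >= 0.869 / 2 & h < 0.869))
  expect_error(hhltexp(0, a = 0.08, theta = 0.869), "support")
})

test_that("quantile function inverts the cdf", {
  expect_equal(qhltexp(0, a = 3, theta = 2), 3)
  expect_equal(qhltexp(0.5, 0, 1), bisect_quantile(0.5, 0, 1),
               tolerance = 1e-10)
  expect_equal(qhltexp(0.5, 0, 1), log(3), tolerance = 1e-12)
  expect_equal(qhltexp(0.5, 17.88, 0.026),
               bisect_quantile(0.5, 17.88, 0.026), tolerance = 1e-8)
  expect_equal(qhltexp(1, 0, 1), Inf)
  expect_error(qhltexp(-0.1), "\\[0, 1\\]")
  expect_error(qhltexp(1.1), "\\[0, 1\\]")

  p <- c(0.001, seq(0.01, 0.99, by = 0.01), 0.999)
  for (s in settings) {
    expect_equal(phltexp(qhltexp(p, s[1], s[2]), s[1], s[2]), p,
                 tolerance = 1e-10)
  }
})

test_that("inverse-transform sampling is reproducible and distributed as the model", {
  set.seed(99); one <- rhltexp(1, 0, 1)
  set.seed(99); expect_identical(rhltexp(1, 0, 1), one)

  set.seed(7)
  x <- rhltexp(10000, a = 5, theta = 2)
  expect_gt(min(x), 5)

  set.seed(11)
  y <- rhltexp(10000, 0, 1)
  sd_mean <- sqrt(hltexp_moments(0, 1)$variance / 10000)
  expect_lt(abs(mean(y) - log(4)), 3 * sd_mean)

  set.seed(4)
  n <- 100000
  zs <- sort(rhltexp(n, 0, 1))
  Fz <- phltexp(zs)
  i <- seq_len(n) / n
  ks <- max(pmax(i - Fz, Fz - (i - 1 / n)))
  expect_lt(ks, 0.01)
  expect_error(rhltexp(0), "positive count")
})

test_that("raw-moment quadrature matches the eta-series oracle and closed forms", {
  # standard case: E[X^p] = 2 p! eta(p)
  for (p in 1:4)
    expect_equal(hltexp_moment(p, 0, 1), hl_raw_moment_series(p),
                 tolerance = 1e-8)
  expect_equal(hltexp_moment(1, 0, 1), log(4), tolerance = 1e-10)
  expect_equal(hltexp_moment(2, 0, 1), pi^2 / 3, tolerance = 1e-10)
  expect_equal(hltexp_moment(3, 0, 1), 9 * 1.2020569031595942854,
               tolerance = 1e-10)

  for (s in list(c(0, 1), c(2, 0.5), c(17.88, 0.026))) {
    m <- hltexp_moments(s[1], s[2])
    for (p in 1:4)
      expect_equal(hltexp_moment(p, s[1], s[2]), m$raw[p],
                   tolerance = 1e-8)
  }
  expect_error(hltexp_moment(0), "positive integer")
  expect_error(hltexp_moment(1.5), "positive integer")
})

test_that("mean, variance and shape constants follow the location-scale structure", {
  m1 <- hltexp_moments(0, 1)
  expect_equal(m1$mean, log(4), tolerance = 1e-12)
  expect_equal(m1$variance, (pi^2 - 3 * log(4)^2) / 3, tolerance = 1e-12)
  expect_printed(m1$variance, 1.368, 3)
  expect_printed(m1$mu3, 2.464, 3)
  expect_printed(m1$skewness, 1.54, 2)

  m2 <- hltexp_moments(a = 7, theta = 0.3)
  expect_equal(m2$skewness, m1$skewness, tolerance = 1e-9)
  expect_equal(m2$kurtosis, m1$kurtosis, tolerance = 1e-9)
  expect_equal(m2$variance, m1$variance / 0.3^2, tolerance = 1e-9)
  expect_equal(m2$mean, 7 + log(4) / 0.3, tolerance = 1e-12)

  # oracle route for the shape constants
  mu <- hl_raw_moment_series(1)
  mu2 <- hl_raw_moment_series(2) - mu^2
  mu3 <- hl_raw_moment_series(3) - 3 * mu * hl_raw_moment_series(2) + 2 * mu^3
  expect_equal(m1$skewness, mu3 / mu2^1.5, tolerance = 1e-8)
})

test_that("Shannon entropy is 2 - log(2) - log(theta) nats, matching quadrature", {
  expect_equal(hltexp_entropy(a = 3, theta = 1), 2 - log(2),
               tolerance = 1e-12)
  expect_equal(hltexp_entropy(theta = 1), entropy_quadrature(0, 1),
               tolerance = 1e-6)
  expect_equal(hltexp_entropy(theta = exp(2)), entropy_quadrature(0, exp(2)),
               tolerance = 1e-6)
  expect_equal(hltexp_entropy(theta = exp(2)), -log(2), tolerance = 1e-12)
  for (th in c(0.04, 0.7, 5))
    expect_equal(hltexp_entropy(theta = th) - hltexp_entropy(theta = 2 * th),
                 log(2), tolerance = 1e-12)
})
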