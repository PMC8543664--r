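test_that("SST reduces to the normal distribution at nu = 1, tau -> Inf", {
  expect_equal(dsst(0, 0, 1, 1, 1e6), dnorm(0), tolerance = 1e-6)
  xs <- seq(-5, 5, by = 0.01)
  expect_lt(max(abs(dsst(xs, 0, 1, 1, 1e6) - dnorm(xs))), 1e-6)
  expect_equal(psst(1.959964, 0, 1, 1, 1e6), 0.975, tolerance = 1e-6)
  # symmetric case: the mean is the median
  expect_equal(psst(5, 5, 2, 1, 8), 0.5)
})

test_that("SST density integrates to one and mu/sigma are the mean and SD", {
  pars <- list(c(10, 3, 0.7, 5), c(0, 1, 1.6, 12), c(-4, 2.5, 1, 3))
  for (p in pars) {
    total <- integrate(function(x) dsst(x, p[1], p[2], p[3], p[4]),
                       -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # moment-integration oracle across the skew/tail grid
  for (tau in c(2.5, 6, 50)) {
    for (nu in c(0.5, 1, 2)) {
      m <- integrate(function(x) x * dsst(x, 10, 3, nu, tau), -Inf, Inf,
                     rel.tol = 1e-10, subdivisions = 500L)$value
      v <- integrate(function(x) (x - 10)^2 * dsst(x, 10, 3, nu, tau),
                     -Inf, Inf, rel.tol = 1e-10, subdivisions = 500L)$value
      expect_equal(m, 10, tolerance = 1e-5)
      expect_equal(sqrt(v), 3, tolerance = 1e-5)
    }
  }
})

test_that("SST quantile and cdf are mutual inverses and monotone", {
  qs <- seq(0.01, 0.99, by = 0.01)
  for (p in list(c(10, 3, 0.7, 5), c(0, 1, 2, 3.5))) {
    x <- qsst(qs, p[1], p[2], p[3], p[4])
    expect_true(all(diff(x) > 0))
    expect_equal(psst(x, p[1], p[2], p[3], p[4]), qs, tolerance = 1e-8)
    expect_lt(qsst(0.25, p[1], p[2], p[3], p[4]),
              qsst(0.75, p[1], p[2], p[3], p[4]))
  }
  expect_equal(qsst(0.5, 7, 2, 1, 9), 7, tolerance = 1e-12)
})

test_that("SST sampling is seed-reproducible and matches the analytic cdf", {
  s1 <- withr::with_seed(11, rsst(1000, 10, 3, 0.7, 5))
  s2 <- withr::with_seed(11, rsst(1000, 10, 3, 0.7, 5))
  expect_identical(s1, s2)
  big <- withr::with_seed(12, rsst(1e5, 0, 1, 1, 1e6))
  expect_lt(abs(mean(big)), 3 / sqrt(1e5))
  # Kolmogorov-Smirnov distance against the analytic cdf
  xs <- sort(big)
  ks <- max(abs(seq_along(xs) / length(xs) - psst(xs, 0, 1, 1, 1e6)))
  expect_lt(ks, 0.01)
})

test_that("SST rejects out-of-domain parameters and probabilities", {
  expect_domain_error(dsst(0, 0, 1, 1, 2))     # tau <= 2
  expect_domain_error(dsst(0, 0, -1, 1, 5))    # sigma <= 0
  expect_domain_error(dsst(0, 0, 1, 0, 5))     # nu <= 0
  expect_domain_error(qsst(0, 0, 1, 1, 5))
  expect_domain_error(qsst(1.2, 0, 1, 1, 5))
  expect_domain_error(dist_params("SST", 0, 1, 1, 2))
})

test_that("BCPE density normalizes on the positive axis with mu ~ median", {
  pars <- list(c(10, 0.1, 1.5, 2), c(110, 0.08, -0.5, 3), c(50, 0.15, 0.3, 1.5))
  for (p in pars) {
    total <- integrate(function(x) dbcpe(x, p[1], p[2], p[3], p[4]),
                       0, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  expect_equal(qbcpe(0.5, 10, 0.1, 1.5, 2), 10, tolerance = 1e-6)
  # with nu = 1, tau = 2 the kernel is a (truncated) normal
  expect_equal(dbcpe(100, 100, 0.05, 1, 2), dnorm(100, 100, 5),
               tolerance = 1e-8)
})

test_that("BCPE quantile/cdf round-trip and respect the support", {
  qs <- seq(0.01, 0.99, by = 0.02)
  for (p in list(c(110, 0.05, 0.8, 2.5), c(20, 0.2, -1, 1.5))) {
    x <- qbcpe(qs, p[1], p[2], p[3], p[4])
    expect_true(all(x > 0))
    expect_true(all(diff(x) > 0))
    expect_equal(pbcpe(x, p[1], p[2], p[3], p[4]), qs, tolerance = 1e-8)
  }
  expect_equal(pbcpe(-1, 10, 0.1, 1, 2), 0)
  expect_domain_error(dbcpe(1, -1, 0.1, 1, 2))
})

test_that("links invert exactly and reject out-of-domain values", {
  expect_equal(link_apply("log", 1), 0)
  expect_equal(link_apply("logshift2", 3), 0)
  expect_equal(link_apply("identity", 12.3), 12.3)
  for (lk in c("identity", "log", "logshift2")) {
    v <- c(2.5, 3.7, 10)
    expect_equal(link_invert(lk, link_apply(lk, v)), v, tolerance = 1e-12)
  }
  expect_domain_error(link_apply("logshift2", 2))
  expect_domain_error(link_apply("log", -1))
  expect_identical(unname(family_links("SST")),
                   c("identity", "log", "log", "logshift2"))
  expect_identical(unname(family_links("BCPE")),
                   c("identity", "log", "identity", "log"))
})

test_that("dist_params serializes to a flat record", {
  dp <- dist_params("SST", 10, 3, 0.7, 5)
  expect_named(dp, c("family", "mu", "sigma", "nu", "tau"))
  js <- jsonlite::fromJSON(jsonlite::toJSON(as.list(dp), auto_unbox = TRUE))
  expect_equal(js$tau, 5)
})
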