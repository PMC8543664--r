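test_that("intercept-only normal fit equals closed-form maximum likelihood", {
  d <- sample_norm_data(strict_pop(), 400, seed = 1)
  f <- fit_norm(d, norm_spec("NO", tolerance = 1e-10))
  p <- predict_params(f, 13)
  expect_equal(p$mu, mean(d$score), tolerance = 1e-8)
  expect_equal(p$sigma, sd(d$score) * sqrt(399 / 400), tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("normal-linear fit recovers a simulated slope against the OLS oracle", {
  set.seed(17)
  ages <- seq(5, 21, length.out = 2000)
  d <- tibble::tibble(age = ages, score = 2 + 3 * ages + rnorm(2000))
  f <- fit_norm(d, norm_spec("NO", mu = term_linear(), tolerance = 1e-8))
  slope_hat <- unname(f$coefficients$mu[2])
  expect_equal(slope_hat, 3, tolerance = 0.1 / 3)
  expect_equal(slope_hat, unname(coef(lm(score ~ age, d))[2]), tolerance = 1e-6)
})

test_that("intercept-only SST fit recovers parameters within 3 asymptotic SEs", {
  pop <- const_sst_pop(mu = 20, sigma = 5, nu = 0.8, tau = 6)
  d <- sample_norm_data(pop, 1e4, seed = 3)
  f <- fit_norm(d, norm_spec("SST", tolerance = 1e-6))
  p <- predict_params(f, 13)
  # asymptotic SEs from the observed information at the fitted link values
  nll <- function(th) -sum(dsst(d$score, th[1], exp(th[2]), exp(th[3]),
                                2 + exp(th[4]), log = TRUE))
  th_hat <- c(p$mu, log(p$sigma), log(p$nu), log(p$tau - 2))
  H <- stats::optimHess(th_hat, nll)
  se <- sqrt(diag(solve(H)))
  truth <- c(20, log(5), log(0.8), log(6 - 2))
  expect_true(all(abs(th_hat - truth) < 3 * se))
})

test_that("GAIC follows its definition and BIC is recoverable", {
  d <- sample_norm_data(strict_pop(), 300, seed = 5)
  f <- fit_norm(d, norm_spec("NO", mu = term_linear()))
  expect_equal(gaic(f, 0), f$deviance)
  expect_equal(gaic(f, log(f$n)), -2 * f$loglik + log(300) * f$edf_total)
  expect_lt(gaic(f, 2), gaic(f, 5))
})

test_that("smoothing selection minimizes profile GAIC and straightens clean lines", {
  set.seed(2)
  ages <- seq(5, 21, length.out = 150)
  d <- tibble::tibble(age = ages, score = 1 + 0.5 * ages + rnorm(150, 0, 0.01))
  sp <- norm_spec("NO", mu = term_pspline())
  sp_no_auto <- norm_spec("NO", mu = term_linear())
  expect_identical(select_lambda(d, sp_no_auto, 5), sp_no_auto)
  sp_sel <- select_lambda(d, sp, k = 5)
  lam <- sp_sel$terms$mu$lambda
  g5 <- function(l) {
    s <- sp
    s$terms$mu$lambda <- l
    gaic(fit_norm(d, s), 5)
  }
  expect_lte(g5(lam), g5(1e-4) + 1e-6)
  expect_lte(g5(lam), g5(1e6) + 1e-6)
  f <- fit_norm(d, sp_sel)
  expect_gt(lam, 1e3)          # near-linear signal drives lambda up
  expect_lt(f$edf$mu, 3.5)     # close to the order-2 null space dimension
})

test_that("BIC model selection returns the minimal-BIC candidate with correct BIC", {
  d <- sample_norm_data(strict_pop(), 250, seed = 8)
  cands <- list(norm_spec("NO", mu = term_poly(0)),
                norm_spec("NO", mu = term_poly(1)),
                norm_spec("NO", mu = term_poly(2)))
  sel <- select_model_bic(d, cands)
  expect_equal(sel$bic, min(sel$table$bic))
  f <- sel$fit
  expect_equal(sel$bic, -2 * f$loglik + log(f$n) * f$edf_total,
               tolerance = 1e-10)
  expect_identical(select_model_bic(d, cands[2])$spec, cands[[2]])
  # the study's polynomial SST grid enumerates 6 * 6 * 6 * 3 models
  expect_length(sst_poly_candidates(), 648L)
})

test_that("predict_params is constant for intercept fits and exact on lines", {
  d <- sample_norm_data(strict_pop(), 300, seed = 9)
  f0 <- fit_norm(d, norm_spec("NO"))
  p <- predict_params(f0, c(5, 10, 21))
  expect_equal(p$mu, rep(p$mu[1], 3))
  expect_equal(p$sigma, rep(p$sigma[1], 3))
  ages <- seq(5, 21, length.out = 200)
  dl <- tibble::tibble(age = ages, score = 2 + 3 * ages)
  fl <- fit_norm(dl, norm_spec("NO", mu = term_linear(), tolerance = 1e-10))
  expect_equal(predict_params(fl, c(7.25, 18.5))$mu, 2 + 3 * c(7.25, 18.5),
               tolerance = 1e-8)
  # SST tau stays in its link range everywhere
  dS <- sample_norm_data(flex_pop(), 400, seed = 10)
  fS <- fit_norm(dS, build_estimation_spec(flex_pop(), "Strict[long]"))
  expect_true(all(predict_params(fS, seq(5, 21, length.out = 50))$tau > 2))
  expect_domain_error(predict_params(fS, NaN))
})

test_that("refitting the same data and spec is bit-reproducible", {
  d <- sample_norm_data(flex_pop(), 300, seed = 12)
  sp <- build_estimation_spec(flex_pop(), "True[linear/splines]")
  f1 <- fit_norm(d, sp)
  f2 <- fit_norm(d, sp)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("true-model parameter curves improve with sample size", {
  pop <- flex_pop()
  sp <- build_estimation_spec(pop, "True[linear/splines]")
  ages <- seq(5, 21, length.out = 100)
  truth <- population_params(pop, ages)
  mae <- vapply(c(500, 2000), function(n) {
    mean(vapply(1:5, function(s) {
      f <- fit_norm(sample_norm_data(pop, n, seed = 20 + s), sp)
      mean(abs(predict_params(f, ages)$mu - truth$mu))
    }, 1))
  }, 1)
  expect_lt(mae[2], mae[1])
})

test_that("failed fits are flagged rather than raising, and block downstream use", {
  # two observations cannot support a four-parameter spline model
  d <- tibble::tibble(age = c(5, 21), score = c(0, 1))
  f <- fit_norm(d, build_estimation_spec(flex_pop(), "True[linear/splines]"))
  expect_true(f$failed)
  expect_error(gaic(f, 2), class = "nt_error_failed_fit")
  expect_error(predict_params(f, 10), class = "nt_error_failed_fit")
})

test_that("fitted models round-trip through JSON with norms intact", {
  d <- sample_norm_data(flex_pop(), 300, seed = 14)
  f <- fit_norm(d, build_estimation_spec(flex_pop(), "Strict[long]"))
  path <- withr::local_tempfile(fileext = ".json")
  write_norm_model(f, path)
  f2 <- read_norm_model(path)
  ages <- c(6, 11, 19)
  expect_equal(predict_params(f2, ages), predict_params(f, ages),
               tolerance = 1e-12)
  zd <- tibble::tibble(age = ages, score = c(10, 20, 30))
  expect_equal(estimate_z(f2, zd)$z, estimate_z(f, zd)$z, tolerance = 1e-12)
})

test_that("tidy and glance summarize fits in broom style", {
  d <- sample_norm_data(strict_pop(), 200, seed = 15)
  f <- fit_norm(d, norm_spec("NO", mu = term_linear()))
  td <- tidy(f)
  expect_named(td, c("parameter", "term", "estimate"))
  expect_identical(nrow(td), 3L)  # two mu coefficients + sigma intercept
  gl <- glance(f)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$BIC, gaic(f, log(200)))
})
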