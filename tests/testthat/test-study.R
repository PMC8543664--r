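test_that("estimation-model applicability follows the factorial rules", {
  pops <- all_populations()
  # fully flexible population: true models, strict variants, BCPE
  expect_setequal(applicable_models(pops[["NL-HeNN"]]),
                  c("True[linear/splines]", "True[poly]", "Strict[long]",
                    "Strict[trans]", "Strict[long,trans]", "BCPE"))
  # most restricted population: true model, flexible variants, BCPE
  expect_setequal(applicable_models(pops[["Li-HoNo"]]),
                  c("True[linear/splines]", "Flex[long]", "Flex[trans]",
                    "Flex[long,trans]", "BCPE"))
  # no single estimation model mixes strict and flexible variants
  for (pop in pops) {
    for (m in applicable_models(pop)) {
      expect_false(grepl("Strict", m) && grepl("Flex", m))
    }
  }
})

test_that("condition enumeration reproduces the design counts", {
  cond <- enumerate_conditions()
  combos <- dplyr::distinct(cond, population_id, model)
  expect_identical(nrow(combos), 43L)
  expect_identical(nrow(cond), 129L)
  samples <- nrow(dplyr::distinct(cond, population_id, n)) * 1000
  expect_identical(samples, 24000)
  # enumeration is order-stable
  expect_identical(cond, enumerate_conditions())
})

test_that("estimation specs encode the flexibility classes", {
  pops <- all_populations()
  flex <- pops[["NL-HeNN"]]
  strictest <- build_estimation_spec(flex, "Strict[long,trans]")
  expect_identical(strictest$family, "NO")
  expect_identical(strictest$terms$mu$kind, "linear")
  expect_identical(strictest$terms$sigma$kind, "intercept")
  bcpe <- build_estimation_spec(flex, "BCPE")
  expect_identical(bcpe$family, "BCPE")
  expect_identical(bcpe$offset, 100)
  expect_true(all(vapply(bcpe$terms, `[[`, "", "kind") == "pspline"))
  tp <- build_estimation_spec(flex, "True[poly]")
  expect_identical(vapply(tp$terms, `[[`, 1L, "degree"),
                   c(mu = 4L, sigma = 2L, nu = 4L, tau = 1L))
  # true model mirrors the population structure
  tr <- build_estimation_spec(flex, "True[linear/splines]")
  expect_identical(tr$family, "SST")
  expect_identical(tr$terms$mu$kind, "pspline")
  tr2 <- build_estimation_spec(pops[["Li-HoNo"]], "True[linear/splines]")
  expect_identical(tr2$family, "NO")
  expect_identical(tr2$terms$mu$kind, "linear")
  expect_identical(tr2$terms$sigma$kind, "intercept")
  ft <- build_estimation_spec(pops[["Li-HoNo"]], "Flex[trans]")
  expect_identical(ft$family, "SST")
  expect_identical(ft$terms$sigma$kind, "pspline")
  expect_domain_error(build_estimation_spec(pops[["Li-HoNo"]], "Strict[long]"))
})

test_that("a reduced study run is deterministic and internally consistent", {
  pop <- strict_pop()
  run1 <- run_study(populations = pop, sample_sizes = 200, R = 3,
                    I = 15, J = 8, seed = 7, models = "True[linear/splines]")
  run2 <- run_study(populations = pop, sample_sizes = 200, R = 3,
                    I = 15, J = 8, seed = 7, models = "True[linear/splines]")
  expect_identical(run1$aggregates, run2$aggregates)
  expect_identical(run1$cells, run2$cells)
  ag <- run1$aggregates
  expect_identical(ag$R_effective + ag$n_failed, as.integer(ag$R))
  # aggregates match recomputation from the cells
  re <- aggregate_outcomes(run1$cells)
  expect_equal(ag$mean_abs_bias, re$mean_abs_bias)
  expect_equal(ag$mean_rmse, re$mean_rmse)
  # per-cell identity survives the streaming accumulation
  expect_lt(max(abs(run1$cells$rmse^2 -
                      (run1$cells$variance + run1$cells$bias^2))), 1e-12)
  # changing the master seed changes the draws
  run3 <- run_study(populations = pop, sample_sizes = 200, R = 3,
                    I = 15, J = 8, seed = 8, models = "True[linear/splines]")
  expect_false(identical(run1$aggregates$mean_rmse, run3$aggregates$mean_rmse))
})

test_that("study results can be exported as CSV tables", {
  dir <- withr::local_tempdir()
  run_study(populations = strict_pop(), sample_sizes = 150, R = 2,
            I = 10, J = 6, seed = 9, models = "True[linear/splines]",
            out_dir = dir)
  expect_true(file.exists(file.path(dir, "aggregates.csv")))
  expect_true(file.exists(file.path(dir, "cells.csv")))
  nc <- utils::read.csv(file.path(dir, "nonconvergence.csv"))
  expect_named(nc, c("population_id", "model", "n", "n_failed", "n_maxiter"))
})

test_that("the heat-map matrix reshapes per-cell RMSE by age and z", {
  st <- run_study(populations = strict_pop(), sample_sizes = 150, R = 2,
                  I = 10, J = 6, seed = 9, models = "True[linear/splines]")
  m <- rmse_heatmap_matrix(st, "Li-HoNo", "True[linear/splines]", 150)
  expect_identical(dim(m), c(10L, 6L))
  expect_true(all(is.finite(m)))
  expect_error(rmse_heatmap_matrix(st, "NL-HeNN", "BCPE", 150),
               class = "nt_error_domain")
})
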