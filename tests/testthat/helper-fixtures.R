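# small fixtures shared across test files

flex_pop <- function() build_population()                       # NL-HeNN
strict_pop <- function() build_population(TRUE, TRUE, TRUE)     # Li-HoNo

# an age-constant SST population, handy for intercept-only fits
const_sst_pop <- function(mu = 20, sigma = 5, nu = 0.8, tau = 6) {
  build_population(curves = list(mu = mu, lsigma = log(sigma),
                                 lnu = log(nu), ltau = log(tau - 2)))
}

expect_domain_error <- function(expr) {
  expect_error(expr, class = "nt_error_domain")
}
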