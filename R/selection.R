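# Model-complexity criteria and model selection: GAIC, profile smoothing
# selection, and the BIC search over the polynomial candidate grid.

#' Generalized Akaike information criterion of a fit
#'
#' `GAIC(k) = -2 logLik + k * edf`, with the effective degrees of freedom of
#' the penalized fit.  `k = 2` gives AIC, `k = log(n)` BIC, `k = 0` the
#' global deviance.
#'
#' @param fit a `normfit` object (not failed).
#' @param k penalty per effective degree of freedom.
#' @export
gaic <- function(fit, k = 2) {
  stopifnot(inherits(fit, "normfit"))
  if (fit$failed)
    abort("cannot compute GAIC for a failed fit", class = "nt_error_failed_fit")
  -2 * fit$loglik + k * fit$edf_total
}

#' Select P-spline smoothing parameters by profile GAIC
#'
#' For every `"auto"` P-spline term in `spec`, searches the smoothing
#' parameter by golden-section on `log(lambda)` over `[1e-4, 1e6]`,
#' minimizing the GAIC of the fully refitted model; ties are broken toward
#' the smoother (larger) lambda.  Terms are profiled one at a time in the
#' order mu, sigma, nu, tau.  This is the explicit, refit-based counterpart
#' of the fast within-cycle selection [fit_norm()] performs; both minimize
#' the same criterion.
#'
#' @param data normative sample with columns `age`, `score`.
#' @param spec an [norm_spec()].
#' @param k GAIC penalty (default 5, as used for smoothing selection in the
#'   norming study).
#' @return `spec` with every `"auto"` lambda replaced by the selected value.
#' @export
select_lambda <- function(data, spec, k = 5) {
  auto <- names(spec$terms)[vapply(spec$terms, function(tm)
    tm$kind == "pspline" && identical(tm$lambda, "auto"), TRUE)]
  if (length(auto) == 0) return(spec)
  for (pname in auto) {
    crit <- function(loglam) {
      sp <- spec
      sp$terms[[pname]]$lambda <- exp(loglam)
      f <- fit_norm(data, sp)
      if (f$failed) return(Inf)
      gaic(f, k)
    }
    opt <- golden_section(crit, log(1e-4), log(1e6), tol = 0.05)
    # near-ties go to the smoother end of the search range
    spec$terms[[pname]]$lambda <-
      if (crit(log(1e6)) <= crit(opt) + 0.1) 1e6 else exp(opt)
  }
  spec
}

# golden-section minimization; on near-ties drifts toward the upper end
golden_section <- function(f, lo, hi, tol = 1e-3) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 > f2 + 1e-12) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

#' Candidate grid of polynomial SST models
#'
#' Enumerates every SST model with orthogonal-polynomial age terms of degree
#' 0..`mu_max` for mu, 0..`sigma_max` for sigma, 0..`nu_max` for nu and
#' 0..`tau_max` for tau.  With the defaults this is the 6 x 6 x 6 x 3 = 648
#' model grid searched (by BIC) to choose the flexible population model of
#' the norming study.
#'
#' @param mu_max,sigma_max,nu_max,tau_max maximal polynomial degrees.
#' @param ... passed on to [norm_spec()].
#' @return A list of `nt_spec` objects.
#' @export
sst_poly_candidates <- function(mu_max = 5, sigma_max = 5, nu_max = 5,
                                tau_max = 2, ...) {
  grid <- expand.grid(mu = 0:mu_max, sigma = 0:sigma_max, nu = 0:nu_max,
                      tau = 0:tau_max, KEEP.OUT.ATTRS = FALSE)
  purrr::pmap(grid, function(mu, sigma, nu, tau) {
    norm_spec("SST", mu = term_poly(mu), sigma = term_poly(sigma),
              nu = term_poly(nu), tau = term_poly(tau), ...)
  })
}

#' Select the best model by BIC over a candidate list
#'
#' Fits every candidate specification and returns the one with the lowest
#' BIC (`GAIC(log n)`) among those that could be estimated.  Ties are broken
#' by smaller total effective df, then by candidate order.
#'
#' @param data normative sample with columns `age`, `score`.
#' @param candidates list of [norm_spec()] objects.
#' @return A list with elements `spec`, `fit`, `bic`, and a tibble `table`
#'   of per-candidate BICs.
#' @export
select_model_bic <- function(data, candidates) {
  if (length(candidates) == 0)
    abort("no candidate models supplied", class = "nt_error_domain")
  fits <- lapply(candidates, function(sp) fit_norm(data, sp))
  ok <- !vapply(fits, `[[`, TRUE, "failed")
  if (!any(ok))
    abort("all candidate models failed to fit", class = "nt_error_failed_fit")
  bic <- rep(Inf, length(fits))
  edf <- rep(Inf, length(fits))
  bic[ok] <- vapply(fits[ok], function(f) gaic(f, log(f$n)), 1)
  edf[ok] <- vapply(fits[ok], `[[`, 1, "edf_total")
  best <- order(bic, edf, seq_along(fits))[1]
  list(spec = candidates[[best]], fit = fits[[best]], bic = bic[best],
       table = tibble(candidate = seq_along(fits), bic = bic, edf = edf,
                      failed = !ok))
}
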