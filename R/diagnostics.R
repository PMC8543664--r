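# Visual-diagnostic data products: normalized quantile residuals, worm
# plots (detrended Q-Q, optionally per age bin), and the underfit/overfit
# contrast between BIC- and GAIC(0.1)-selected smoothing.

#' Normalized quantile residuals
#'
#' For each record, the standard-normal quantile of the score's percentile
#' in the model's conditional distribution at its age.  Under a correctly
#' specified model the residuals are standard normal.  Scores are
#' continuous, so plain (non-randomized) quantile residuals apply.
#'
#' @param object a `normfit` or `norm_population` object.
#' @param data data frame with columns `age`, `score`.
#' @return Numeric vector of residuals.
#' @export
quantile_residuals <- function(object, data) {
  estimate_z(object, data)$z
}

#' Worm-plot data: detrended Q-Q of quantile residuals per age bin
#'
#' Splits the sample into `n_bins` equal-count age bins; within each bin the
#' ordered residuals are matched to standard-normal order quantiles
#' (`qnorm(ppoints(m))`) and the deviation (ordered residual minus
#' theoretical quantile) is the worm.  Deviations near zero indicate good
#' fit; systematic shapes indicate misfit of location, spread, skewness or
#' tail weight within that age range.
#'
#' @param object a `normfit` or `norm_population` object.
#' @param data data frame with columns `age`, `score`.
#' @param n_bins number of equal-count age bins (`1` = one global worm).
#' @return A tibble of class `nt_worm` with columns `bin`, `bin_lo`,
#'   `bin_hi`, `theoretical`, `residual`, `deviation`.
#' @export
worm_plot_data <- function(object, data, n_bins = 4) {
  if (n_bins < 1) abort("n_bins must be >= 1", class = "nt_error_domain")
  res <- quantile_residuals(object, data)
  age <- as.numeric(data$age)
  if (n_bins == 1) {
    bin <- rep(1L, length(age))
    brks <- range(age)
  } else {
    brks <- unique(quantile(age, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- as.integer(cut(age, breaks = brks, include.lowest = TRUE))
  }
  out <- purrr::map_dfr(sort(unique(bin)), function(b) {
    rb <- sort(res[bin == b])
    m <- length(rb)
    if (m == 0) return(NULL)
    tibble(bin = b, bin_lo = brks[b], bin_hi = brks[b + 1],
           theoretical = qnorm(ppoints(m)), residual = rb,
           deviation = rb - qnorm(ppoints(m)))
  })
  class(out) <- c("nt_worm", class(out))
  out
}

#' @rdname worm_plot_data
#' @param object a `nt_worm` tibble (for `autoplot`).
#' @param ... unused.
#' @export
autoplot.nt_worm <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$theoretical, .data$deviation)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::facet_wrap(~ .data$bin) +
    ggplot2::labs(x = "standard-normal quantile", y = "deviation") +
    ggplot2::theme_minimal()
}

#' Strict vs BIC-smoothed vs GAIC(0.1)-smoothed fits
#'
#' Fits three norming models to one normative sample: a very strict model
#' (normal family, linear mean, constant sigma), a properly smoothed skew
#' Student *t* P-spline model with smoothing selected by BIC, and a very
#' flexible one with smoothing selected by GAIC(0.1), whose penalty on
#' complexity is far weaker than the BIC's.  The trio illustrates under-
#' and overfitting: the strict fit shows large worm deviations, the
#' GAIC(0.1) fit spends at least as many effective df as the BIC fit.
#'
#' @param data normative sample with columns `age`, `score` (n >= 100).
#' @param n_knots interior knots for the P-spline terms.
#' @return A named list of `normfit` objects: `strict`, `bic`, `gaic01`.
#' @export
fit_three_way <- function(data, n_knots = 6) {
  if (nrow(data) < 100)
    abort("fit_three_way needs n >= 100", class = "nt_error_domain")
  n <- nrow(data)
  ps <- function() term_pspline(n_knots = n_knots)
  strict <- fit_norm(data, norm_spec("NO", mu = term_linear(),
                                     sigma = term_intercept()))
  sst <- function(k) norm_spec("SST", mu = ps(), sigma = ps(), nu = ps(),
                               tau = ps(), gaic_k = k)
  bic <- fit_norm(data, sst(log(n)))
  gaic01 <- fit_norm(data, sst(0.1))
  list(strict = strict, bic = bic, gaic01 = gaic01)
}
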