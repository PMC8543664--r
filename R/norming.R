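# Norming: convert observed scores into estimated normalized z scores under
# a fitted (or population) model, and produce centile curves.

#' Centile sets used for centile-curve displays
#'
#' Two conventional percentile sets for centile plots of normative data.
#' @export
centile_sets <- list(
  default = c(1, 5, 15, 25, 50, 75, 85, 95, 99),
  extended = c(1, 5, 10, 25, 50, 75, 90, 95, 99)
)

model_family <- function(object) {
  if (inherits(object, "norm_population")) object$family else object$family
}

model_offset <- function(object) {
  if (inherits(object, "normfit")) object$offset else 0
}

#' Estimate normalized z scores for observed scores
#'
#' For each (age, score) record, computes the score's percentile in the
#' model's conditional distribution at that age and maps it through the
#' inverse normal distribution.  Extreme estimated percentiles would give
#' infinite z, so probabilities are clipped to `[1e-15, 1 - 1e-15]` and the
#' resulting z scores are bounded to `[-5, +5]`; records affected by either
#' guard carry `clamped = TRUE`.  The clamp is part of the estimator: all
#' downstream bias/variance/RMSE evaluation uses the clamped values.
#'
#' @param object a `normfit` or `norm_population` object.
#' @param data data frame with columns `age` and `score`.
#' @param ... unused.
#' @return A tibble with columns `age`, `score`, `percentile`, `z`,
#'   `clamped`.
#' @export
estimate_z <- function(object, data, ...) {
  if (inherits(object, "normfit") && object$failed)
    abort("cannot norm scores with a failed fit", class = "nt_error_failed_fit")
  age <- as.numeric(data$age)
  score <- as.numeric(data$score) + model_offset(object)
  par <- predict_params(object, age)
  p <- fam_cdf(model_family(object), score, par$mu, par$sigma, par$nu, par$tau)
  pc <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  z <- qnorm(pc)
  zc <- pmin(pmax(z, -5), 5)
  tibble(age = age, score = as.numeric(data$score), percentile = pc, z = zc,
         clamped = (p < 1e-15 | p > 1 - 1e-15 | abs(z) > 5))
}

#' Centile curves of a fitted norming model
#'
#' Scores at fixed percentiles as a function of age.
#'
#' @param object a `normfit` or `norm_population` object.
#' @param ages ages at which to evaluate the curves.
#' @param percentiles percentiles in (0, 100); defaults to
#'   `centile_sets$default`.
#' @param ... unused.
#' @return A tibble with one row per age and one column `p<percentile>` per
#'   percentile; scores increase strictly with percentile at every age.
#' @export
centile_curves <- function(object, ages, percentiles = centile_sets$default,
                           ...) {
  if (any(percentiles <= 0 | percentiles >= 100))
    abort("percentiles must lie strictly in (0, 100)", class = "nt_error_domain")
  par <- predict_params(object, ages)
  fam <- model_family(object)
  off <- model_offset(object)
  cols <- lapply(percentiles, function(p) {
    fam_quantile(fam, p / 100, par$mu, par$sigma, par$nu, par$tau) - off
  })
  names(cols) <- paste0("p", percentiles)
  out <- tibble(age = ages)
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]
  class(out) <- c("nt_centiles", class(out))
  out
}

#' Plot centile curves
#'
#' @param object a tibble from [centile_curves()].
#' @param data optional normative sample (columns `age`, `score`) drawn as
#'   points behind the curves.
#' @param ... unused.
#' @export
autoplot.nt_centiles <- function(object, data = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"age",
                              names_to = "percentile", values_to = "score")
  long$percentile <- factor(long$percentile,
                            levels = setdiff(names(object), "age"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$score,
                                          group = .data$percentile))
  if (!is.null(data))
    p <- p + ggplot2::geom_point(data = as_tibble(data),
                                 ggplot2::aes(.data$age, .data$score),
                                 inherit.aes = FALSE,
                                 colour = "grey70", size = 0.5)
  p + ggplot2::geom_line(ggplot2::aes(colour = .data$percentile)) +
    ggplot2::labs(x = "age", y = "score", colour = "percentile") +
    ggplot2::theme_minimal()
}

# ---- serialization: a fitted model file sufficient to recompute norms -------

#' Write or read a fitted norming model as JSON
#'
#' The file stores the family, links, per-parameter coefficients, term
#' references (polynomial transforms, spline knots), offset and fit
#' summaries -- enough to recompute norms and centiles without the training
#' sample.
#'
#' @param fit a `normfit` object.
#' @param path file path.
#' @export
write_norm_model <- function(fit, path) {
  if (fit$failed) abort("cannot serialize a failed fit",
                        class = "nt_error_failed_fit")
  jsonlite::write_json(list(
    family = fit$family, links = as.list(fit$links),
    coefficients = fit$coefficients, term_refs = fit$term_refs,
    lambda = fit$lambda, edf = fit$edf, loglik = fit$loglik,
    iterations = fit$iterations, converged = fit$converged,
    n = fit$n, offset = fit$offset, age_range = fit$age_range
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_norm_model
#' @export
read_norm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$links <- unlist(obj$links)
  obj$failed <- FALSE
  obj$deviance <- -2 * obj$loglik
  obj$edf <- as.list(obj$edf)
  obj$edf_total <- sum(unlist(obj$edf))
  obj$term_refs <- lapply(obj$term_refs, function(r) {
    r <- as.list(r)
    if (!is.null(r$coefs)) r$coefs <- as.list(r$coefs)[c("alpha", "norm2")] |>
        lapply(unlist)
    r
  })
  structure(obj, class = "normfit")
}
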