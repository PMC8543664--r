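# Study orchestration: enumerate the factorial conditions, build estimation
# models per condition, run replicates with managed seeds, and aggregate.

estimation_model_labels <- c(
  "True[linear/splines]", "True[poly]",
  "Strict[long]", "Strict[trans]", "Strict[long,trans]",
  "Flex[long]", "Flex[trans]", "Flex[long,trans]", "BCPE")

#' Estimation models applicable to a population
#'
#' The applicability rules of the factorial design: the true model and the
#' BCPE model are estimated for every population; `True[poly]` only for the
#' fully flexible population; a strict variant only where the population has
#' the corresponding structure to restrict (strict longitudinal needs a
#' nonlinear mean, strict transversal needs heteroscedasticity or
#' nonnormality); a flexible variant only where the population has the
#' corresponding restriction to relax.  Strict and flexible variants are
#' never mixed.
#'
#' @param pop a [build_population()] object.
#' @return Character vector of estimation-model labels.
#' @export
applicable_models <- function(pop) {
  fl <- pop$flags
  nonlinear <- !fl[["linear_mu"]]
  het_or_nn <- !fl[["homoscedastic"]] || !fl[["normal"]]
  ho_or_no <- fl[["homoscedastic"]] || fl[["normal"]]
  out <- c("True[linear/splines]",
           if (nonlinear && het_or_nn && !fl[["homoscedastic"]] && !fl[["normal"]])
             "True[poly]",
           if (nonlinear) "Strict[long]",
           if (het_or_nn) "Strict[trans]",
           if (nonlinear && het_or_nn) "Strict[long,trans]",
           if (!nonlinear) "Flex[long]",
           if (ho_or_no) "Flex[trans]",
           if (!nonlinear && ho_or_no) "Flex[long,trans]",
           "BCPE")
  out
}

#' Enumerate study conditions
#'
#' Crosses the eight populations with their applicable estimation models
#' and the sample sizes.  With the defaults this reproduces the design:
#' 43 population x estimation combinations, 129 conditions over 3 sample
#' sizes, and `8 * 3 * R` generated samples (24,000 at R = 1000; one sample
#' per population x n x replicate is shared by all applicable estimation
#' models).
#'
#' @param sample_sizes normative sample sizes.
#' @param R replicates per condition.
#' @param populations list of populations (default [all_populations()]).
#' @return A tibble with one row per condition: `population_id`, `model`,
#'   `n`, `R`.
#' @export
enumerate_conditions <- function(sample_sizes = c(500, 1000, 2000), R = 1000,
                                 populations = all_populations()) {
  purrr::map_dfr(populations, function(pop) {
    tidyr::expand_grid(population_id = pop$population_id,
                       model = applicable_models(pop),
                       n = sample_sizes, R = R)
  }) |>
    dplyr::arrange(match(.data$population_id,
                         vapply(populations, `[[`, "", "population_id")),
                   match(.data$model, estimation_model_labels), .data$n)
}

#' Build the estimation-model specification for a condition
#'
#' Translates an estimation-model label into a concrete [norm_spec()] for a
#' given population.  The true model mirrors the population structure:
#' family equal to the population's, a linear mean term when the population
#' mean is linear and a P-spline when it is nonlinear, intercepts for
#' constant parameters and P-splines for age-varying ones.  Strict variants
#' restrict (normal family with constant sigma for the transversal strict,
#' linear mean for the longitudinal strict); flexible variants free the
#' corresponding part (skew *t* with age-varying sigma, nu, tau; P-spline
#' mean).  The BCPE model uses P-splines for all four parameters and is
#' fitted on scores + 100.  `True[poly]` uses the flexible population's
#' polynomial degrees (4, 2, 4, 1).
#'
#' @param pop a [build_population()] object.
#' @param model an estimation-model label (see [applicable_models()]).
#' @param n_knots interior knots for all P-spline terms.
#' @param gaic_k GAIC penalty for smoothing selection.
#' @param max_iterations iteration cap.
#' @return An [norm_spec()] object.
#' @export
build_estimation_spec <- function(pop, model, n_knots = 6, gaic_k = 5,
                                  max_iterations = 2000) {
  if (!model %in% applicable_models(pop))
    abort(paste0("estimation model '", model, "' is not applicable to ",
                 pop$population_id), class = "nt_error_domain")
  fl <- pop$flags
  ps <- function() term_pspline(n_knots = n_knots)
  mu_true <- if (fl[["linear_mu"]]) term_linear() else ps()
  sigma_true <- if (fl[["homoscedastic"]]) term_intercept() else ps()

  spec <- switch(
    model,
    "True[linear/splines]" = {
      if (fl[["normal"]])
        norm_spec("NO", mu = mu_true, sigma = sigma_true)
      else
        norm_spec("SST", mu = mu_true, sigma = sigma_true,
                  nu = ps(), tau = ps())
    },
    "True[poly]" = norm_spec("SST", mu = term_poly(4), sigma = term_poly(2),
                             nu = term_poly(4), tau = term_poly(1)),
    "Strict[long]" = {
      if (fl[["normal"]])
        norm_spec("NO", mu = term_linear(), sigma = sigma_true)
      else
        norm_spec("SST", mu = term_linear(), sigma = sigma_true,
                  nu = ps(), tau = ps())
    },
    "Strict[trans]" = norm_spec("NO", mu = mu_true, sigma = term_intercept()),
    "Strict[long,trans]" = norm_spec("NO", mu = term_linear(),
                                     sigma = term_intercept()),
    "Flex[long]" = {
      if (fl[["normal"]])
        norm_spec("NO", mu = ps(), sigma = sigma_true)
      else
        norm_spec("SST", mu = ps(), sigma = sigma_true, nu = ps(), tau = ps())
    },
    "Flex[trans]" = norm_spec("SST", mu = mu_true, sigma = ps(),
                              nu = ps(), tau = ps()),
    "Flex[long,trans]" = norm_spec("SST", mu = ps(), sigma = ps(),
                                   nu = ps(), tau = ps()),
    "BCPE" = norm_spec("BCPE", mu = ps(), sigma = ps(), nu = ps(), tau = ps(),
                       offset = 100)
  )
  spec$gaic_k <- gaic_k
  spec$max_iterations <- as.integer(max_iterations)
  spec
}

# counter-based seed splitter: reproducible child seeds independent of which
# conditions are run, kept inside the 32-bit integer range
child_seed <- function(master, pop_index, n_index, r) {
  x <- (master %% 2147483647) * 48271 + pop_index * 1e6 + n_index * 1e4 + r
  as.integer(x %% 2147483629 + 1)
}

#' Run the bias-variance norming study
#'
#' For every population and sample size, generates `R` normative samples
#' (one per replicate, shared across all estimation models fitted to it),
#' fits every requested estimation model, norms the evaluation grid under
#' each fit, and accumulates per-cell bias, variance and RMSE of the
#' estimated normalized z scores.  Fits that fail outright (type-1
#' nonconvergence) are excluded from the outcome computations; fits stopped
#' at the iteration cap (type-2) are included.  Results are deterministic
#' given `seed`, regardless of the subset of conditions run.
#'
#' @param populations list of [build_population()] objects.
#' @param sample_sizes vector of normative sample sizes.
#' @param R replicates per condition.
#' @param I,J evaluation-grid resolution (ages x z values).
#' @param seed master seed; per-replicate seeds are derived from it with a
#'   counter-based splitter.
#' @param models optional character vector restricting the estimation
#'   models; default all applicable ones per population.
#' @param n_knots,gaic_k,max_iterations passed to [build_estimation_spec()].
#' @param out_dir optional directory; if given, `aggregates.csv`,
#'   `cells.csv` and `nonconvergence.csv` are written there.
#' @param progress print per-condition progress lines?
#' @return An object of class `norm_study`: list with tibbles `aggregates`
#'   (one row per condition: mean |bias|, mean variance, mean RMSE,
#'   Monte-Carlo SE of the mean squared error, nonconvergence counts) and
#'   `cells` (per-cell outcomes, long format).
#' @export
run_study <- function(populations = all_populations(),
                      sample_sizes = c(500, 1000, 2000), R = 1000,
                      I = 1000, J = 100, seed = 1, models = NULL,
                      n_knots = 6, gaic_k = 5, max_iterations = 2000,
                      out_dir = NULL, progress = FALSE) {
  if (inherits(populations, "norm_population")) populations <- list(populations)
  agg_rows <- list()
  cell_rows <- list()
  for (pi in seq_along(populations)) {
    pop <- populations[[pi]]
    mods <- applicable_models(pop)
    if (!is.null(models)) mods <- intersect(mods, models)
    if (length(mods) == 0) next
    grid <- build_grid(pop, I = I, J = J)
    zmat <- matrix(grid$z, I, J, byrow = TRUE)
    specs <- lapply(setNames(mods, mods), function(m)
      build_estimation_spec(pop, m, n_knots = n_knots, gaic_k = gaic_k,
                            max_iterations = max_iterations))
    for (ni in seq_along(sample_sizes)) {
      n <- sample_sizes[ni]
      acc <- lapply(setNames(mods, mods), function(m) new_accumulator(I, J))
      fail1 <- setNames(integer(length(mods)), mods)
      fail2 <- setNames(integer(length(mods)), mods)
      for (r in seq_len(R)) {
        d <- sample_norm_data(pop, n, seed = child_seed(seed, pi, ni, r))
        for (m in mods) {
          fit <- fit_norm(d, specs[[m]])
          if (fit$failed) {
            fail1[m] <- fail1[m] + 1L
            next
          }
          if (!fit$converged) fail2[m] <- fail2[m] + 1L
          acc[[m]] <- acc_add(acc[[m]], evaluate_on_grid(fit, grid), zmat)
        }
      }
      for (m in mods) {
        if (acc[[m]]$R == 0L) {
          agg_rows[[length(agg_rows) + 1]] <- tibble(
            population_id = pop$population_id, model = m, n = n, R = R,
            R_effective = 0L, mean_abs_bias = NA_real_,
            mean_variance = NA_real_, mean_rmse = NA_real_,
            mc_se_mse = NA_real_, n_failed = fail1[[m]], n_maxiter = fail2[[m]])
          next
        }
        cells <- acc_cells(acc[[m]], grid)
        ag <- aggregate_outcomes(cells)
        agg_rows[[length(agg_rows) + 1]] <- dplyr::bind_cols(
          tibble(population_id = pop$population_id, model = m, n = n, R = R,
                 R_effective = acc[[m]]$R),
          ag,
          tibble(mc_se_mse = stats::sd(acc[[m]]$repmean_sqerr) /
                   sqrt(acc[[m]]$R),
                 n_failed = fail1[[m]], n_maxiter = fail2[[m]]))
        cell_rows[[length(cell_rows) + 1]] <- dplyr::bind_cols(
          tibble(population_id = pop$population_id, model = m, n = n), cells)
        if (progress)
          message(sprintf("%s | %-20s | n=%4d : |bias|=%.4f var=%.4f rmse=%.4f",
                          pop$population_id, m, n, ag$mean_abs_bias,
                          ag$mean_variance, ag$mean_rmse))
      }
    }
  }
  out <- structure(list(aggregates = dplyr::bind_rows(agg_rows),
                        cells = dplyr::bind_rows(cell_rows),
                        I = I, J = J, seed = seed),
                   class = "norm_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$aggregates, file.path(out_dir, "aggregates.csv"),
                     row.names = FALSE)
    utils::write.csv(out$cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(
      dplyr::select(out$aggregates, "population_id", "model", "n",
                    "n_failed", "n_maxiter"),
      file.path(out_dir, "nonconvergence.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.norm_study <- function(x, ...) {
  cat(sprintf("<norm_study> %d conditions, grid %d x %d, seed %d\n",
              nrow(x$aggregates), x$I, x$J, x$seed))
  print(x$aggregates, n = 20)
  invisible(x)
}

#' Heat-map matrix of per-cell RMSE for one condition
#'
#' @param study a [run_study()] result.
#' @param population_id,model,n condition selectors.
#' @return An I x J matrix of RMSE values (ages by z).
#' @export
rmse_heatmap_matrix <- function(study, population_id, model, n) {
  cells <- dplyr::filter(study$cells, .data$population_id == !!population_id,
                         .data$model == !!model, .data$n == !!n)
  if (nrow(cells) == 0) abort("no such condition in the study result",
                              class = "nt_error_domain")
  I <- max(cells$age_index); J <- max(cells$z_index)
  m <- matrix(NA_real_, I, J)
  m[cbind(cells$age_index, cells$z_index)] <- cells$rmse
  m
}

#' Plot study outcomes
#'
#' Bar chart of one aggregate outcome per estimation model, faceted by
#' population and sample size.
#'
#' @param object a `norm_study` result.
#' @param outcome one of `"mean_abs_bias"`, `"mean_variance"`, `"mean_rmse"`.
#' @param ... unused.
#' @export
autoplot.norm_study <- function(object, outcome = "mean_rmse", ...) {
  ggplot2::ggplot(object$aggregates,
                  ggplot2::aes(.data$model, .data[[outcome]])) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$population_id),
                        cols = ggplot2::vars(.data$n)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = outcome) +
    ggplot2::theme_minimal()
}

#' Heat map of per-cell RMSE over the age-by-z grid
#'
#' @param study a [run_study()] result.
#' @param population_id,model,n condition selectors.
#' @export
plot_rmse_heatmap <- function(study, population_id, model, n) {
  cells <- dplyr::filter(study$cells, .data$population_id == !!population_id,
                         .data$model == !!model, .data$n == !!n)
  ggplot2::ggplot(cells, ggplot2::aes(.data$age, .data$z, fill = .data$rmse)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "age", y = "population z", fill = "RMSE") +
    ggplot2::theme_minimal()
}
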