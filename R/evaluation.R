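# Outcome measures: bias, variance and RMSE of estimated normalized z
# scores per (age, score) cell across Monte-Carlo replicates.

#' Build an age-by-z evaluation grid for a population
#'
#' Lays out `I` equally spaced ages over the population's age range and `J`
#' equally spaced population z values over `[-3, +3]` (both inclusive of the
#' endpoints), and computes the population score at every cell, i.e. the
#' score whose conditional percentile equals `pnorm(z)`.  Scores outside
#' three population SDs are excluded by construction, as such extreme normed
#' scores are not reported in practice.
#'
#' @param pop a [build_population()] object.
#' @param I number of age values (default 1000).
#' @param J number of z values (default 100).
#' @param z_range range of population z values.
#' @return An object of class `norm_grid`: list with `ages` (length I),
#'   `z` (length J), `scores` (I x J matrix, strictly increasing along z),
#'   and the population.
#' @export
build_grid <- function(pop, I = 1000, J = 100, z_range = c(-3, 3)) {
  if (I < 2 || J < 2) abort("I and J must be >= 2", class = "nt_error_domain")
  ages <- seq(pop$age_range[1], pop$age_range[2], length.out = I)
  z <- seq(z_range[1], z_range[2], length.out = J)
  par <- population_params(pop, ages)
  scores <- vapply(z, function(zj) {
    fam_quantile(pop$family, pnorm(zj), par$mu, par$sigma, par$nu, par$tau)
  }, numeric(I))
  structure(list(ages = ages, z = z, scores = scores, population = pop),
            class = "norm_grid")
}

#' @export
print.norm_grid <- function(x, ...) {
  cat(sprintf("<norm_grid> %d ages x %d z values, population %s\n",
              length(x$ages), length(x$z), x$population$population_id))
  invisible(x)
}

#' @export
as_tibble.norm_grid <- function(x, ...) {
  tidyr::expand_grid(age_index = seq_along(x$ages),
                     z_index = seq_along(x$z)) |>
    dplyr::mutate(age = x$ages[.data$age_index], z = x$z[.data$z_index],
                  score = x$scores[cbind(.data$age_index, .data$z_index)])
}

#' Estimated z scores of a fit over an evaluation grid
#'
#' Norms every grid score under the fitted model, returning the clamped
#' estimated z values as an I x J matrix.
#'
#' @param fit a usable `normfit` (or a `norm_population`, e.g. as an oracle).
#' @param grid a [build_grid()] object.
#' @export
evaluate_on_grid <- function(fit, grid) {
  if (inherits(fit, "normfit") && fit$failed)
    abort("cannot evaluate a failed fit", class = "nt_error_failed_fit")
  par <- predict_params(fit, grid$ages)
  off <- model_offset(fit)
  fam <- model_family(fit)
  J <- length(grid$z)
  out <- matrix(NA_real_, length(grid$ages), J)
  for (j in seq_len(J)) {
    p <- fam_cdf(fam, grid$scores[, j] + off, par$mu, par$sigma, par$nu, par$tau)
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    out[, j] <- pmin(pmax(qnorm(p), -5), 5)
  }
  out
}

#' Bias, variance and RMSE of one grid cell
#'
#' The three outcome measures across replicates, each with `1/R`
#' normalization: `bias = mean(zhat) - z`,
#' `variance = mean((zhat - mean(zhat))^2)`,
#' `rmse = sqrt(mean((zhat - z)^2))`, so that
#' `rmse^2 = variance + bias^2` holds as an identity.
#'
#' @param zhat vector of replicate z estimates for one cell.
#' @param z the population z of that cell.
#' @return A one-row tibble with `bias`, `variance`, `rmse`, `R`.
#' @export
cell_outcomes <- function(zhat, z) {
  if (length(zhat) == 0)
    abort("no replicate estimates supplied", class = "nt_error_domain")
  R <- length(zhat)
  zbar <- mean(zhat)
  tibble(bias = zbar - z,
         variance = mean((zhat - zbar)^2),
         rmse = sqrt(mean((zhat - z)^2)),
         R = R)
}

#' Aggregate per-cell outcomes over the grid
#'
#' Unweighted means over all cells of |bias|, variance and RMSE -- the
#' study's condition-level summaries.
#'
#' @param cells tibble of per-cell outcomes (columns `bias`, `variance`,
#'   `rmse`), e.g. the `cells` component of a study result.
#' @return A one-row tibble with `mean_abs_bias`, `mean_variance`,
#'   `mean_rmse`.
#' @export
aggregate_outcomes <- function(cells) {
  tibble(mean_abs_bias = mean(abs(cells$bias)),
         mean_variance = mean(cells$variance),
         mean_rmse = mean(cells$rmse))
}

# streaming accumulator over replicates: keeps per-cell sums rather than all
# replicate draws
new_accumulator <- function(I, J) {
  list(s1 = matrix(0, I, J), s2 = matrix(0, I, J), sse = matrix(0, I, J),
       R = 0L, repmean_sqerr = numeric(0))
}

acc_add <- function(acc, zhat, zmat) {
  acc$s1 <- acc$s1 + zhat
  acc$s2 <- acc$s2 + zhat^2
  sq <- (zhat - zmat)^2
  acc$sse <- acc$sse + sq
  acc$R <- acc$R + 1L
  acc$repmean_sqerr <- c(acc$repmean_sqerr, mean(sq))
  acc
}

acc_cells <- function(acc, grid) {
  R <- acc$R
  zbar <- acc$s1 / R
  zmat <- matrix(grid$z, length(grid$ages), length(grid$z), byrow = TRUE)
  bias <- zbar - zmat
  mse <- acc$sse / R
  variance <- pmax(mse - bias^2, 0)
  rmse <- sqrt(mse)
  tidyr::expand_grid(age_index = seq_along(grid$ages),
                     z_index = seq_along(grid$z)) |>
    dplyr::mutate(age = grid$ages[.data$age_index], z = grid$z[.data$z_index],
                  bias = bias[cbind(.data$age_index, .data$z_index)],
                  variance = variance[cbind(.data$age_index, .data$z_index)],
                  rmse = rmse[cbind(.data$age_index, .data$z_index)],
                  R_effective = R)
}
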