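# Population models: the factorial cube of data-generating truths over ages
# 5-21, and normative-sample generation from them.

# Default flexible population curves, on the link scale, as polynomials in
# the rescaled age t = (age - 13)/8 (so t runs over [-1, 1] on ages 5-21).
# They emulate a developmental ability test: the mean rises steeply in
# childhood and decelerates toward adulthood; the spread varies mildly with
# age; scores are left-skewed (nu < 1); tails are moderately heavy.  The
# degrees match the flexible-model structure of the study: 4 for mu and
# ln(nu), 2 for ln(sigma), 1 for ln(tau - 2).
default_curves <- function() {
  list(mu = c(24, 11.5, -3.5, 1.0, 0.8),
       lsigma = c(1.5, 0.18, -0.10),
       lnu = c(-0.35, 0.15, -0.10, -0.08, 0.05),
       ltau = c(1.3, -0.3))
}

polyval <- function(coefs, t) {
  out <- rep(coefs[length(coefs)], length(t))
  for (j in rev(seq_len(length(coefs) - 1))) out <- out * t + coefs[j]
  out
}

age_to_t <- function(age, age_range) {
  (age - mean(age_range)) / (diff(age_range) / 2)
}

#' Build a population model from restriction flags
#'
#' Constructs one of the factorial population models: starting from a fully
#' flexible data-generating truth (skew Student *t* whose mean, spread,
#' skewness and tail weight all vary smoothly with age), each flag replaces
#' part of it by its restricted variant.  `linear_mu` replaces the mean
#' curve by its least-squares line over the age range; `homoscedastic` fixes
#' sigma at its age-average; `normal` switches the family to the exact
#' normal distribution (the nu = 1, tau = Inf limit of the skew *t*).  The
#' `2^3 = 8` flag combinations give the full population cube, labelled
#' `NL/Li - He/Ho NN/No` (nonlinear/linear, hetero/homoscedastic,
#' nonnormal/normal).
#'
#' @param linear_mu,homoscedastic,normal restriction flags.
#' @param curves optional override of the flexible curves: a list with
#'   components `mu`, `lsigma`, `lnu`, `ltau`, each a vector of polynomial
#'   coefficients (increasing powers) in the rescaled age
#'   `t = (age - mean(range)) / (width/2)`.
#' @param age_range ages covered by the model.
#' @return An object of class `norm_population`.
#' @examples
#' pop <- build_population()                 # fully flexible (NL-HeNN)
#' pop$population_id
#' build_population(TRUE, TRUE, TRUE)$population_id  # most restricted
#' @export
build_population <- function(linear_mu = FALSE, homoscedastic = FALSE,
                             normal = FALSE, curves = default_curves(),
                             age_range = c(5, 21)) {
  cv <- curves
  tgrid <- seq(-1, 1, length.out = 401)
  if (linear_mu) {
    muv <- polyval(cv$mu, tgrid)
    cv$mu <- unname(coef(lm(muv ~ tgrid)))
  }
  if (homoscedastic) {
    cv$lsigma <- log(mean(exp(polyval(cv$lsigma, tgrid))))
  }
  family <- if (normal) "NO" else "SST"
  if (normal) cv$lnu <- cv$ltau <- NULL
  id <- paste0(if (linear_mu) "Li" else "NL", "-",
               if (homoscedastic) "Ho" else "He",
               if (normal) "No" else "NN")
  structure(list(family = family, curves = cv, age_range = age_range,
                 flags = c(linear_mu = linear_mu, homoscedastic = homoscedastic,
                           normal = normal),
                 population_id = id),
            class = "norm_population")
}

#' All eight factorial population models
#'
#' @inheritParams build_population
#' @return A named list of the 8 [build_population()] objects, ordered from
#'   the fully flexible model (`NL-HeNN`) to the most restricted (`Li-HoNo`).
#' @export
all_populations <- function(curves = default_curves(), age_range = c(5, 21)) {
  flags <- expand.grid(normal = c(FALSE, TRUE), homoscedastic = c(FALSE, TRUE),
                       linear_mu = c(FALSE, TRUE), KEEP.OUT.ATTRS = FALSE)
  pops <- purrr::pmap(flags, function(normal, homoscedastic, linear_mu) {
    build_population(linear_mu, homoscedastic, normal, curves, age_range)
  })
  names(pops) <- vapply(pops, `[[`, "", "population_id")
  pops
}

#' @export
print.norm_population <- function(x, ...) {
  cat("<norm_population>", x$population_id, paste0("(", x$family, ")"),
      "ages", x$age_range[1], "-", x$age_range[2], "\n")
  invisible(x)
}

#' Population distributional parameters at given ages
#'
#' @param pop a [build_population()] object.
#' @param age ages within the population's age range.
#' @return A tibble with columns `age`, `mu`, `sigma`, `nu`, `tau`.
#' @export
population_params <- function(pop, age) {
  stopifnot(inherits(pop, "norm_population"))
  if (any(age < pop$age_range[1] - 1e-9 | age > pop$age_range[2] + 1e-9))
    abort("age outside the population's age range", class = "nt_error_domain")
  t <- age_to_t(age, pop$age_range)
  tibble(age = age,
         mu = polyval(pop$curves$mu, t),
         sigma = exp(polyval(pop$curves$lsigma, t)),
         nu = if (pop$family == "NO") NA_real_ else exp(polyval(pop$curves$lnu, t)),
         tau = if (pop$family == "NO") NA_real_ else 2 + exp(polyval(pop$curves$ltau, t)))
}

#' @export
predict_params.norm_population <- function(object, ages, ...) {
  population_params(object, ages)
}

# run an expression with a private, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a normative sample from a population model
#'
#' Ages are fixed at `n` evenly spaced values spanning the population age
#' range (they are a design choice, not sampled); one score is drawn from
#' the conditional distribution at each age by inverse-cdf sampling.
#'
#' @param pop a [build_population()] object.
#' @param n sample size (>= 2).
#' @param seed integer seed; draws are reproducible given the seed and do
#'   not disturb the caller's RNG state.
#' @return A tibble with columns `age`, `score`; attributes `population_id`
#'   and `seed` record provenance.
#' @export
sample_norm_data <- function(pop, n, seed) {
  stopifnot(inherits(pop, "norm_population"))
  if (n < 2) abort("n must be >= 2", class = "nt_error_domain")
  ages <- seq(pop$age_range[1], pop$age_range[2], length.out = n)
  par <- population_params(pop, ages)
  u <- with_seed(seed, runif(n))
  scores <- fam_quantile(pop$family, u, par$mu, par$sigma, par$nu, par$tau)
  out <- tibble(age = ages, score = scores)
  attr(out, "population_id") <- pop$population_id
  attr(out, "seed") <- seed
  out
}

#' Population score at a given normalized z
#'
#' The raw score whose conditional percentile at `age` equals `pnorm(z)`:
#' the inverse of the population's normalization.  Vectorized over `age`
#' and `z`.
#'
#' @param pop a [build_population()] object.
#' @param age ages within range.
#' @param z population normalized z scores.
#' @export
population_score_at_z <- function(pop, age, z) {
  r <- recycle_args(age = age, z = z)
  par <- population_params(pop, r$age)
  fam_quantile(pop$family, pnorm(r$z), par$mu, par$sigma, par$nu, par$tau)
}

# population config <-> JSON (round-trippable)
#' Read and write population-model configurations as JSON
#'
#' @param pop a [build_population()] object.
#' @param path file path.
#' @export
write_population <- function(pop, path) {
  jsonlite::write_json(
    list(flags = as.list(pop$flags), curves = pop$curves,
         age_range = pop$age_range),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  fl <- cfg$flags
  # stored curves are post-restriction; the restrictions are idempotent, so
  # rebuilding through build_population() reproduces the same model
  curves <- modifyList(default_curves(), Filter(Negate(is.null), cfg$curves))
  build_population(fl$linear_mu, fl$homoscedastic, fl$normal,
                   curves = curves, age_range = cfg$age_range)
}
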