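# Distribution machinery: skew Student t (SST), Box-Cox Power Exponential
# (BCPE) and the normal, with the link functions used for norming models.

# ---- skew Student t ---------------------------------------------------------

# The SST is the Fernandez & Steel two-piece skew t, rescaled so that mu is
# the mean and sigma the standard deviation of the distribution (tau > 2 is
# required for the variance to exist).  Writing t_tau for the standard
# Student t density, the "raw" skew variate Z has density
#   f(z) = 2/(nu + 1/nu) * [ t_tau(z/nu) 1{z>=0} + t_tau(nu z) 1{z<0} ],
# and the SST variate is X = mu + sigma * (Z - E Z) / sd(Z).
# With nu = 1 and tau -> Inf this is the standard normal.

# first absolute moment of the t distribution and the implied mean/var of Z
sst_zmoments <- function(nu, tau) {
  m1 <- 2 * sqrt(tau) * exp(lgamma((tau + 1) / 2) - lgamma(tau / 2)) /
    (sqrt(pi) * (tau - 1))
  m2 <- tau / (tau - 2)
  mz <- m1 * (nu - 1 / nu)
  vz <- m2 * (nu^3 + 1 / nu^3) / (nu + 1 / nu) - mz^2
  list(mean = mz, sd = sqrt(vz))
}

check_sst <- function(sigma, nu, tau) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    abort("SST requires sigma > 0", class = "nt_error_domain")
  if (any(!is.finite(nu)) || any(nu <= 0))
    abort("SST requires nu > 0", class = "nt_error_domain")
  if (any(!is.finite(tau)) || any(tau <= 2))
    abort("SST requires tau > 2", class = "nt_error_domain")
}

#' Skew Student t distribution (mean-SD parameterization)
#'
#' Density, distribution function, quantile function and random generation
#' for the skew Student *t* distribution (SST), the Fernandez-Steel two-piece
#' skew *t* rescaled so that `mu` is the mean and `sigma` the standard
#' deviation of the distribution.  `nu > 0` controls skewness (`nu = 1` is
#' symmetric, `nu < 1` skews left) and `tau > 2` controls tail weight; as
#' `nu -> 1` and `tau -> Inf` the SST converges to the normal distribution.
#'
#' @param x,q vector of quantiles (raw-score units).
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param mu mean.
#' @param sigma standard deviation, `> 0`.
#' @param nu skewness parameter, `> 0`.
#' @param tau tail-weight parameter, `> 2`.
#' @param log logical; return the log density?
#'
#' @return `dsst` the density, `psst` the cdf, `qsst` the quantile, `rsst`
#'   a numeric vector of draws.
#'
#' @examples
#' dsst(0, mu = 0, sigma = 1, nu = 1, tau = 1e6)  # ~ dnorm(0)
#' psst(qsst(0.25, mu = 10, sigma = 3, nu = 0.7, tau = 5),
#'      mu = 10, sigma = 3, nu = 0.7, tau = 5)
#' @export
dsst <- function(x, mu = 0, sigma = 1, nu = 1, tau = 10, log = FALSE) {
  check_sst(sigma, nu, tau)
  r <- recycle_args(x = x, mu = mu, sigma = sigma, nu = nu, tau = tau)
  zm <- sst_zmoments(r$nu, r$tau)
  z <- zm$mean + zm$sd * (r$x - r$mu) / r$sigma
  neg <- !is.na(z) & z < 0
  ld <- z
  ld[neg] <- dt(r$nu[neg] * z[neg], df = r$tau[neg], log = TRUE)
  ld[!neg] <- dt(z[!neg] / r$nu[!neg], df = r$tau[!neg], log = TRUE)
  out <- log(2 / (r$nu + 1 / r$nu)) + ld + log(zm$sd) - log(r$sigma)
  if (log) out else exp(out)
}

#' @rdname dsst
#' @export
psst <- function(q, mu = 0, sigma = 1, nu = 1, tau = 10) {
  check_sst(sigma, nu, tau)
  r <- recycle_args(q = q, mu = mu, sigma = sigma, nu = nu, tau = tau)
  zm <- sst_zmoments(r$nu, r$tau)
  z <- zm$mean + zm$sd * (r$q - r$mu) / r$sigma
  out <- numeric(length(z))
  neg <- !is.na(z) & z < 0
  out[neg] <- 2 / (1 + r$nu[neg]^2) * pt(r$nu[neg] * z[neg], df = r$tau[neg])
  out[!neg] <- 1 / (1 + r$nu[!neg]^2) +
    2 * r$nu[!neg]^2 / (1 + r$nu[!neg]^2) * (pt(z[!neg] / r$nu[!neg], df = r$tau[!neg]) - 0.5)
  out[is.na(z)] <- NA_real_
  out
}

#' @rdname dsst
#' @export
qsst <- function(p, mu = 0, sigma = 1, nu = 1, tau = 10) {
  check_sst(sigma, nu, tau)
  if (any(p <= 0 | p >= 1, na.rm = TRUE))
    abort("probabilities must lie strictly in (0, 1)", class = "nt_error_domain")
  r <- recycle_args(p = p, mu = mu, sigma = sigma, nu = nu, tau = tau)
  zm <- sst_zmoments(r$nu, r$tau)
  p0 <- 1 / (1 + r$nu^2)
  z <- numeric(length(r$p))
  lo <- !is.na(r$p) & r$p < p0
  z[lo] <- qt(r$p[lo] * (1 + r$nu[lo]^2) / 2, df = r$tau[lo]) / r$nu[lo]
  z[!lo] <- r$nu[!lo] *
    qt((r$p[!lo] - p0[!lo]) * (1 + r$nu[!lo]^2) / (2 * r$nu[!lo]^2) + 0.5, df = r$tau[!lo])
  z[is.na(r$p)] <- NA_real_
  r$mu + r$sigma * (z - zm$mean) / zm$sd
}

#' @rdname dsst
#' @export
rsst <- function(n, mu = 0, sigma = 1, nu = 1, tau = 10) {
  qsst(runif(n), mu = mu, sigma = sigma, nu = nu, tau = tau)
}

# ---- power exponential kernel (standardized, sd = 1) ------------------------

pe_scale <- function(tau) sqrt(exp(lgamma(1 / tau) - lgamma(3 / tau)))

dpe_std <- function(t, tau, log = FALSE) {
  c0 <- pe_scale(tau)
  ld <- log(tau) - log(2 * c0) - lgamma(1 / tau) - abs(t / c0)^tau
  if (log) ld else exp(ld)
}

ppe_std <- function(t, tau) {
  c0 <- pe_scale(tau)
  0.5 * (1 + sign(t) * pgamma(abs(t / c0)^tau, shape = 1 / tau))
}

qpe_std <- function(p, tau) {
  c0 <- pe_scale(tau)
  sign(p - 0.5) * c0 * qgamma(abs(2 * p - 1), shape = 1 / tau)^(1 / tau)
}

# ---- Box-Cox Power Exponential ----------------------------------------------

check_bcpe <- function(mu, sigma, tau) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    abort("BCPE requires mu > 0", class = "nt_error_domain")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    abort("BCPE requires sigma > 0", class = "nt_error_domain")
  if (any(!is.finite(tau)) || any(tau <= 0))
    abort("BCPE requires tau > 0", class = "nt_error_domain")
}

bcpe_trunc <- function(sigma, nu, tau) {
  # mass of the power-exponential kernel retained by the positivity constraint
  ifelse(abs(nu) < 1e-12, 1, ppe_std(1 / (sigma * abs(nu)), tau))
}

#' Box-Cox Power Exponential distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Box-Cox Power Exponential (BCPE) distribution on positive scores.
#' A Box-Cox transform of `x/mu` with power `nu` is modelled as a
#' standardized power-exponential variate with kurtosis parameter `tau`
#' (`tau = 2` gives a normal kernel).  `mu > 0` is (approximately) the
#' median, `sigma` the approximate coefficient of variation.  The density is
#' normalized exactly on `(0, Inf)`, i.e. the truncation induced by the
#' positivity constraint is accounted for.
#'
#' @inheritParams dsst
#' @param mu location (approximate median), `> 0`.
#' @param sigma scale (approximate coefficient of variation), `> 0`.
#' @param nu skewness (Box-Cox power), any real.
#' @param tau kurtosis parameter, `> 0`.
#' @export
dbcpe <- function(x, mu = 1, sigma = 0.1, nu = 1, tau = 2, log = FALSE) {
  check_bcpe(mu, sigma, tau)
  r <- recycle_args(x = x, mu = mu, sigma = sigma, nu = nu, tau = tau)
  z <- bcpe_z(r$x, r$mu, r$sigma, r$nu)
  ld <- (r$nu - 1) * log(r$x / r$mu) - log(r$mu) - log(r$sigma) +
    dpe_std(z, r$tau, log = TRUE) - log(bcpe_trunc(r$sigma, r$nu, r$tau))
  ld[!is.na(r$x) & r$x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

bcpe_z <- function(y, mu, sigma, nu) {
  ifelse(abs(nu) < 1e-12,
         log(pmax(y, .Machine$double.xmin) / mu) / sigma,
         ((pmax(y, .Machine$double.xmin) / mu)^nu - 1) / (nu * sigma))
}

#' @rdname dbcpe
#' @export
pbcpe <- function(q, mu = 1, sigma = 0.1, nu = 1, tau = 2) {
  check_bcpe(mu, sigma, tau)
  r <- recycle_args(q = q, mu = mu, sigma = sigma, nu = nu, tau = tau)
  z <- bcpe_z(r$q, r$mu, r$sigma, r$nu)
  ctr <- bcpe_trunc(r$sigma, r$nu, r$tau)
  out <- ifelse(r$nu > 1e-12,
                (ppe_std(z, r$tau) - (1 - ctr)) / ctr,
                ppe_std(z, r$tau) / ctr)
  out[!is.na(r$q) & r$q <= 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' @rdname dbcpe
#' @export
qbcpe <- function(p, mu = 1, sigma = 0.1, nu = 1, tau = 2) {
  check_bcpe(mu, sigma, tau)
  if (any(p <= 0 | p >= 1, na.rm = TRUE))
    abort("probabilities must lie strictly in (0, 1)", class = "nt_error_domain")
  r <- recycle_args(p = p, mu = mu, sigma = sigma, nu = nu, tau = tau)
  ctr <- bcpe_trunc(r$sigma, r$nu, r$tau)
  pz <- ifelse(r$nu > 1e-12, r$p * ctr + (1 - ctr), r$p * ctr)
  z <- qpe_std(pz, r$tau)
  ifelse(abs(r$nu) < 1e-12,
         r$mu * exp(r$sigma * z),
         r$mu * (pmax(1 + r$nu * r$sigma * z, 0))^(1 / r$nu))
}

#' @rdname dbcpe
#' @export
rbcpe <- function(n, mu = 1, sigma = 0.1, nu = 1, tau = 2) {
  qbcpe(runif(n), mu = mu, sigma = sigma, nu = nu, tau = tau)
}

# ---- family dispatch --------------------------------------------------------

nt_families <- c("SST", "BCPE", "NO")

family_param_names <- function(family) {
  switch(family,
         NO = c("mu", "sigma"),
         SST = , BCPE = c("mu", "sigma", "nu", "tau"),
         abort(paste("unknown family:", family), class = "nt_error_domain"))
}

fam_density <- function(family, x, mu, sigma, nu = NULL, tau = NULL, log = FALSE) {
  switch(family,
         SST = dsst(x, mu, sigma, nu, tau, log = log),
         BCPE = dbcpe(x, mu, sigma, nu, tau, log = log),
         NO = dnorm(x, mu, sigma, log = log))
}

fam_cdf <- function(family, q, mu, sigma, nu = NULL, tau = NULL) {
  switch(family,
         SST = psst(q, mu, sigma, nu, tau),
         BCPE = pbcpe(q, mu, sigma, nu, tau),
         NO = pnorm(q, mu, sigma))
}

fam_quantile <- function(family, p, mu, sigma, nu = NULL, tau = NULL) {
  switch(family,
         SST = qsst(p, mu, sigma, nu, tau),
         BCPE = qbcpe(p, mu, sigma, nu, tau),
         NO = qnorm(p, mu, sigma))
}

# inverse-cdf sampling so every family shares one uniform stream
fam_sample <- function(family, n, mu, sigma, nu = NULL, tau = NULL) {
  fam_quantile(family, runif(n), mu, sigma, nu, tau)
}

#' Validate and package distributional parameters
#'
#' Bundles the four distributional parameters of a conditional score
#' distribution, checking the family's domain constraints (SST: `sigma > 0`,
#' `nu > 0`, `tau > 2`; BCPE: `mu, sigma, tau > 0`; normal: `sigma > 0`).
#'
#' @param family `"SST"`, `"BCPE"` or `"NO"` (normal).
#' @param mu,sigma,nu,tau parameter values; `nu`, `tau` are ignored for the
#'   normal family.
#' @return A one-row tibble with columns `family`, `mu`, `sigma`, `nu`, `tau`.
#' @export
dist_params <- function(family, mu, sigma, nu = NA_real_, tau = NA_real_) {
  family <- match.arg(family, nt_families)
  switch(family,
         SST = check_sst(sigma, nu, tau),
         BCPE = check_bcpe(mu, sigma, tau),
         NO = if (any(sigma <= 0)) abort("normal requires sigma > 0",
                                         class = "nt_error_domain"))
  tibble(family = family, mu = mu, sigma = sigma,
         nu = if (family == "NO") NA_real_ else nu,
         tau = if (family == "NO") NA_real_ else tau)
}

# ---- links ------------------------------------------------------------------

#' Link functions for distributional parameters
#'
#' `link_apply` maps a parameter value to the unconstrained (link) scale,
#' `link_invert` maps back.  Available links: `"identity"`, `"log"` and
#' `"logshift2"` (`log(tau - 2)`, the SST tail-parameter link).
#' `family_links` returns each family's default link set: SST uses
#' identity/log/log/logshift2 for mu/sigma/nu/tau, BCPE uses
#' identity/log/identity/log, the normal identity/log.
#'
#' @param link link name.
#' @param value parameter value (`link_apply`) or link-scale value
#'   (`link_invert`).
#' @param family family name.
#' @examples
#' link_apply("logshift2", 3)   # 0
#' link_invert("log", 0)        # 1
#' @export
link_apply <- function(link, value) {
  switch(link,
         identity = value,
         log = {
           if (any(value <= 0, na.rm = TRUE))
             abort("log link requires positive values", class = "nt_error_domain")
           log(value)
         },
         logshift2 = {
           if (any(value <= 2, na.rm = TRUE))
             abort("logshift2 link requires values > 2", class = "nt_error_domain")
           log(value - 2)
         },
         abort(paste("unknown link:", link), class = "nt_error_domain"))
}

#' @rdname link_apply
#' @export
link_invert <- function(link, value) {
  switch(link,
         identity = value,
         log = exp(value),
         logshift2 = 2 + exp(value),
         abort(paste("unknown link:", link), class = "nt_error_domain"))
}

#' @rdname link_apply
#' @export
family_links <- function(family) {
  family <- match.arg(family, nt_families)
  switch(family,
         SST = c(mu = "identity", sigma = "log", nu = "log", tau = "logshift2"),
         BCPE = c(mu = "identity", sigma = "log", nu = "identity", tau = "log"),
         NO = c(mu = "identity", sigma = "log"))
}

# ---- small utilities --------------------------------------------------------

recycle_args <- function(...) {
  args <- list(...)
  n <- max(vapply(args, length, 1L))
  lapply(args, rep_len, length.out = n)
}
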