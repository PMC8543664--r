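# Penalized maximum-likelihood fitting of a distributional regression model:
# each distributional parameter is modelled, through its link, as a term
# function of age.  Estimation is by outer backfitting across parameters,
# updating one parameter's coefficients by penalized iteratively reweighted
# least squares (score and curvature of the log-likelihood with respect to
# the linear predictor) while holding the others fixed.  Smoothing
# parameters of "auto" P-spline terms are profiled each cycle by minimizing
# the GAIC of the weighted working model.

#' Specify a distributional-regression norming model
#'
#' A model specification pairs a response family (`"SST"`, `"BCPE"` or
#' `"NO"`) with one term per distributional parameter (see
#' [term_intercept()] and friends), the family's default links, an optional
#' score offset (the BCPE estimation model in the norming study is fitted on
#' scores + 100, and all fitted quantiles are shifted back), and fitting
#' controls.
#'
#' @param family response family.
#' @param mu,sigma,nu,tau `nt_term` objects; `nu`/`tau` are ignored for the
#'   normal family.
#' @param offset value added to the scores before fitting (predicted
#'   quantiles are shifted back by the same amount).
#' @param max_iterations cap on outer backfitting cycles; a fit that hits it
#'   is returned with `converged = FALSE` but remains usable.
#' @param tolerance convergence threshold on the absolute change in global
#'   deviance between outer cycles.
#' @param gaic_k GAIC penalty used to select `"auto"` smoothing parameters
#'   (`5` in the norming study; `log(n)` gives BIC-selected smoothing).
#' @return An object of class `nt_spec`.
#' @export
norm_spec <- function(family = c("SST", "BCPE", "NO"),
                      mu = term_intercept(), sigma = term_intercept(),
                      nu = term_intercept(), tau = term_intercept(),
                      offset = 0, max_iterations = 2000, tolerance = 1e-3,
                      gaic_k = 5) {
  family <- match.arg(family)
  if (max_iterations < 1)
    abort("max_iterations must be >= 1", class = "nt_error_domain")
  terms <- list(mu = mu, sigma = sigma, nu = nu, tau = tau)
  terms <- terms[family_param_names(family)]
  for (tm in terms)
    if (!inherits(tm, "nt_term"))
      abort("terms must be built with term_*() constructors",
            class = "nt_error_domain")
  structure(list(family = family, links = family_links(family), terms = terms,
                 offset = offset, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, gaic_k = gaic_k),
            class = "nt_spec")
}

#' @export
print.nt_spec <- function(x, ...) {
  cat("<nt_spec>", x$family,
      if (x$offset != 0) paste0("(offset ", x$offset, ")"), "\n")
  for (k in names(x$terms)) {
    cat(sprintf("  %-6s [%s link] ", k, x$links[[k]]))
    print(x$terms[[k]])
  }
  invisible(x)
}

# clamp linear predictors of exponential links so inversion cannot overflow
ETA_CLAMP <- 30

linkinv_eta <- function(link, eta) {
  if (link != "identity") eta <- pmin(pmax(eta, -ETA_CLAMP), ETA_CLAMP)
  link_invert(link, eta)
}

# pointwise log-likelihood given the linear predictors (list over parameters)
ll_pointwise <- function(family, links, y, etas) {
  th <- lapply(names(etas), function(k) linkinv_eta(links[[k]], etas[[k]]))
  names(th) <- names(etas)
  fam_density(family, y, th$mu, th$sigma, th$nu, th$tau, log = TRUE)
}

#' Fit a norming model to a normative sample
#'
#' Fits the distributional regression described by `spec` to a normative
#' sample by penalized maximum likelihood.  Numerical breakdown (the model
#' "could not be estimated") is reported through `failed = TRUE` rather than
#' an error; a fit stopped by the iteration cap has `converged = FALSE` but
#' carries coefficients and is included in downstream evaluation, mirroring
#' how such fits are treated in the simulation study.
#'
#' @param data a data frame with numeric columns `age` and `score`.
#' @param spec an [norm_spec()] object.
#' @return An object of class `normfit`; see [glance.normfit()] for the
#'   fit summaries and [predict_params()] for fitted parameter curves.
#' @examples
#' pop <- build_population(normal = TRUE, homoscedastic = TRUE, linear_mu = TRUE)
#' d <- sample_norm_data(pop, n = 300, seed = 7)
#' f <- fit_norm(d, norm_spec("NO", mu = term_linear()))
#' glance(f)
#' @export
fit_norm <- function(data, spec) {
  stopifnot(inherits(spec, "nt_spec"))
  age <- as.numeric(data$age)
  y <- as.numeric(data$score) + spec$offset
  n <- length(y)
  if (n == 0) abort("empty sample", class = "nt_error_domain")
  if (spec$family == "BCPE" && any(y <= 0))
    abort("BCPE requires positive scores after the offset",
          class = "nt_error_domain")

  pk <- family_param_names(spec$family)
  built <- lapply(spec$terms, build_term, ages = age)
  X <- lapply(built, `[[`, "X")
  P <- lapply(built, `[[`, "P")
  lambda <- lapply(built, `[[`, "lambda")

  # fewer observations than coefficients: the model cannot be estimated
  p_total <- sum(vapply(X, ncol, 1L))
  fit <- if (n < p_total) NULL else tryCatch(
    rs_backfit(spec, y, X, P, lambda, n),
    error = function(e) NULL
  )
  if (is.null(fit) || !all(vapply(fit$beta, function(b) all(is.finite(b)), TRUE))) {
    return(structure(list(spec = spec, failed = TRUE, converged = FALSE,
                          coefficients = NULL, n = n),
                     class = "normfit"))
  }

  structure(list(
    spec = spec, family = spec$family, links = spec$links,
    coefficients = fit$beta,
    term_refs = lapply(built, `[[`, "ref"),
    lambda = fit$lambda, edf = fit$edf, edf_total = sum(unlist(fit$edf)),
    loglik = fit$loglik, deviance = -2 * fit$loglik,
    iterations = fit$iterations, converged = fit$converged, failed = FALSE,
    n = n, offset = spec$offset, age_range = range(age)
  ), class = "normfit")
}

# initial coefficients: least squares for mu, residual SD for sigma's
# intercept, link-zero elsewhere (BCPE tau starts at 2, the normal kernel)
init_coefs <- function(spec, y, X, pk) {
  beta <- list()
  qr_mu <- qr(X$mu)
  beta$mu <- qr.coef(qr_mu, y)
  beta$mu[is.na(beta$mu)] <- 0
  res <- y - X$mu %*% beta$mu
  s0 <- max(sd(res), 1e-3)
  if (spec$family == "BCPE") s0 <- s0 / max(mean(y), 1e-6)  # approx CV scale
  beta$sigma <- c(log(s0), rep(0, ncol(X$sigma) - 1))
  if ("nu" %in% pk) {
    nu0 <- if (spec$family == "BCPE") 1 else 0  # identity vs log link
    beta$nu <- c(nu0, rep(0, ncol(X$nu) - 1))
  }
  if ("tau" %in% pk) {
    tau0 <- if (spec$family == "BCPE") log(2) else 0  # tau = 2 vs tau = 3
    beta$tau <- c(tau0, rep(0, ncol(X$tau) - 1))
  }
  beta
}

# spline bases carry no constant column; replace "intercept at position 1"
# inits by a constant fitted through the basis
spread_const <- function(Xk, const) {
  # coefficients all equal to const reproduce a constant curve because the
  # B-spline rows sum to one
  rep(const, ncol(Xk))
}

rs_backfit <- function(spec, y, X, P, lambda, n) {
  pk <- names(X)
  beta <- init_coefs(spec, y, X, pk)
  # fix up inits for bases without a constant first column (P-splines)
  for (k in pk) {
    if (is.null(P[[k]])) next
    beta[[k]] <- spread_const(X[[k]], beta[[k]][1])
    if (k == "mu") {
      # P-spline mu: start from penalized LS on the scores
      beta$mu <- plls_solve(X$mu, P$mu, rep(1, n), y, 10)$beta
    }
  }
  lam <- lapply(pk, function(k) {
    if (is.null(P[[k]])) NULL
    else if (identical(lambda[[k]], "auto")) NA_real_ else lambda[[k]]
  })
  names(lam) <- pk

  etas <- lapply(pk, function(k) drop(X[[k]] %*% beta[[k]]))
  names(etas) <- pk
  ll <- ll_pointwise(spec$family, spec$links, y, etas)
  if (!all(is.finite(ll))) {
    # nudge sigma up until the likelihood is finite at the start
    for (i in 1:8) {
      beta$sigma[1] <- beta$sigma[1] + 0.5
      etas$sigma <- drop(X$sigma %*% beta$sigma)
      ll <- ll_pointwise(spec$family, spec$links, y, etas)
      if (all(is.finite(ll))) break
    }
    if (!all(is.finite(ll))) stop("non-finite likelihood at initialization")
  }
  dev_old <- -2 * sum(ll)

  converged <- FALSE
  iter <- 0L
  # smoothing parameters are re-profiled while the working weights are still
  # settling, then frozen so the fixed-penalty backfit converges monotonically
  lambda_freeze <- 15L
  W_last <- vector("list", length(pk)); names(W_last) <- pk
  while (iter < spec$max_iterations) {
    iter <- iter + 1L
    refresh <- iter <= lambda_freeze
    for (k in pk) {
      if (refresh && !is.null(P[[k]]) && identical(lambda[[k]], "auto"))
        lam[[k]] <- NA_real_
      upd <- irls_update(spec, y, X, P, lam, beta, etas, k, n)
      beta <- upd$beta; etas <- upd$etas; lam <- upd$lam
      W_last[[k]] <- upd$w
    }
    dev_new <- -2 * sum(ll_pointwise(spec$family, spec$links, y, etas))
    if (!is.finite(dev_new)) stop("deviance diverged")
    if (abs(dev_new - dev_old) < spec$tolerance) {
      converged <- TRUE
      dev_old <- dev_new
      break
    }
    dev_old <- dev_new
  }

  edf <- lapply(pk, function(k) {
    if (is.null(P[[k]])) ncol(X[[k]])
    else {
      XtWX <- crossprod(X[[k]] * W_last[[k]], X[[k]])
      A <- XtWX + lam[[k]] * P[[k]]
      sum(diag(solve(A, XtWX)))
    }
  })
  names(edf) <- pk

  list(beta = beta, lambda = lam, edf = edf,
       loglik = -dev_old / 2, iterations = iter, converged = converged)
}

# one penalized IRLS update for parameter k, with local GAIC selection of an
# "auto" smoothing parameter and step-halving on the penalized deviance
irls_update <- function(spec, y, X, P, lam, beta, etas, k, n) {
  eta_k <- etas[[k]]
  ll0 <- ll_pointwise(spec$family, spec$links, y, etas)
  if (spec$family == "NO") {
    # exact score and expected curvature for the normal family
    mu <- etas$mu
    sigma <- linkinv_eta("log", etas$sigma)
    zres <- (y - mu) / sigma
    if (k == "mu") {
      u <- zres / sigma
      w <- 1 / sigma^2
    } else {
      u <- zres^2 - 1
      w <- rep(2, n)
    }
  } else {
    # central differences of the pointwise log-likelihood in eta
    h <- 1e-3
    base_etas <- etas
    base_etas[[k]] <- eta_k + h
    llp <- ll_pointwise(spec$family, spec$links, y, base_etas)
    base_etas[[k]] <- eta_k - h
    llm <- ll_pointwise(spec$family, spec$links, y, base_etas)
    u <- (llp - llm) / (2 * h)
    w <- -(llp - 2 * ll0 + llm) / h^2
  }
  bad <- !is.finite(u) | !is.finite(w)
  u[bad] <- 0
  w[bad] <- 1
  wfloor <- 1e-4 * stats::median(abs(w[w > 0]), na.rm = TRUE)
  if (!is.finite(wfloor) || wfloor <= 0) wfloor <- 1e-6
  w <- pmax(w, wfloor)
  zwork <- eta_k + u / w

  if (!is.null(P[[k]]) && is.na(lam[[k]])) {
    lam[[k]] <- select_lambda_local(X[[k]], P[[k]], w, zwork, spec$gaic_k)
  }
  sol <- plls_solve(X[[k]], P[[k]], w, zwork, lam[[k]])
  beta_new <- sol$beta

  # step-halving on the penalized deviance
  pen <- function(b) if (is.null(P[[k]])) 0 else drop(lam[[k]] * (t(b) %*% P[[k]] %*% b))
  pdev0 <- -2 * sum(ll0) + pen(beta[[k]])
  step <- 1
  for (i in 1:6) {
    cand <- beta[[k]] + step * (beta_new - beta[[k]])
    et <- etas
    et[[k]] <- drop(X[[k]] %*% cand)
    llc <- ll_pointwise(spec$family, spec$links, y, et)
    pdev <- -2 * sum(llc) + pen(cand)
    if (is.finite(pdev) && pdev <= pdev0 + 1e-10) {
      beta[[k]] <- cand
      etas <- et
      break
    }
    step <- step / 2
  }
  list(beta = beta, etas = etas, lam = lam, w = w)
}

# weighted penalized least squares solve
plls_solve <- function(Xk, Pk, w, z, lambda) {
  XtW <- t(Xk * w)
  A <- XtW %*% Xk
  if (!is.null(Pk)) A <- A + lambda * Pk
  b <- XtW %*% z
  beta <- tryCatch(solve(A, b), error = function(e) {
    solve(A + diag(1e-8 * mean(diag(A)), ncol(A)), b)
  })
  list(beta = drop(beta))
}

# profile the GAIC of the weighted working model over log-lambda
select_lambda_local <- function(Xk, Pk, w, z, k_pen) {
  XtW <- t(Xk * w)
  XtWX <- XtW %*% Xk
  XtWz <- XtW %*% z
  zz <- sum(w * z^2)
  crit <- function(loglam) {
    lamv <- exp(loglam)
    A <- XtWX + lamv * Pk
    beta <- tryCatch(solve(A, XtWz), error = function(e) NULL)
    if (is.null(beta)) return(Inf)
    edf <- sum(diag(solve(A, XtWX)))
    rss <- zz - 2 * sum(beta * XtWz) + drop(t(beta) %*% XtWX %*% beta)
    rss + k_pen * edf
  }
  opt <- optimize(crit, interval = log(c(1e-4, 1e6)), tol = 0.05)
  # prefer the smoother end on a flat criterion
  if (crit(log(1e6)) <= opt$objective + 1e-8) return(1e6)
  exp(opt$minimum)
}

# ---- fitted-model accessors -------------------------------------------------

#' Fitted distributional parameters at given ages
#'
#' Evaluates a fitted model's (or a population model's) parameter curves,
#' inverting each link, at the requested ages.
#'
#' @param object a `normfit` or `norm_population` object.
#' @param ages numeric vector of ages.
#' @param ... unused.
#' @return A tibble with columns `age`, `mu`, `sigma`, `nu`, `tau` (`nu` and
#'   `tau` are `NA` for the normal family).
#' @export
predict_params <- function(object, ages, ...) UseMethod("predict_params")

#' @export
predict_params.normfit <- function(object, ages, ...) {
  if (object$failed)
    abort("cannot predict from a failed fit", class = "nt_error_failed_fit")
  if (any(!is.finite(ages)))
    abort("ages must be finite", class = "nt_error_domain")
  pk <- family_param_names(object$family)
  th <- lapply(pk, function(k) {
    Xk <- eval_term(object$term_refs[[k]], ages)
    linkinv_eta(object$links[[k]], drop(Xk %*% object$coefficients[[k]]))
  })
  names(th) <- pk
  tibble(age = ages, mu = th$mu, sigma = th$sigma,
         nu = th$nu %||% NA_real_, tau = th$tau %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.normfit <- function(x, ...) {
  if (x$failed) {
    cat("<normfit> FAILED (could not be estimated)\n")
    return(invisible(x))
  }
  cat(sprintf("<normfit> %s, n = %d, logLik = %.2f, edf = %.2f, %s in %d cycles\n",
              x$family, x$n, x$loglik, x$edf_total,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Tidy and summarize fitted norming models
#'
#' `tidy()` returns one row per coefficient (parameter curve by basis
#' column, on the link scale); `glance()` returns a one-row fit summary.
#'
#' @param x a `normfit` object.
#' @param ... unused.
#' @export
tidy.normfit <- function(x, ...) {
  if (x$failed) return(tibble(parameter = character(), term = character(),
                              estimate = numeric()))
  purrr::map_dfr(names(x$coefficients), function(k) {
    b <- x$coefficients[[k]]
    tibble(parameter = k, term = paste0(k, seq_along(b) - 1), estimate = b)
  })
}

#' @rdname tidy.normfit
#' @export
glance.normfit <- function(x, ...) {
  if (x$failed)
    return(tibble(logLik = NA_real_, deviance = NA_real_, edf = NA_real_,
                  AIC = NA_real_, BIC = NA_real_, iterations = NA_integer_,
                  converged = FALSE, failed = TRUE, nobs = x$n))
  tibble(logLik = x$loglik, deviance = x$deviance, edf = x$edf_total,
         AIC = gaic(x, 2), BIC = gaic(x, log(x$n)),
         iterations = x$iterations, converged = x$converged, failed = FALSE,
         nobs = x$n)
}
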