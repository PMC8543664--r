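# Design-matrix builders: orthogonal polynomials of age and P-spline bases
# (equally spaced cubic B-splines with a difference penalty).

#' Orthogonal polynomial basis of age
#'
#' Builds an orthonormal polynomial design matrix including the constant
#' column, using a QR orthogonalization against the supplied age vector
#' (via [stats::poly()]).  The orthogonalizing transform is stored in the
#' `"coefs"` attribute so fitted curves can be evaluated at arbitrary ages
#' with [poly_basis_predict()].
#'
#' @param ages numeric vector of ages.
#' @param degree polynomial degree (`0` gives the constant column only).
#' @return A matrix with `degree + 1` columns; column 1 is the constant.
#' @export
poly_basis <- function(ages, degree) {
  if (degree < 0) abort("degree must be >= 0", class = "nt_error_domain")
  if (degree >= length(unique(ages)))
    abort("polynomial degree too high for the distinct ages supplied",
          class = "nt_error_rank")
  if (degree == 0) {
    out <- matrix(1, length(ages), 1)
    attr(out, "coefs") <- NULL
    attr(out, "degree") <- 0L
    return(out)
  }
  pb <- stats::poly(ages, degree = degree)
  out <- cbind(1, unclass(pb))
  attr(out, "coefs") <- attr(pb, "coefs")
  attr(out, "degree") <- as.integer(degree)
  colnames(out) <- c("(const)", paste0("poly", seq_len(degree)))
  out
}

#' @rdname poly_basis
#' @param basis a matrix from [poly_basis()] (supplies the stored transform).
#' @param new_ages ages at which to evaluate the same polynomial basis.
#' @export
poly_basis_predict <- function(basis, new_ages) {
  degree <- attr(basis, "degree")
  if (degree == 0) return(matrix(1, length(new_ages), 1))
  pb <- stats::poly(new_ages, degree = degree, coefs = attr(basis, "coefs"))
  out <- cbind(1, unclass(pb))
  colnames(out) <- colnames(basis)
  out
}

# equally spaced knot sequence in the Eilers-Marx style: n_knots interior
# knots plus the two boundaries, extended spline_degree knots past each end
pspline_knots <- function(lo, hi, n_knots, spline_degree) {
  inner <- seq(lo, hi, length.out = n_knots + 2)
  h <- inner[2] - inner[1]
  c(lo - h * rev(seq_len(spline_degree)), inner, hi + h * seq_len(spline_degree))
}

#' P-spline basis with difference penalty
#'
#' Builds a B-spline design matrix on equally spaced knots over the observed
#' age range together with its difference-penalty matrix.  The default is the
#' configuration used throughout the norming study: 6 interior knots, cubic
#' splines, second-order differences (so the penalty's null space is the
#' space of straight lines, and a very large smoothing parameter shrinks the
#' fitted curve to a line).  Rows of the basis sum to one over the age range;
#' ages outside the knot range are evaluated by clamping to the boundary.
#'
#' @param ages numeric vector of ages.
#' @param n_knots number of interior knots.
#' @param spline_degree B-spline degree (3 = cubic).
#' @param penalty_order order of the difference penalty.
#' @param range age range covered by the knots; defaults to `range(ages)`.
#' @return A list with elements `B` (n x p basis matrix), `P` (p x p penalty
#'   matrix, positive semidefinite with null space of dimension
#'   `penalty_order`), and `knots`.
#' @export
pspline_basis <- function(ages, n_knots = 6, spline_degree = 3,
                          penalty_order = 2, range = NULL) {
  if (n_knots < 1) abort("n_knots must be >= 1", class = "nt_error_domain")
  rg <- if (is.null(range)) base::range(ages) else range
  if (diff(rg) <= 0)
    abort("degenerate age support for the spline basis", class = "nt_error_rank")
  knots <- pspline_knots(rg[1], rg[2], n_knots, spline_degree)
  B <- pspline_eval(knots, spline_degree, ages, rg)
  p <- ncol(B)
  D <- diff(diag(p), differences = penalty_order)
  list(B = B, P = crossprod(D), knots = knots, spline_degree = spline_degree,
       penalty_order = penalty_order, range = rg)
}

# evaluate the B-spline basis, clamping ages to the covered range
pspline_eval <- function(knots, spline_degree, ages, rg) {
  x <- pmin(pmax(ages, rg[1]), rg[2])
  splines::splineDesign(knots, x, ord = spline_degree + 1)
}

# ---- term specifications ----------------------------------------------------

#' Term specifications for a distributional parameter
#'
#' Each distributional parameter of a norming model is modelled, on its link
#' scale, as one function of age: a constant, a straight line, an orthogonal
#' polynomial of given degree, or a penalized B-spline (P-spline).  For
#' P-spline terms, `lambda = "auto"` selects the smoothing parameter by
#' GAIC during fitting (penalty set on the model specification).
#'
#' @param degree polynomial degree.
#' @param n_knots,spline_degree,penalty_order see [pspline_basis()].
#' @param lambda nonnegative smoothing parameter, or `"auto"`.
#' @return An object of class `nt_term`.
#' @export
term_intercept <- function() {
  structure(list(kind = "intercept"), class = "nt_term")
}

#' @rdname term_intercept
#' @export
term_linear <- function() {
  structure(list(kind = "linear"), class = "nt_term")
}

#' @rdname term_intercept
#' @export
term_poly <- function(degree) {
  structure(list(kind = "poly", degree = as.integer(degree)), class = "nt_term")
}

#' @rdname term_intercept
#' @export
term_pspline <- function(n_knots = 6, spline_degree = 3, penalty_order = 2,
                         lambda = "auto") {
  if (!identical(lambda, "auto") && (!is.numeric(lambda) || lambda < 0))
    abort("lambda must be 'auto' or a nonnegative number",
          class = "nt_error_domain")
  structure(list(kind = "pspline", n_knots = as.integer(n_knots),
                 spline_degree = as.integer(spline_degree),
                 penalty_order = as.integer(penalty_order), lambda = lambda),
            class = "nt_term")
}

#' @export
print.nt_term <- function(x, ...) {
  desc <- switch(x$kind,
                 intercept = "intercept",
                 linear = "linear in age",
                 poly = paste0("orthogonal polynomial, degree ", x$degree),
                 pspline = paste0("P-spline (", x$n_knots, " knots, lambda ",
                                  if (identical(x$lambda, "auto")) "auto"
                                  else signif(x$lambda, 3), ")"))
  cat("<nt_term>", desc, "\n")
  invisible(x)
}

# build the design matrix (+ penalty) for one term; returns everything needed
# to re-evaluate the same columns at new ages
build_term <- function(term, ages, range = NULL) {
  switch(term$kind,
         intercept = list(X = matrix(1, length(ages), 1), P = NULL,
                          lambda = NULL, ref = list(kind = "intercept")),
         linear = list(X = cbind(1, ages), P = NULL, lambda = NULL,
                       ref = list(kind = "linear")),
         poly = {
           X <- poly_basis(ages, term$degree)
           list(X = X, P = NULL, lambda = NULL,
                ref = list(kind = "poly", degree = term$degree,
                           coefs = attr(X, "coefs")))
         },
         pspline = {
           bs <- pspline_basis(ages, term$n_knots, term$spline_degree,
                               term$penalty_order, range = range)
           list(X = bs$B, P = bs$P, lambda = term$lambda,
                ref = list(kind = "pspline", knots = bs$knots,
                           spline_degree = bs$spline_degree, range = bs$range))
         },
         abort(paste("unknown term kind:", term$kind), class = "nt_error_domain"))
}

# evaluate a stored term reference at new ages
eval_term <- function(ref, ages) {
  switch(ref$kind,
         intercept = matrix(1, length(ages), 1),
         linear = cbind(1, ages),
         poly = {
           if (ref$degree == 0) matrix(1, length(ages), 1)
           else cbind(1, unclass(stats::poly(ages, degree = ref$degree,
                                             coefs = ref$coefs)))
         },
         pspline = pspline_eval(ref$knots, ref$spline_degree, ages, ref$range))
}
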