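#' Item difficulty functions
#'
#' The item difficulty function \eqn{\delta_i(y)} is a non-decreasing function
#' on the item's response support that encodes how hard it is to exceed each
#' response level.  Parametric families have the form
#' \eqn{\delta(y) = \delta_0 + \delta\, g(y)} with a fixed monotone transform
#' \eqn{g}:
#'
#' * `difficulty_linear()`: \eqn{g(y) = y}, for real-valued or rating-type
#'   responses;
#' * `difficulty_log()`: \eqn{g(y) = \log y}, for positive responses;
#' * `difficulty_log1p()`: \eqn{g(y) = \log(1 + y)}, for counts and ordinal
#'   categories (keeps 0 in the support);
#' * `difficulty_adapted_logit()`: \eqn{g(y) = \log((1+y)/(k-y))}, an ordinal
#'   transform symmetric around \eqn{m = (k-1)/2};
#' * `difficulty_inverse_cdf()`: \eqn{g(y) = a F^{-1}(z)} with
#'   \eqn{z = (y-a_0)/(b_0-a_0)} for responses in a bounded interval
#'   \eqn{(a_0, b_0)}; the affine map into \eqn{(0,1)} is part of the
#'   transform, so densities on the original scale need no extra Jacobian;
#' * `difficulty_binary()`: a single intercept \eqn{\delta(0) = \delta_0}
#'   (for binary items the shape of \eqn{g} is irrelevant and no slope is
#'   stored);
#' * `difficulty_free_ordinal()`: one free, strictly increasing value per
#'   threshold, \eqn{\delta_{r+1} = \delta(r)} - the graded-response
#'   parameterization;
#' * `difficulty_bspline()`: a monotone cubic B-spline expansion
#'   \eqn{\delta(y) = \sum_l \delta_l \Phi_l(y)} with non-decreasing
#'   coefficients (see [difficulty_bspline()]).
#'
#' Boundary conventions: \eqn{\delta(-1) = -\infty} for discrete supports
#' (so that \eqn{P(Y > -1) = 1}) and \eqn{\delta(k) = +\infty} at the top of
#' a finite support (so that \eqn{P(Y > k) = 0}).
#'
#' @param intercept Intercept \eqn{\delta_0}.
#' @param slope Positive slope \eqn{\delta} of the difficulty function.
#' @param k Threshold count of the ordinal support (responses `{0..k}`).
#' @param a Scaling constant of the inverse-cdf transform (default 1).
#' @param rf Response function whose quantile defines \eqn{F^{-1}} for the
#'   inverse-cdf transform.
#' @param bounds Original interval `(a0, b0)` of a bounded continuous item.
#' @param values Strictly increasing threshold values
#'   \eqn{\delta_1 < \dots < \delta_k} of a free-ordinal difficulty.
#' @return An object of class `irt_difficulty`.
#' @examples
#' d <- difficulty_linear(2, 3)
#' delta_eval(d, 1)       # 5
#' delta_inverse(d, 5)    # 1
#' @name difficulty
NULL

.difficulty <- function(family, ...) {
  structure(c(list(family = family), list(...)), class = "irt_difficulty")
}

.check_slope <- function(slope) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (slope <= 0) stop("difficulty slope must be positive", call. = FALSE)
  as.numeric(slope)
}

#' @rdname difficulty
#' @export
difficulty_linear <- function(intercept, slope = 1) {
  .difficulty("linear", intercept = as.numeric(intercept),
              slope = .check_slope(slope))
}

#' @rdname difficulty
#' @export
difficulty_log <- function(intercept, slope = 1) {
  .difficulty("log", intercept = as.numeric(intercept),
              slope = .check_slope(slope))
}

#' @rdname difficulty
#' @export
difficulty_log1p <- function(intercept, slope = 1) {
  .difficulty("log1p", intercept = as.numeric(intercept),
              slope = .check_slope(slope))
}

#' @rdname difficulty
#' @export
difficulty_adapted_logit <- function(intercept, slope = 1, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  .difficulty("adapted_logit", intercept = as.numeric(intercept),
              slope = .check_slope(slope), k = as.numeric(k))
}

#' @rdname difficulty
#' @export
difficulty_inverse_cdf <- function(intercept, slope = 1, a = 1,
                                   rf = response_function("normal"),
                                   bounds = c(0, 1)) {
  stopifnot(inherits(rf, "irt_response"), is.numeric(a), a > 0,
            length(bounds) == 2L, bounds[1] < bounds[2])
  .difficulty("inverse_cdf", intercept = as.numeric(intercept),
              slope = .check_slope(slope), a = as.numeric(a),
              quantile = rf$quantile, qdensity = rf$density,
              bounds = as.numeric(bounds))
}

#' @rdname difficulty
#' @export
difficulty_binary <- function(intercept) {
  .difficulty("binary", intercept = as.numeric(intercept))
}

#' @rdname difficulty
#' @export
difficulty_free_ordinal <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(diff(values) <= 0)) {
    stop("free-ordinal difficulty values must be strictly increasing",
         call. = FALSE)
  }
  .difficulty("free_ordinal", ordinal_values = values)
}

#' Monotone B-spline difficulty function
#'
#' Builds a difficulty function as a cubic B-spline expansion
#' \eqn{\delta(y) = \sum_{l=0}^{M} \delta_l \Phi_l(y)} with non-decreasing
#' coefficients \eqn{\delta_0 \le \dots \le \delta_M}, which guarantees that
#' \eqn{\delta} is non-decreasing.  Knots are equally spaced over `range`
#' (for discrete items, the observed-response range `0..k-1` or
#' `0..max(y)`), with boundary knots repeated.  Six basis functions are a
#' practical default.
#'
#' @param coefs Non-decreasing spline coefficients, one per basis function.
#' @param range Numeric length-2 interval covered by the spline.
#' @param support Optional `irt_support` the function is meant for (stored
#'   for validation; defaults to `support_real()`).
#' @return An `irt_difficulty` of family `"bspline"`.
#' @export
difficulty_bspline <- function(coefs, range, support = support_real()) {
  coefs <- as.numeric(coefs)
  n_basis <- length(coefs)
  if (n_basis < 4L) stop("need at least 4 cubic B-spline coefficients",
                         call. = FALSE)
  if (any(diff(coefs) < -1e-12)) {
    stop("B-spline coefficients must be non-decreasing", call. = FALSE)
  }
  stopifnot(is.numeric(range), length(range) == 2L, range[1] < range[2])
  knots <- .bspline_knots(range, n_basis)
  .difficulty("bspline", spline_coefs = coefs, knots = knots,
              range = as.numeric(range), n_basis = n_basis,
              support_kind = support$kind)
}

# full knot vector for `n_basis` cubic B-splines on [lo, hi]
.bspline_knots <- function(range, n_basis) {
  ord <- 4L
  n_int <- n_basis - ord
  interior <- if (n_int > 0) {
    seq(range[1], range[2], length.out = n_int + 2L)[-c(1L, n_int + 2L)]
  } else numeric(0)
  c(rep(range[1], ord), interior, rep(range[2], ord))
}

.bspline_basis <- function(d, y, deriv = 0L) {
  y <- pmin(pmax(y, d$range[1]), d$range[2])
  splines::splineDesign(d$knots, y, ord = 4L, derivs = rep(deriv, length(y)),
                        outer.ok = FALSE)
}

# g(y) and g'(y) for the parametric families
.g_eval <- function(d, y) {
  switch(d$family,
    linear = y,
    log = log(y),
    log1p = log1p(y),
    adapted_logit = log((1 + y) / (d$k - y)),
    inverse_cdf = {
      z <- (y - d$bounds[1]) / (d$bounds[2] - d$bounds[1])
      d$a * d$quantile(z)
    },
    stop("no parametric transform for family ", d$family))
}

.g_deriv <- function(d, y) {
  switch(d$family,
    linear = rep(1, length(y)),
    log = 1 / y,
    log1p = 1 / (1 + y),
    adapted_logit = 1 / (1 + y) + 1 / (d$k - y),
    inverse_cdf = {
      w <- d$bounds[2] - d$bounds[1]
      z <- (y - d$bounds[1]) / w
      d$a / (d$qdensity(d$quantile(z)) * w)
    })
}

.parametric_families <- c("linear", "log", "log1p", "adapted_logit",
                          "inverse_cdf")

is_parametric_difficulty <- function(d) d$family %in% .parametric_families

#' Evaluate a difficulty function
#'
#' @param d An `irt_difficulty` object.
#' @param y Response values (vectorized).  For discrete items the
#'   conventions \eqn{\delta(-1) = -\infty} and, when `top` is finite,
#'   \eqn{\delta(top) = +\infty} apply.
#' @param top Top of a finite discrete support (threshold index at which
#'   \eqn{\delta} is \eqn{+\infty}); `Inf` (default) means no upper
#'   truncation.  [item_spec()] supplies this automatically.
#' @param discrete Apply the discrete boundary conventions?  Defaults to
#'   `TRUE` for the inherently discrete families (`binary`,
#'   `free_ordinal`), `FALSE` otherwise; model-level code sets it from the
#'   item support.
#' @return Numeric vector \eqn{\delta(y)}.
#' @export
delta_eval <- function(d, y, top = Inf,
                       discrete = .family_discrete(d)) {
  y <- as.numeric(y)
  out <- rep(NA_real_, length(y))
  lo <- !is.na(y) & discrete & y == -1
  hi <- !is.na(y) & discrete & is.finite(top) & y >= top
  mid <- !is.na(y) & !lo & !hi
  out[lo] <- -Inf
  out[hi] <- Inf
  if (any(mid)) {
    ym <- y[mid]
    out[mid] <- switch(d$family,
      binary = {
        if (any(ym != 0)) stop("binary difficulty is defined at y = 0 only",
                               call. = FALSE)
        rep(d$intercept, length(ym))
      },
      free_ordinal = {
        r <- ym + 1
        if (any(r < 1 | r > length(d$ordinal_values) | r != round(r))) {
          stop("response outside the free-ordinal support", call. = FALSE)
        }
        d$ordinal_values[r]
      },
      bspline = drop(.bspline_basis(d, ym) %*% d$spline_coefs),
      {
        .check_g_domain(d, ym)
        d$intercept + d$slope * .g_eval(d, ym)
      })
  }
  out
}

.check_g_domain <- function(d, y) {
  bad <- switch(d$family,
    log = y <= 0,
    log1p = y <= -1,
    adapted_logit = y <= -1 | y >= d$k,
    inverse_cdf = y <= d$bounds[1] | y >= d$bounds[2],
    rep(FALSE, length(y)))
  if (any(bad)) {
    stop("response value outside the domain of the ", d$family,
         " difficulty transform", call. = FALSE)
  }
  invisible(TRUE)
}

#' Derivative of a difficulty function
#'
#' Analytic derivative \eqn{\delta'(y)} for continuous difficulty families;
#' used by the continuous density \eqn{f(\alpha(\theta-\delta(y)))\,\alpha\,
#' \delta'(y)} and by the score function.
#'
#' @inheritParams delta_eval
#' @return Numeric vector \eqn{\delta'(y)}.
#' @export
delta_deriv <- function(d, y) {
  y <- as.numeric(y)
  switch(d$family,
    free_ordinal = ,
    binary = stop("difficulty family \"", d$family,
                  "\" has no derivative (discrete-only family)",
                  call. = FALSE),
    bspline = drop(.bspline_basis(d, y, deriv = 1L) %*% d$spline_coefs),
    {
      .check_g_domain(d, y)
      d$slope * .g_deriv(d, y)
    })
}

#' Inverse of a difficulty function
#'
#' Solves \eqn{\delta(y) = v} for strictly increasing continuous families:
#' closed form for the parametric transforms, bracketed root search for
#' B-splines.  Needed by the inverse-construction response sampler.
#'
#' @param d An `irt_difficulty` object.
#' @param v Difficulty values (vectorized).
#' @return Numeric vector `y` with `delta_eval(d, y) = v`.
#' @export
delta_inverse <- function(d, v) {
  v <- as.numeric(v)
  if (d$family == "bspline") {
    rng <- d$range
    vr <- delta_eval(d, rng)
    out <- vapply(v, function(vi) {
      if (vi < vr[1] - 1e-9 || vi > vr[2] + 1e-9) {
        stop("value outside the range of the B-spline difficulty",
             call. = FALSE)
      }
      if (vi <= vr[1]) return(rng[1])
      if (vi >= vr[2]) return(rng[2])
      stats::uniroot(function(y) delta_eval(d, y) - vi, interval = rng,
                     tol = 1e-12)$root
    }, numeric(1))
    return(out)
  }
  if (!is_parametric_difficulty(d)) {
    stop("difficulty family \"", d$family, "\" is not invertible",
         call. = FALSE)
  }
  u <- (v - d$intercept) / d$slope
  out <- switch(d$family,
    linear = u,
    log = exp(u),
    log1p = expm1(u),
    adapted_logit = (d$k * exp(u) - 1) / (1 + exp(u)),
    inverse_cdf = {
      w <- d$bounds[2] - d$bounds[1]
      # invert a F^{-1}((y - a0)/w): z = F(u/a)
      d$bounds[1] + w * .quantile_cdf_inverse(d, u / d$a)
    })
  out
}

# cdf matching the stored quantile of an inverse_cdf difficulty
.quantile_cdf_inverse <- function(d, x) {
  # the shipped response functions are normal and logistic; recognise them
  # through their quantile functions, falling back to numeric inversion
  if (identical(d$quantile, stats::qnorm)) return(stats::pnorm(x))
  if (identical(d$quantile, stats::qlogis)) return(stats::plogis(x))
  vapply(x, function(xi) {
    stats::uniroot(function(z) d$quantile(z) - xi, interval = c(1e-12, 1 - 1e-12),
                   tol = 1e-12)$root
  }, numeric(1))
}

.family_discrete <- function(d) d$family %in% c("binary", "free_ordinal")

# basis matrix of partial derivatives d delta(y) / d par (natural order);
# rows for y = -1 or y >= top are zero (discrete boundary conventions)
.delta_basis <- function(d, y, top = Inf, discrete = .family_discrete(d)) {
  n <- length(y)
  p <- n_difficulty_params(d)
  B <- matrix(0, n, p)
  mid <- !is.na(y) &
    !(discrete & (y == -1 | (is.finite(top) & y >= top)))
  if (!any(mid)) return(B)
  ym <- y[mid]
  B[mid, ] <- switch(d$family,
    binary = matrix(1, sum(mid), 1L),
    free_ordinal = {
      M <- matrix(0, sum(mid), p)
      M[cbind(seq_len(sum(mid)), ym + 1)] <- 1
      M
    },
    bspline = .bspline_basis(d, ym),
    cbind(1, .g_eval(d, ym)))
  B
}

# derivative basis d delta'(y) / d par for continuous families
.delta_basis_deriv <- function(d, y) {
  switch(d$family,
    bspline = .bspline_basis(d, y, deriv = 1L),
    cbind(0, .g_deriv(d, y)))
}

n_difficulty_params <- function(d) {
  switch(d$family,
    binary = 1L,
    free_ordinal = length(d$ordinal_values),
    bspline = d$n_basis,
    2L)
}

# current natural parameter vector of a difficulty
.difficulty_params <- function(d) {
  switch(d$family,
    binary = d$intercept,
    free_ordinal = d$ordinal_values,
    bspline = d$spline_coefs,
    c(d$intercept, d$slope))
}

# replace natural parameters, preserving family metadata
.difficulty_set_params <- function(d, par) {
  switch(d$family,
    binary = { d$intercept <- par[1] },
    free_ordinal = { d$ordinal_values <- par },
    bspline = { d$spline_coefs <- par },
    { d$intercept <- par[1]; d$slope <- par[2] })
  d
}

#' @export
print.irt_difficulty <- function(x, ...) {
  desc <- switch(x$family,
    binary = paste0("delta(0) = ", format(x$intercept)),
    free_ordinal = paste0("thresholds ",
                          paste(format(x$ordinal_values, digits = 4),
                                collapse = ", ")),
    bspline = paste0(x$n_basis, " cubic B-spline coefficients on [",
                     format(x$range[1]), ", ", format(x$range[2]), "]"),
    paste0("intercept ", format(x$intercept), ", slope ", format(x$slope)))
  cat("<irt_difficulty> ", x$family, ": ", desc, "\n", sep = "")
  invisible(x)
}

#' Squeeze bounded responses off the boundary
#'
#' Responses observed exactly at the boundary of a bounded interval have
#' infinite difficulty and are rejected by the likelihood.  This utility
#' applies the usual compression `(y * (n - 1) + 0.5) / n` on the unit scale,
#' pulling boundary observations strictly inside the interval.
#'
#' @param y Responses in `[a, b]`.
#' @param n Sample size used for the compression.
#' @param bounds Interval `(a, b)` of the responses.
#' @return Responses strictly inside `(a, b)`.
#' @export
squeeze_unit <- function(y, n, bounds = c(0, 1)) {
  z <- (y - bounds[1]) / (bounds[2] - bounds[1])
  z <- (z * (n - 1) + 0.5) / n
  bounds[1] + z * (bounds[2] - bounds[1])
}
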