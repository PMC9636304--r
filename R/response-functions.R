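#' Response functions for thresholds models
#'
#' A response function is the strictly increasing distribution function
#' \eqn{F} in the thresholds model \eqn{P(Y > y) = F(\alpha(\theta - \delta(y)))}.
#' Together with its density and the first two density derivatives it supplies
#' everything the likelihood, the score function and the information formulas
#' need.  Two symmetric response functions are shipped: the standard normal
#' ("normal") and the standard logistic ("logistic").
#'
#' The moment constants `c_const` and `d_const` are the variance and the mean
#' of the distribution \eqn{F}: with a linear difficulty
#' \eqn{\delta(y) = \delta_0 + \delta y} the response can be written as
#' \eqn{Y = (\theta - V/\alpha - \delta_0)/\delta} with \eqn{V \sim F}, so
#' \eqn{E(Y) = \gamma\theta - \gamma_0} and \eqn{var(Y) = c\,\gamma^2/\alpha^2}
#' with \eqn{\gamma = 1/\delta}, \eqn{\gamma_0 = (\delta_0 + d/\alpha)/\delta},
#' \eqn{d = E(V)} and \eqn{c = var(V)}.  They are computed once at
#' construction by adaptive numeric integration.
#'
#' @param name Label of the response function, one of `"normal"` or
#'   `"logistic"`.
#' @return An object of class `irt_response`: a list with elements `name`,
#'   `cdf`, `density`, `density_d1`, `density_d2`, `quantile`, `symmetric`,
#'   `c_const` and `d_const`.
#' @examples
#' F <- response_function("logistic")
#' F$cdf(0)               # 0.5
#' moment_constants(F)    # c = pi^2/3, d = 0
#' @export
response_function <- function(name = c("normal", "logistic")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("normal", "logistic")) {
    stop("unknown response function ", deparse(substitute(name)),
         "; supported labels are \"normal\" and \"logistic\"", call. = FALSE)
  }
  rf <- switch(name,
    normal = list(
      name = "normal",
      cdf = stats::pnorm,
      density = stats::dnorm,
      # f(x) = phi(x): f'(x) = -x phi(x), f''(x) = (x^2 - 1) phi(x)
      density_d1 = function(x) -x * stats::dnorm(x),
      density_d2 = function(x) (x^2 - 1) * stats::dnorm(x),
      quantile = stats::qnorm,
      symmetric = TRUE
    ),
    logistic = list(
      name = "logistic",
      cdf = stats::plogis,
      density = stats::dlogis,
      # f'(x) = f(x)(1 - 2F(x)), f''(x) = f(x)((1 - 2F(x))^2 - 2f(x))
      density_d1 = function(x) stats::dlogis(x) * (1 - 2 * stats::plogis(x)),
      density_d2 = function(x) {
        fx <- stats::dlogis(x)
        fx * ((1 - 2 * stats::plogis(x))^2 - 2 * fx)
      },
      quantile = stats::qlogis,
      symmetric = TRUE
    )
  )
  cd <- .moment_constants_numeric(rf)
  rf$d_const <- if (rf$symmetric) 0 else cd[["d"]]
  rf$c_const <- cd[["c"]]
  class(rf) <- "irt_response"
  rf
}

# mean and variance of the distribution F by adaptive quadrature
.moment_constants_numeric <- function(rf) {
  d <- stats::integrate(function(v) v * rf$density(v), -Inf, Inf,
                        rel.tol = 1e-12)$value
  c_ <- stats::integrate(function(v) (v - d)^2 * rf$density(v), -Inf, Inf,
                         rel.tol = 1e-12)$value
  if (!is.finite(c_) || c_ <= 0) {
    stop("response function density is not integrable", call. = FALSE)
  }
  c(c = c_, d = d)
}

#' Moment constants of a response function
#'
#' Returns the constants \eqn{(c, d)} that govern the mean and variance of a
#' response under a linear difficulty function (see
#' [response_function()]): `c` is the variance and `d` the mean of the
#' distribution \eqn{F}.  For a symmetric response function `d = 0`.
#'
#' @param rf An `irt_response` object.
#' @return Named numeric vector with elements `c` and `d`.
#' @export
moment_constants <- function(rf) {
  stopifnot(inherits(rf, "irt_response"))
  c(c = rf$c_const, d = rf$d_const)
}

#' @export
print.irt_response <- function(x, ...) {
  cat("<irt_response> ", x$name,
      if (x$symmetric) " (symmetric)" else "",
      "  c = ", format(x$c_const), ", d = ", format(x$d_const), "\n", sep = "")
  invisible(x)
}

# log-density derivative ratio f'(x)/f(x), used throughout the score function
.dlogf <- function(rf, x) {
  if (rf$name == "normal") return(-x)
  if (rf$name == "logistic") return(1 - 2 * stats::plogis(x))
  rf$density_d1(x) / rf$density(x)
}

# second-derivative ratio f''(x)/f(x), stable in the tails
.d2ratio <- function(rf, x) {
  if (rf$name == "normal") return(x^2 - 1)
  if (rf$name == "logistic") {
    return((1 - 2 * stats::plogis(x))^2 - 2 * stats::dlogis(x))
  }
  rf$density_d2(x) / rf$density(x)
}
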