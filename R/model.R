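#' Item specification
#'
#' Bundles an item's support, difficulty function and discrimination
#' parameter \eqn{\alpha_i > 0} into a single object and validates the
#' support/family combination: continuous supports need a continuous
#' difficulty; ordinal and count supports take the discrete-capable
#' families; binary items carry a single intercept.
#'
#' @param item_id Item label.
#' @param support An `irt_support`.
#' @param difficulty An `irt_difficulty` legal for the support.
#' @param discrimination Discrimination parameter \eqn{\alpha_i > 0}.
#' @return An object of class `irt_item`.
#' @export
item_spec <- function(item_id, support, difficulty, discrimination = 1) {
  stopifnot(inherits(support, "irt_support"),
            inherits(difficulty, "irt_difficulty"))
  if (!is.numeric(discrimination) || length(discrimination) != 1L ||
      discrimination <= 0) {
    stop("discrimination must be a positive scalar", call. = FALSE)
  }
  legal <- switch(support$kind,
    real = c("linear", "bspline"),
    positive = c("log", "bspline"),
    unit_interval = c("inverse_cdf", "bspline"),
    binary = "binary",
    ordinal = c("linear", "log1p", "adapted_logit", "free_ordinal", "bspline"),
    count = c("log1p", "log", "linear", "bspline"))
  if (!difficulty$family %in% legal) {
    stop("difficulty family \"", difficulty$family,
         "\" is not legal for support \"", support$kind, "\" (legal: ",
         paste(legal, collapse = ", "), ")", call. = FALSE)
  }
  if (difficulty$family == "free_ordinal" &&
      length(difficulty$ordinal_values) != support$k) {
    stop("free-ordinal difficulty needs exactly k = ", support$k,
         " threshold values", call. = FALSE)
  }
  structure(list(item_id = as.character(item_id), support = support,
                 difficulty = difficulty,
                 discrimination = as.numeric(discrimination)),
            class = "irt_item")
}

#' @export
print.irt_item <- function(x, ...) {
  cat("<irt_item> ", x$item_id, " [", x$support$kind, ", ",
      x$difficulty$family, ", alpha = ", format(x$discrimination), "]\n",
      sep = "")
  invisible(x)
}

is_discrete_item <- function(item) is_discrete_support(item$support)

# threshold values of an item at responses y, honouring the top convention
item_delta <- function(item, y) {
  if (is_discrete_item(item)) {
    delta_eval(item$difficulty, y, top = .support_top(item$support),
               discrete = TRUE)
  } else {
    delta_eval(item$difficulty, y)
  }
}

#' Thresholds model
#'
#' A test model: an ordered list of items sharing one response function
#' \eqn{F} and one latent distribution \eqn{\theta \sim N(0, \sigma_\theta^2)}.
#' The form of the response function is the same for all items; what differs
#' between items is the difficulty function (and possibly the
#' discrimination).
#'
#' @param items List of [item_spec()] objects (at least one); item ids must
#'   be unique.
#' @param response An `irt_response` or a label accepted by
#'   [response_function()].
#' @param sigma_theta Latent scale \eqn{\sigma_\theta > 0}.
#' @return An object of class `thresholds_model`.
#' @export
thresholds_model <- function(items, response = "normal", sigma_theta = 1) {
  if (inherits(items, "irt_item")) items <- list(items)
  stopifnot(length(items) >= 1L,
            all(vapply(items, inherits, logical(1), "irt_item")))
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) stop("duplicated item ids", call. = FALSE)
  if (is.character(response)) response <- response_function(response)
  stopifnot(inherits(response, "irt_response"))
  if (!is.numeric(sigma_theta) || sigma_theta <= 0) {
    stop("sigma_theta must be positive", call. = FALSE)
  }
  names(items) <- ids
  structure(list(items = items, response = response,
                 sigma_theta = as.numeric(sigma_theta)),
            class = "thresholds_model")
}

#' @export
print.thresholds_model <- function(x, ...) {
  cat("<thresholds_model> ", length(x$items), " item(s), ",
      x$response$name, " response, sigma_theta = ",
      format(x$sigma_theta), "\n", sep = "")
  for (it in x$items) {
    cat("  ", format(it$item_id, width = 10), " ", it$support$kind,
        " / ", it$difficulty$family,
        if (it$discrimination != 1) paste0(" (alpha = ",
                                           format(it$discrimination), ")"),
        "\n", sep = "")
  }
  invisible(x)
}

.get_item <- function(m, item) {
  if (inherits(item, "irt_item")) return(item)
  it <- m$items[[as.character(item)]]
  if (is.null(it)) stop("unknown item \"", item, "\"", call. = FALSE)
  it
}

#' Exceedance probability (person threshold function)
#'
#' The defining probability of the thresholds model,
#' \eqn{P(Y > y \mid \theta) = F(\alpha(\theta - \delta(y)))}.  As a function
#' of \eqn{y} for fixed \eqn{\theta} this is the person threshold (PT)
#' function; as a function of \eqn{\theta} for fixed \eqn{y} it is the item
#' characteristic (IC) function (see [ic_function()]).
#'
#' @param m A `thresholds_model`.
#' @param item Item id or an `irt_item`.
#' @param theta Ability value(s).
#' @param y Threshold value(s) in the item support; `-1` is allowed for
#'   discrete items and gives probability 1.
#' @return Probabilities, vectorized over `theta` or `y`.
#' @export
prob_exceed <- function(m, item, theta, y) {
  it <- .get_item(m, item)
  d <- item_delta(it, y)
  eta <- it$discrimination * (theta - d)
  p <- m$response$cdf(eta)
  # guard 0 * Inf at the boundary conventions
  p[is.infinite(d) & d < 0] <- 1
  p[is.infinite(d) & d > 0] <- 0
  p
}

#' Item characteristic function on an ability grid
#'
#' @inheritParams prob_exceed
#' @param thetas Grid of abilities.
#' @return Vector of exceedance probabilities along `thetas`; non-decreasing
#'   in \eqn{\theta}.
#' @export
ic_function <- function(m, item, y, thetas) {
  stopifnot(length(y) == 1L)
  prob_exceed(m, item, thetas, y)
}

#' Response distribution function
#'
#' \eqn{F_{pi}(y) = P(Y \le y \mid \theta) = 1 - F(\alpha(\theta -
#' \delta(y)))}, the complement of [prob_exceed()].
#'
#' @inheritParams prob_exceed
#' @return Probabilities.
#' @export
model_cdf <- function(m, item, theta, y) {
  1 - prob_exceed(m, item, theta, y)
}

#' Density of a continuous response
#'
#' For continuous items the response density is obtained by differentiating
#' the distribution function:
#' \eqn{f_{pi}(y) = f(\alpha(\theta - \delta(y)))\,\alpha\,\delta'(y)}.
#'
#' @inheritParams prob_exceed
#' @return Density values.
#' @export
density_continuous <- function(m, item, theta, y) {
  it <- .get_item(m, item)
  if (is_discrete_item(it)) {
    stop("item \"", it$item_id, "\" is discrete; use pmf_discrete()",
         call. = FALSE)
  }
  a <- it$discrimination
  eta <- a * (theta - delta_eval(it$difficulty, y))
  m$response$density(eta) * a * delta_deriv(it$difficulty, y)
}

#' Probability mass function of a discrete response
#'
#' For discrete items the probabilities are differences of exceedance
#' probabilities: \eqn{f(0) = 1 - F(\alpha(\theta - \delta(0)))} and
#' \eqn{f(r) = F(\alpha(\theta - \delta(r-1))) - F(\alpha(\theta -
#' \delta(r)))}; the top category of a finite support uses
#' \eqn{\delta(k) = +\infty}.
#'
#' @inheritParams prob_exceed
#' @param r Category value(s) in the item support.
#' @return Probabilities summing to one over the support.
#' @export
pmf_discrete <- function(m, item, theta, r) {
  it <- .get_item(m, item)
  if (!is_discrete_item(it)) {
    stop("item \"", it$item_id, "\" is continuous; use density_continuous()",
         call. = FALSE)
  }
  ok <- support_contains(it$support, r)
  if (any(!ok & !is.na(r))) {
    stop("category ", paste(r[!ok], collapse = ", "),
         " outside the support of item \"", it$item_id, "\"", call. = FALSE)
  }
  prob_exceed(m, item, theta, r - 1) - prob_exceed(m, item, theta, r)
}

#' Moments under a linear difficulty function
#'
#' For a continuous item with linear difficulty
#' \eqn{\delta(y) = \delta_0 + \delta y} the response has
#' \eqn{E(Y) = \gamma\theta - \gamma_0} and
#' \eqn{var(Y) = c\,\gamma^2/\alpha^2}, where \eqn{\gamma = 1/\delta},
#' \eqn{\gamma_0 = (\delta_0 + d/\alpha)/\delta} and \eqn{(c, d)} are the
#' moment constants of the response function.
#'
#' @inheritParams prob_exceed
#' @return Named vector `c(mean, variance)`.
#' @export
linear_moments <- function(m, item, theta) {
  it <- .get_item(m, item)
  if (is_discrete_item(it) || it$difficulty$family != "linear") {
    stop("linear_moments() requires a continuous item with linear difficulty",
         call. = FALSE)
  }
  cd <- moment_constants(m$response)
  gam <- 1 / it$difficulty$slope
  gam0 <- (it$difficulty$intercept + cd[["d"]] / it$discrimination) /
    it$difficulty$slope
  c(mean = gam * theta - gam0,
    variance = cd[["c"]] * gam^2 / it$discrimination^2)
}

#' Categorize a continuous item
#'
#' Thresholds models are stable under categorization: cutting a continuous
#' response at ordered thresholds \eqn{\tau_1 < \dots < \tau_k}
#' (category \eqn{r \iff Y \in (\tau_r, \tau_{r+1}]}) yields an ordinal
#' thresholds model - a graded response model - with the same discrimination
#' and free-ordinal difficulties \eqn{\delta_r^{(c)} = \delta(\tau_r)}.
#'
#' @inheritParams prob_exceed
#' @param taus Strictly increasing cut points inside the item support.
#' @return An ordinal [item_spec()] whose pmf equals the interval
#'   probabilities of the continuous item.
#' @export
categorize_item <- function(m, item, taus) {
  it <- .get_item(m, item)
  if (is_discrete_item(it)) {
    stop("categorize_item() needs a continuous item", call. = FALSE)
  }
  taus <- as.numeric(taus)
  if (length(taus) < 1L || any(diff(taus) <= 0)) {
    stop("taus must be strictly increasing", call. = FALSE)
  }
  vals <- delta_eval(it$difficulty, taus)
  if (length(vals) == 1L) {
    item_spec(paste0(it$item_id, "_cat"), support_binary(),
              difficulty_binary(vals), it$discrimination)
  } else {
    item_spec(paste0(it$item_id, "_cat"), support_ordinal(length(taus)),
              difficulty_free_ordinal(vals), it$discrimination)
  }
}
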