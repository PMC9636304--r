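#' Item information for discrete items
#'
#' Fisher information of a discrete item at ability \eqn{\theta}:
#' \deqn{I(\theta) = \sum_r \frac{\pi_r'(\theta)^2 -
#'   \pi_r(\theta)\pi_r''(\theta)}{\pi_r(\theta)}}
#' with analytic category-probability derivatives
#' \eqn{\pi_r' = \alpha f(\eta_{r-1}) - \alpha f(\eta_r)} and
#' \eqn{\pi_r'' = \alpha^2 f'(\eta_{r-1}) - \alpha^2 f'(\eta_r)} at
#' \eqn{\eta_r = \alpha(\theta - \delta(r))}.  For finite supports the
#' equivalent second-derivative-free form
#' \eqn{\sum_{r\ge 1} \pi_r'^2/\pi_r + (\sum_{r\ge 1}\pi_r')^2/\pi_0}
#' is also available; the two agree identically.  For count items the
#' category sum is truncated once the upper-tail mass falls below
#' `tail_tol`.
#'
#' @param m A `thresholds_model`.
#' @param item Item id or `irt_item`.
#' @param theta Ability value (scalar).
#' @param form `"general"` (default) or `"finite"` (finite supports only).
#' @param tail_tol Truncation tolerance for infinite supports.
#' @return Nonnegative information value.
#' @export
item_information_discrete <- function(m, item, theta,
                                      form = c("general", "finite"),
                                      tail_tol = 1e-12) {
  form <- match.arg(form)
  it <- .get_item(m, item)
  if (!is_discrete_item(it)) {
    stop("item \"", it$item_id, "\" is continuous", call. = FALSE)
  }
  a <- it$discrimination
  rf <- m$response
  top <- .support_top(it$support)
  rmax <- if (is.finite(top)) top else {
    r <- 0L
    while (prob_exceed(m, it, theta, r) > tail_tol && r < 1e6) r <- r + 1L
    r + 1L
  }
  rs <- 0:rmax
  dlo <- item_delta(it, rs - 1)
  dhi <- item_delta(it, rs)
  if (!is.finite(top)) dhi[length(dhi)] <- Inf  # absorb truncated tail
  pr <- .cdfd(rf, a, theta, dlo) - .cdfd(rf, a, theta, dhi)
  if (isTRUE(rf$symmetric)) {
    # survival form avoids cancellation when both cdf values are near one
    pr <- pmax(pr, .cdfd(rf, a, -theta, -dhi) - .cdfd(rf, a, -theta, -dlo))
  }
  if (any(pr <= 0)) {
    stop("zero probability in category ", rs[which(pr <= 0)[1]],
         " at theta = ", theta, call. = FALSE)
  }
  d1 <- a * (.densd(rf, a, theta, dlo) - .densd(rf, a, theta, dhi))
  if (form == "general") {
    d2 <- a^2 * (.densd1(rf, a, theta, dlo) - .densd1(rf, a, theta, dhi))
    sum((d1^2 - pr * d2) / pr)
  } else {
    if (!is.finite(top)) {
      stop("the finite-category form needs a finite support", call. = FALSE)
    }
    sum(d1[-1]^2 / pr[-1]) + sum(d1[-1])^2 / pr[1]
  }
}

# F, f, f' at eta = a(theta - d) with the +-infinity conventions
.cdfd <- function(rf, a, theta, d) {
  out <- ifelse(is.infinite(d), ifelse(d > 0, 0, 1),
                rf$cdf(a * (theta - d)))
  out
}
.densd <- function(rf, a, theta, d) {
  ifelse(is.infinite(d), 0, rf$density(a * (theta - d)))
}
.densd1 <- function(rf, a, theta, d) {
  ifelse(is.infinite(d), 0, rf$density_d1(a * (theta - d)))
}

#' Observed information for continuous items
#'
#' Closed form of the negative second derivative of the item log-likelihood
#' with respect to \eqn{\theta}:
#' \deqn{I_{obs}(\theta, y) = \alpha^2\left[\left(\frac{f'(\eta)}{f(\eta)}
#'   \right)^2 - \frac{f''(\eta)}{f(\eta)}\right],\quad
#'   \eta = \alpha(\theta - \delta(y)).}
#' For the normal response function this is \eqn{\alpha^2} regardless of
#' \eqn{y} and \eqn{\theta}.
#'
#' @inheritParams item_information_discrete
#' @param y Observed response.
#' @return Observed information value.
#' @export
observed_information_continuous <- function(m, item, theta, y) {
  it <- .get_item(m, item)
  if (is_discrete_item(it)) {
    stop("item \"", it$item_id, "\" is discrete", call. = FALSE)
  }
  a <- it$discrimination
  eta <- a * (theta - delta_eval(it$difficulty, y))
  a^2 * (.dlogf(m$response, eta)^2 - .d2ratio(m$response, eta))
}

#' Expected information for continuous items
#'
#' Numerical integral of the observed information over the implied response
#' distribution at \eqn{\theta}.  Integration runs on the response-function
#' scale (\eqn{\eta = \alpha(\theta - \delta(Y))} has density \eqn{f}), so
#' the result does not depend on the difficulty function.
#'
#' @inheritParams item_information_discrete
#' @return Nonnegative expected information.
#' @export
expected_information_continuous <- function(m, item, theta) {
  it <- .get_item(m, item)
  if (is_discrete_item(it)) {
    stop("item \"", it$item_id, "\" is discrete", call. = FALSE)
  }
  a <- it$discrimination
  rf <- m$response
  stats::integrate(function(eta) {
    a^2 * (.dlogf(rf, eta)^2 * rf$density(eta) - rf$density_d2(eta))
  }, -Inf, Inf, rel.tol = 1e-10)$value
}

#' Test information
#'
#' Sum of the per-item information values (expected information for
#' continuous items, Fisher information for discrete ones) at `theta`.
#'
#' @param m A `thresholds_model`.
#' @param theta Ability value (scalar).
#' @return Total information.
#' @export
test_information <- function(m, theta) {
  sum(vapply(m$items, function(it) {
    if (is_discrete_item(it)) {
      item_information_discrete(m, it, theta)
    } else {
      expected_information_continuous(m, it, theta)
    }
  }, numeric(1)))
}

#' Information curves over an ability grid
#'
#' @param m A `thresholds_model`.
#' @param thetas Ability grid.
#' @return Data frame in long format: `item`, `theta`, `information`.
#' @export
information_curves <- function(m, thetas) {
  out <- lapply(m$items, function(it) {
    info <- vapply(thetas, function(th) {
      if (is_discrete_item(it)) item_information_discrete(m, it, th)
      else expected_information_continuous(m, it, th)
    }, numeric(1))
    data.frame(item = it$item_id, theta = thetas, information = info)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
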