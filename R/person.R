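# per-item log density/pmf of one response vector at a grid of abilities
.person_logdens <- function(m, responses, thetas) {
  ll <- rep(0, length(thetas))
  n_obs <- 0L
  for (i in seq_along(m$items)) {
    y <- responses[[i]]
    if (is.na(y)) next
    n_obs <- n_obs + 1L
    it <- m$items[[i]]
    ll <- ll + if (is_discrete_item(it)) {
      log(pmax(pmf_discrete(m, it, thetas, y), 1e-300))
    } else {
      log(pmax(density_continuous(m, it, thetas, y), 1e-300))
    }
  }
  attr(ll, "n_obs") <- n_obs
  ll
}

.align_responses <- function(m, responses) {
  ids <- names(m$items)
  if (!is.null(names(responses))) {
    responses <- responses[ids]
  } else if (length(responses) != length(ids)) {
    stop("need one response per item (use item-id names for partial vectors)",
         call. = FALSE)
  }
  as.numeric(responses)
}

#' Posterior density of the person parameter
#'
#' Given fitted item parameters, the posterior of \eqn{\theta} for a
#' response vector \eqn{y} is the product of the per-item densities (pmf for
#' discrete items, density for continuous ones) with the
#' \eqn{N(0, \sigma_\theta^2)} prior, normalized by the Gauss-Hermite
#' approximated marginal.  Missing responses are skipped; with no observed
#' responses the prior is returned (with a warning).
#'
#' @param m A `thresholds_model`.
#' @param responses Response vector, one value per item (named or in item
#'   order); `NA` = missing.
#' @param theta Evaluation point(s).
#' @param nodes Gauss-Hermite nodes for the normalizer.
#' @return Posterior density values at `theta`.
#' @export
posterior_density <- function(m, responses, theta, nodes = 61) {
  responses <- .align_responses(m, responses)
  ll <- .person_logdens(m, responses, theta)
  if (attr(ll, "n_obs") == 0L) {
    warning("no observed responses; returning the prior density")
    return(stats::dnorm(theta, 0, m$sigma_theta))
  }
  rule <- gh_rule(nodes)
  t_q <- sqrt(2) * m$sigma_theta * rule$nodes
  w_q <- rule$weights / sqrt(pi)
  marg <- sum(w_q * exp(.person_logdens(m, responses, t_q)))
  exp(ll) * stats::dnorm(theta, 0, m$sigma_theta) / marg
}

#' Person parameter estimates (EAP, MAP, posterior SD)
#'
#' EAP is the posterior mean computed by Gauss-Hermite quadrature; MAP is
#' the posterior mode from a one-dimensional derivative-free maximization;
#' the posterior SD comes from the second posterior moment.
#'
#' @inheritParams posterior_density
#' @return A list with `theta_eap`, `theta_map`, `posterior_sd` and
#'   `n_observed`.
#' @export
score_person <- function(m, responses, nodes = 61) {
  responses <- .align_responses(m, responses)
  rule <- gh_rule(nodes)
  t_q <- sqrt(2) * m$sigma_theta * rule$nodes
  w_q <- rule$weights / sqrt(pi)
  ll <- .person_logdens(m, responses, t_q)
  n_obs <- attr(ll, "n_obs")
  if (n_obs == 0L) {
    warning("no observed responses; returning the prior")
    return(list(theta_eap = 0, theta_map = 0,
                posterior_sd = m$sigma_theta, n_observed = 0L))
  }
  wpost <- w_q * exp(ll - max(ll))
  wpost <- wpost / sum(wpost)
  eap <- sum(wpost * t_q)
  psd <- sqrt(max(sum(wpost * t_q^2) - eap^2, 0))
  lim <- 6 * m$sigma_theta
  map <- stats::optimize(function(th) {
    .person_logdens(m, responses, th) + stats::dnorm(th, 0, m$sigma_theta,
                                                     log = TRUE)
  }, interval = c(-lim, lim), maximum = TRUE)$maximum
  list(theta_eap = eap, theta_map = map, posterior_sd = psd,
       n_observed = n_obs)
}

#' Score all persons of a response matrix
#'
#' @param m A `thresholds_model`.
#' @param data Persons x items response matrix.
#' @param nodes Gauss-Hermite nodes.
#' @return Data frame with one row per person: `theta_eap`, `theta_map`,
#'   `posterior_sd`, `n_observed`.
#' @export
score_persons <- function(m, data, nodes = 61) {
  data <- .check_data(data, m$items)
  rows <- lapply(seq_len(nrow(data)), function(p) {
    as.data.frame(score_person(m, data[p, ], nodes = nodes))
  })
  do.call(rbind, rows)
}
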