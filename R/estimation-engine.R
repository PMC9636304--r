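# Internal marginal-likelihood engine.
#
# The marginal likelihood integrates the person parameter out against
# N(0, sigma_theta^2).  The integral is standardized to the current sigma at
# every evaluation: with probabilists' substitution theta = sqrt(2) sigma x,
#   int g(theta) phi_sigma(theta) dtheta ~ sum_q w_q/sqrt(pi) g(sqrt(2) sigma x_q)
# so the Gauss-Hermite nodes track the latent scale and sigma's score
# contribution comes through d theta_q / d sigma = theta_q / sigma.
#
# Every difficulty family is linear in its natural parameters
# (delta(y) = Phi(y)^T delta), so the per-item basis matrices at the observed
# responses are precomputed once per fit; a likelihood or score evaluation is
# then a handful of dense P x Q matrix operations per item.

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights of the physicists' Gauss-Hermite rule
#' \eqn{\int e^{-x^2} f(x) dx \approx \sum_q w_q f(x_q)}; the weights sum to
#' \eqn{\sqrt\pi}.  Used for all marginal integrals over the latent trait.
#'
#' @param n_nodes Number of nodes (default 61).
#' @return List with `nodes`, `weights` and `n_nodes`.
#' @export
gh_rule <- function(n_nodes = 61) {
  stopifnot(n_nodes >= 2)
  gh <- pracma::gaussHermite(as.integer(n_nodes))
  list(nodes = gh$x, weights = gh$w, n_nodes = as.integer(n_nodes))
}

# validate a response matrix against the items; returns matrix with columns
# in item order
.check_data <- function(data, items) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("responses must be numeric", call. = FALSE)
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (!is.null(colnames(data))) {
    missing_cols <- setdiff(ids, colnames(data))
    if (length(missing_cols)) {
      stop("response matrix lacks columns for item(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    data <- data[, ids, drop = FALSE]
  } else if (ncol(data) != length(ids)) {
    stop("response matrix has ", ncol(data), " columns but the model has ",
         length(ids), " items", call. = FALSE)
  } else {
    colnames(data) <- ids
  }
  for (j in seq_along(items)) {
    y <- data[, j]
    obs <- !is.na(y)
    bad <- obs & !support_contains(items[[j]]$support, y)
    if (any(bad)) {
      stop("response of person ", which(bad)[1], " on item \"", ids[j],
           "\" (value ", y[which(bad)[1]], ") is outside the item support",
           call. = FALSE)
    }
  }
  data
}

# per-item precomputation that does not depend on parameter values
.precompute_item <- function(item, y) {
  obs <- !is.na(y)
  d <- item$difficulty
  if (is_discrete_item(item)) {
    top <- .support_top(item$support)
    ysafe <- ifelse(obs, y, 0)
    ylo <- ysafe - 1
    yhi <- ysafe
    list(discrete = TRUE, obs = obs, y = ysafe,
         lo_inf = ylo < 0, hi_inf = is.finite(top) & yhi >= top,
         B_lo = .delta_basis(d, ylo, top, discrete = TRUE),
         B_hi = .delta_basis(d, yhi, top, discrete = TRUE))
  } else {
    safe <- switch(item$support$kind,
      positive = 1, unit_interval = mean(item$support$bounds), 0)
    ysafe <- ifelse(obs, y, safe)
    list(discrete = FALSE, obs = obs, y = ysafe,
         B = .delta_basis(d, ysafe), Bp = .delta_basis_deriv(d, ysafe))
  }
}

.engine_new <- function(items, rf, data, rule, X = NULL,
                        dif_items = integer(0)) {
  data <- .check_data(data, items)
  if (length(dif_items)) {
    X <- as.matrix(X)
    if (nrow(X) != nrow(data)) {
      stop("covariate rows must align with response rows", call. = FALSE)
    }
    if (any(apply(X, 2, stats::sd) < 1e-12)) {
      stop("constant covariate column: confounded with the item intercept",
           call. = FALSE)
    }
    if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
      stop("collinear covariates in the DIF configuration", call. = FALSE)
    }
  }
  pre <- lapply(seq_along(items), function(j) {
    .precompute_item(items[[j]], data[, j])
  })
  list(items = items, rf = rf, data = data, rule = rule, pre = pre,
       X = X, dif_items = dif_items, P = nrow(data))
}

# Evaluate marginal log-likelihood (and analytic score if grad = TRUE) at the
# given natural parameter state.
#   pars:   list of per-item natural difficulty parameter vectors
#   alphas: per-item discrimination vector
#   sigma:  latent scale
#   gammas: list (aligned with eng$dif_items) of covariate effect vectors
.engine_eval <- function(eng, pars, alphas, sigma, gammas = NULL,
                         grad = FALSE) {
  rf <- eng$rf
  P <- eng$P
  t_q <- sqrt(2) * sigma * eng$rule$nodes
  w_q <- eng$rule$weights / sqrt(pi)
  Q <- length(t_q)
  I <- length(eng$items)

  item_cache <- vector("list", I)
  LL <- matrix(0, P, Q)
  for (j in seq_len(I)) {
    pj <- eng$pre[[j]]
    a <- alphas[j]
    s <- rep(0, P)
    kdif <- match(j, eng$dif_items)
    if (!is.na(kdif)) s <- drop(eng$X %*% gammas[[kdif]])
    if (pj$discrete) {
      dlo <- drop(pj$B_lo %*% pars[[j]]); dlo[pj$lo_inf] <- -Inf
      dhi <- drop(pj$B_hi %*% pars[[j]]); dhi[pj$hi_inf] <- Inf
      ETA_lo <- a * outer(s - dlo, t_q, "+")
      ETA_hi <- a * outer(s - dhi, t_q, "+")
      pm <- rf$cdf(ETA_lo) - rf$cdf(ETA_hi)
      if (isTRUE(rf$symmetric)) {
        # survival form is accurate where both cdf values approach one
        pm <- pmax(pm, rf$cdf(-ETA_hi) - rf$cdf(-ETA_lo))
      }
      pm <- pmax(pm, 1e-300)
      lf <- log(pm)
      lf[!pj$obs, ] <- 0
      item_cache[[j]] <- list(ETA_lo = ETA_lo, ETA_hi = ETA_hi, pm = pm,
                              s = s, dlo = dlo, dhi = dhi)
    } else {
      dv <- drop(pj$B %*% pars[[j]])
      dd <- drop(pj$Bp %*% pars[[j]])
      E <- a * outer(s - dv, t_q, "+")
      lf <- log(pmax(rf$density(E), 1e-300)) + log(a) +
        log(pmax(dd, 1e-300))
      lf[!pj$obs, ] <- 0
      item_cache[[j]] <- list(E = E, dv = dv, dd = dd, s = s)
    }
    LL <- LL + lf
  }

  mrow <- apply(LL, 1, max)
  W0 <- exp(LL - mrow)
  cp <- drop(W0 %*% w_q)
  loglik <- sum(mrow + log(cp))
  if (!grad) return(list(loglik = loglik))

  # posterior weights: W[p, q] = w_q f(y_p | theta_q) / c_p, rows sum to 1
  W <- sweep(W0, 2, w_q, "*") / cp

  g_diff <- vector("list", I)
  g_alpha <- numeric(I)
  g_gamma <- if (length(eng$dif_items)) {
    lapply(gammas, function(g) numeric(length(g)))
  } else NULL
  sig_acc <- numeric(Q)

  for (j in seq_len(I)) {
    pj <- eng$pre[[j]]
    cc <- item_cache[[j]]
    a <- alphas[j]
    obs <- pj$obs
    kdif <- match(j, eng$dif_items)
    if (pj$discrete) {
      f_lo <- rf$density(cc$ETA_lo)
      f_hi <- rf$density(cc$ETA_hi)
      U <- W * (a * f_lo / cc$pm); U[!obs, ] <- 0
      V <- W * (a * f_hi / cc$pm); V[!obs, ] <- 0
      g_diff[[j]] <- drop(-crossprod(pj$B_lo, rowSums(U)) +
                            crossprod(pj$B_hi, rowSums(V)))
      # alpha score: (theta - delta) f terms, vanishing at +-infinite delta
      TH <- outer(cc$s, t_q, "+")
      Tlo <- (TH - cc$dlo) * f_lo; Tlo[is.infinite(cc$dlo), ] <- 0
      Thi <- (TH - cc$dhi) * f_hi; Thi[is.infinite(cc$dhi), ] <- 0
      Ra <- (Tlo - Thi) / cc$pm; Ra[!obs, ] <- 0
      g_alpha[j] <- sum(W * Ra)
      Rt <- a * (f_lo - f_hi) / cc$pm; Rt[!obs, ] <- 0
    } else {
      r <- .dlogf(rf, cc$E)
      wr <- rowSums(W * r)
      g <- -a * drop(crossprod(pj$B[obs, , drop = FALSE], wr[obs])) +
        drop(crossprod(pj$Bp[obs, , drop = FALSE], 1 / cc$dd[obs]))
      g_diff[[j]] <- g
      TH <- outer(cc$s, t_q, "+")
      Ra <- (TH - cc$dv) * r + 1 / a; Ra[!obs, ] <- 0
      g_alpha[j] <- sum(W * Ra)
      Rt <- a * r; Rt[!obs, ] <- 0
    }
    WRt <- W * Rt
    if (!is.na(kdif)) {
      g_gamma[[kdif]] <- drop(crossprod(eng$X, rowSums(WRt)))
    }
    sig_acc <- sig_acc + colSums(WRt)
  }
  g_sigma <- sum(sig_acc * t_q / sigma)
  list(loglik = loglik,
       grads = list(diff = g_diff, alpha = g_alpha, gamma = g_gamma,
                    sigma = g_sigma))
}
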