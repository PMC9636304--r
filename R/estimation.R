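# Parameter layout: maps between the natural item parameters, a flat named
# natural vector (reported to users; covariance lives here), and the
# unconstrained vector handed to the optimizer.  Transforms: intercepts and
# covariate effects are unconstrained; slopes, discriminations and
# sigma_theta are log-transformed; free-ordinal thresholds and B-spline
# coefficients use an increment reparameterization (first value free, each
# further value = previous + exp(u)), which keeps them ordered.

.build_layout <- function(items, vary_alpha = FALSE, common_slope = FALSE,
                          dif_items = integer(0), n_covariates = 0L) {
  blocks <- list()
  names_nat <- character(0)
  pos <- 0L
  add <- function(block, nm) {
    block$nat_idx <- pos + seq_along(nm)
    pos <<- pos + length(nm)
    names_nat <<- c(names_nat, nm)
    blocks[[length(blocks) + 1L]] <<- block
  }
  slope_block <- list()  # family -> block index (common-slope grouping)
  for (i in seq_along(items)) {
    it <- items[[i]]
    id <- it$item_id
    fam <- it$difficulty$family
    if (fam == "binary") {
      add(list(kind = "ident", role = "diff", items = i, par_idx = 1L),
          paste0(id, ".delta0"))
    } else if (fam %in% .parametric_families) {
      add(list(kind = "ident", role = "diff", items = i, par_idx = 1L),
          paste0(id, ".delta0"))
      if (common_slope) {
        bi <- slope_block[[fam]]
        if (is.null(bi)) {
          add(list(kind = "log", role = "diff", items = i, par_idx = 2L),
              paste0("slope.", fam))
          slope_block[[fam]] <- length(blocks)
        } else {
          blocks[[bi]]$items <- c(blocks[[bi]]$items, i)
          blocks[[bi]]$par_idx <- c(blocks[[bi]]$par_idx, 2L)
        }
      } else {
        add(list(kind = "log", role = "diff", items = i, par_idx = 2L),
            paste0(id, ".delta"))
      }
    } else {
      k <- n_difficulty_params(it$difficulty)
      lab <- if (fam == "free_ordinal") "d" else "b"
      add(list(kind = "ordered", role = "diff", items = i,
               par_idx = seq_len(k)),
          paste0(id, ".", lab, seq_len(k)))
    }
  }
  if (vary_alpha && length(items) > 1L) {
    for (i in seq_along(items)[-1L]) {
      add(list(kind = "log", role = "alpha", items = i),
          paste0("alpha.", items[[i]]$item_id))
    }
  }
  for (k in seq_along(dif_items)) {
    add(list(kind = "ident", role = "gamma", dif_idx = k),
        paste0("gamma.", items[[dif_items[k]]]$item_id, ".x",
               seq_len(n_covariates)))
  }
  add(list(kind = "log", role = "sigma"), "sigma_theta")
  list(blocks = blocks, names = names_nat, npar = pos)
}

# natural vector from a parameter state
.pack_nat <- function(layout, state) {
  v <- numeric(layout$npar)
  for (b in layout$blocks) {
    v[b$nat_idx] <- switch(b$role,
      diff = if (b$kind == "ordered") {
        state$pars[[b$items]]
      } else state$pars[[b$items[1]]][b$par_idx[1]],
      alpha = state$alphas[b$items],
      gamma = state$gammas[[b$dif_idx]],
      sigma = state$sigma)
  }
  v
}

# parameter state from a natural vector
.unpack_nat <- function(layout, v, template) {
  state <- template
  for (b in layout$blocks) {
    val <- v[b$nat_idx]
    switch(b$role,
      diff = {
        if (b$kind == "ordered") {
          state$pars[[b$items]] <- val
        } else {
          for (m in seq_along(b$items)) {
            state$pars[[b$items[m]]][b$par_idx[m]] <- val
          }
        }
      },
      alpha = state$alphas[b$items] <- val,
      gamma = state$gammas[[b$dif_idx]] <- val,
      sigma = state$sigma <- val)
  }
  state
}

.u_from_nat <- function(layout, v) {
  u <- v
  for (b in layout$blocks) {
    x <- v[b$nat_idx]
    u[b$nat_idx] <- switch(b$kind,
      ident = x,
      log = log(x),
      ordered = c(x[1], log(pmax(diff(x), 1e-8))))
  }
  u
}

.nat_from_u <- function(layout, u) {
  v <- u
  for (b in layout$blocks) {
    x <- u[b$nat_idx]
    v[b$nat_idx] <- switch(b$kind,
      ident = x,
      log = exp(x),
      ordered = cumsum(c(x[1], exp(x[-1]))))
  }
  v
}

# chain rule: gradient in natural space -> gradient in unconstrained space
.chain_to_u <- function(layout, g_nat, v_nat) {
  g_u <- g_nat
  for (b in layout$blocks) {
    g <- g_nat[b$nat_idx]
    x <- v_nat[b$nat_idx]
    g_u[b$nat_idx] <- switch(b$kind,
      ident = g,
      log = g * x,
      ordered = {
        cs <- rev(cumsum(rev(g)))
        c(cs[1], cs[-1] * diff(x))
      })
  }
  g_u
}

# assemble the natural score vector from the engine's per-role gradients
.score_nat <- function(layout, grads) {
  g <- numeric(layout$npar)
  for (b in layout$blocks) {
    g[b$nat_idx] <- switch(b$role,
      diff = if (b$kind == "ordered") {
        grads$diff[[b$items]]
      } else sum(vapply(seq_along(b$items), function(m) {
        grads$diff[[b$items[m]]][b$par_idx[m]]
      }, numeric(1))),
      alpha = grads$alpha[b$items],
      gamma = grads$gamma[[b$dif_idx]],
      sigma = grads$sigma)
  }
  g
}

# shape penalty for common-basis B-spline difficulties: penalizes, across
# neighbouring items, differences of adjacent-coefficient increments; large
# lambda forces all items' difficulty functions to identical shape up to a
# shift
.shape_penalty <- function(pars, lambda, grad = FALSE) {
  Dm <- t(vapply(pars, diff, numeric(length(pars[[1]]) - 1L)))
  if (nrow(Dm) < 2L || lambda == 0) {
    if (!grad) return(0)
    return(list(value = 0, grads = lapply(pars, function(p) numeric(length(p)))))
  }
  E <- Dm[-1L, , drop = FALSE] - Dm[-nrow(Dm), , drop = FALSE]
  val <- lambda * sum(E^2)
  if (!grad) return(val)
  # d val / d D[i, l]
  gD <- matrix(0, nrow(Dm), ncol(Dm))
  gD[-1L, ] <- gD[-1L, ] + 2 * lambda * E
  gD[-nrow(Dm), ] <- gD[-nrow(Dm), ] - 2 * lambda * E
  grads <- lapply(seq_along(pars), function(i) {
    g <- numeric(length(pars[[i]]))
    g[-1L] <- g[-1L] + gD[i, ]
    g[-length(g)] <- g[-length(g)] - gD[i, ]
    g
  })
  list(value = val, grads = grads)
}

.spline_par_idx <- function(items) {
  which(vapply(items, function(it) it$difficulty$family == "bspline",
               logical(1)))
}

.check_common_basis <- function(items) {
  idx <- .spline_par_idx(items)
  if (length(idx) != length(items)) {
    stop("the shape penalty requires all items to use a B-spline difficulty",
         call. = FALSE)
  }
  nb <- vapply(items, function(it) it$difficulty$n_basis, integer(1))
  if (length(unique(nb)) != 1L) {
    stop("the shape penalty requires a common B-spline basis across items",
         call. = FALSE)
  }
  invisible(idx)
}

.state_from_model <- function(m) {
  list(pars = lapply(m$items, function(it) .difficulty_params(it$difficulty)),
       alphas = vapply(m$items, `[[`, numeric(1), "discrimination"),
       gammas = NULL, sigma = m$sigma_theta)
}

#' Marginal log-likelihood of a thresholds model
#'
#' Sum over persons of the log of the Gauss-Hermite approximated integral
#' \eqn{\int \prod_i f_{pi}(y_{pi})\, \phi_{\sigma_\theta}(\theta)\,
#' d\theta}, where each item contributes its continuous density or discrete
#' pmf; mixed formats are handled natively and missing responses simply drop
#' out of the product.
#'
#' @param m A `thresholds_model` whose item parameters are the evaluation
#'   point.
#' @param data Persons x items response matrix (columns matched to item ids
#'   when named).
#' @param nodes Number of Gauss-Hermite nodes.
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(m, data, nodes = 61) {
  stopifnot(inherits(m, "thresholds_model"))
  eng <- .engine_new(m$items, m$response, data, gh_rule(nodes))
  st <- .state_from_model(m)
  .engine_eval(eng, st$pars, st$alphas, st$sigma)$loglik
}

#' Analytic score of the marginal log-likelihood
#'
#' Gradient of [marginal_loglik()] with respect to all natural item
#' parameters (difficulty parameters, discriminations and
#' \eqn{\sigma_\theta}), assembled from the analytic integrand derivatives
#' on the quadrature grid.
#'
#' @inheritParams marginal_loglik
#' @return Named numeric gradient vector.
#' @export
score_function <- function(m, data, nodes = 61) {
  stopifnot(inherits(m, "thresholds_model"))
  eng <- .engine_new(m$items, m$response, data, gh_rule(nodes))
  st <- .state_from_model(m)
  ev <- .engine_eval(eng, st$pars, st$alphas, st$sigma, grad = TRUE)
  out <- c()
  for (i in seq_along(m$items)) {
    id <- m$items[[i]]$item_id
    g <- ev$grads$diff[[i]]
    names(g) <- paste0(id, ".d", seq_along(g))
    out <- c(out, g, stats::setNames(ev$grads$alpha[i], paste0("alpha.", id)))
  }
  c(out, sigma_theta = ev$grads$sigma)
}

#' Penalized marginal log-likelihood
#'
#' For models in which every item uses a common B-spline basis, subtracts
#' the shape penalty
#' \eqn{P_\lambda = \lambda \sum_{i\ge 2} \sum_l [(\delta_{il} -
#' \delta_{i,l-1}) - (\delta_{i-1,l} - \delta_{i-1,l-1})]^2}
#' from the marginal log-likelihood.  With \eqn{\lambda = 0} this is the
#' plain log-likelihood; as \eqn{\lambda \to \infty} adjacent-coefficient
#' increments are forced equal across items, i.e. all difficulty functions
#' share one shape and differ only by shifts.
#'
#' @inheritParams marginal_loglik
#' @param lambda Non-negative penalty weight.
#' @return Penalized log-likelihood (scalar).
#' @export
penalized_loglik <- function(m, data, lambda, nodes = 61) {
  stopifnot(lambda >= 0)
  if (lambda > 0) .check_common_basis(m$items)
  st <- .state_from_model(m)
  marginal_loglik(m, data, nodes) - .shape_penalty(st$pars, lambda)
}

.default_control <- function(control) {
  utils::modifyList(list(maxit = 500L, reltol = 1e-12, grad_tol = 1e-5,
                         restarts = 2L), control)
}

# shared optimizer core for fit_mml and fit_dif
.fit_core <- function(eng, layout, template, v0, lambda = 0, se = TRUE,
                      control = list(), verbose = FALSE) {
  control <- .default_control(control)
  sp_idx <- if (lambda > 0) .check_common_basis(eng$items) else integer(0)

  eval_nat <- function(v, grad = FALSE) {
    st <- .unpack_nat(layout, v, template)
    ev <- .engine_eval(eng, st$pars, st$alphas, st$sigma, st$gammas,
                       grad = grad)
    if (lambda > 0) {
      pen <- .shape_penalty(st$pars, lambda, grad = grad)
      if (grad) {
        ev$loglik <- ev$loglik - pen$value
        for (i in seq_along(pen$grads)) {
          ev$grads$diff[[i]] <- ev$grads$diff[[i]] - pen$grads[[i]]
        }
      } else {
        ev$loglik <- ev$loglik - pen
      }
    }
    ev
  }
  n_iter <- 0L
  fn <- function(u) {
    n_iter <<- n_iter + 1L
    -eval_nat(.nat_from_u(layout, u))$loglik
  }
  gr <- function(u) {
    v <- .nat_from_u(layout, u)
    ev <- eval_nat(v, grad = TRUE)
    -.chain_to_u(layout, .score_nat(layout, ev$grads), v)
  }

  # Newton polish on the analytic gradient: BFGS stops once function-value
  # changes fall below floating-point resolution, which can leave the score
  # norm above tolerance; a few Newton steps with a finite-difference
  # Hessian of the score finish the job.
  polish <- function(u) {
    for (step in 1:5) {
      g <- gr(u)
      if (max(abs(g)) < control$grad_tol) break
      n <- length(u)
      H <- matrix(0, n, n)
      h <- 1e-5 * pmax(abs(u), 1)
      for (j in seq_len(n)) {
        up <- u; up[j] <- up[j] + h[j]
        um <- u; um[j] <- um[j] - h[j]
        H[, j] <- (gr(up) - gr(um)) / (2 * h[j])
      }
      H <- (H + t(H)) / 2
      du <- tryCatch(-solve(H, g), error = function(e) NULL)
      if (is.null(du)) break
      # backtrack on the score norm
      ok <- FALSE
      lam <- 1
      for (bt in 1:6) {
        u_new <- u + lam * du
        if (max(abs(gr(u_new))) < max(abs(g))) { ok <- TRUE; break }
        lam <- lam / 2
      }
      if (!ok) break
      u <- u_new
    }
    u
  }

  u <- .u_from_nat(layout, v0)
  opt <- NULL
  for (trial in 0:control$restarts) {
    opt <- stats::optim(u, fn, gr, method = "BFGS",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    u <- opt$par
    gnorm <- max(abs(gr(u)))
    if (gnorm >= control$grad_tol) {
      u <- polish(u)
      gnorm <- max(abs(gr(u)))
    }
    if (verbose) {
      message(sprintf("pass %d: loglik %.6f, max|grad| %.3g",
                      trial + 1L, -fn(u), gnorm))
    }
    if (gnorm < control$grad_tol) break
  }
  v_hat <- .nat_from_u(layout, u)
  ev <- eval_nat(v_hat, grad = TRUE)
  gnorm <- max(abs(.chain_to_u(layout, .score_nat(layout, ev$grads), v_hat)))
  converged <- gnorm < control$grad_tol

  cov <- NULL
  if (se) {
    score_at <- function(v) {
      .score_nat(layout, eval_nat(v, grad = TRUE)$grads)
    }
    H <- matrix(NA_real_, layout$npar, layout$npar)
    h <- 1e-5 * pmax(abs(v_hat), 1)
    for (j in seq_len(layout$npar)) {
      vp <- v_hat; vp[j] <- vp[j] + h[j]
      vm <- v_hat; vm[j] <- vm[j] - h[j]
      H[, j] <- (score_at(vp) - score_at(vm)) / (2 * h[j])
    }
    H <- (H + t(H)) / 2
    cov <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(cov)) dimnames(cov) <- list(layout$names, layout$names)
  }

  st <- .unpack_nat(layout, v_hat, template)
  list(state = st, v_hat = stats::setNames(v_hat, layout$names),
       loglik_pen = ev$loglik, cov = cov, converged = converged,
       gradient_norm = gnorm, n_iter = n_iter)
}

# data-driven starting values (intercepts from mean responses mapped through
# the difficulty transform; slopes and discriminations 1; sigma 1)
.start_items <- function(items, data, rf) {
  for (j in seq_along(items)) {
    it <- items[[j]]
    y <- data[, j]
    y <- y[!is.na(y)]
    if (!length(y)) next
    d <- it$difficulty
    items[[j]]$difficulty <- switch(d$family,
      binary = difficulty_binary(-rf$quantile(min(max(mean(y), 0.05), 0.95))),
      free_ordinal = {
        k <- length(d$ordinal_values)
        p_exceed <- vapply(seq_len(k), function(r) mean(y >= r), numeric(1))
        v <- -rf$quantile(pmin(pmax(p_exceed, 0.02), 0.98))
        v <- cummax(v + seq_len(k) * 1e-6)
        difficulty_free_ordinal(v)
      },
      bspline = {
        # map the empirical survival function through -F^{-1} at the
        # Greville abscissae of the basis, then isotonize
        kn <- d$knots
        grev <- vapply(seq_len(d$n_basis), function(l) {
          mean(kn[(l + 1):(l + 3)])
        }, numeric(1))
        sv <- vapply(grev, function(g) mean(y > g), numeric(1))
        v <- -rf$quantile(pmin(pmax(sv, 0.02), 0.98))
        v <- cummax(v + seq_along(v) * 1e-4)
        difficulty_bspline(v, d$range)
      },
      {
        ybar <- mean(y)
        ybar <- switch(d$family,
          log = max(ybar, 1e-3),
          inverse_cdf = min(max(ybar, d$bounds[1] + 1e-3 *
                                  diff(d$bounds)),
                            d$bounds[2] - 1e-3 * diff(d$bounds)),
          ybar)
        dd <- d
        dd$intercept <- -.g_eval(d, ybar) * d$slope
        dd
      })
  }
  items
}

#' Fit a thresholds model by marginal maximum likelihood
#'
#' Maximizes the Gauss-Hermite approximated marginal log-likelihood with a
#' quasi-Newton (BFGS) optimizer and analytic score functions, on an
#' unconstrained reparameterization (log slopes, log discriminations,
#' ordered-increment thresholds, log \eqn{\sigma_\theta}).
#'
#' Identifiability: when `vary_alpha = TRUE` the first item's discrimination
#' stays fixed at its supplied value (1 by convention) and
#' \eqn{\sigma_\theta} is free; with all discriminations fixed,
#' \eqn{\sigma_\theta} is free.  `common_slope = TRUE` ties the difficulty
#' slope across items sharing a parametric family.
#'
#' @param data Persons x items response matrix.
#' @param items List of [item_spec()] objects; their parameter values are
#'   used as starting values unless `start_from_data = TRUE` (default),
#'   which derives intercept-type starts from the observed responses.
#' @param response Response function or label.
#' @param vary_alpha Estimate per-item discriminations (first fixed)?
#' @param common_slope Tie difficulty slopes across items of the same
#'   parametric family?
#' @param sigma_start Starting value for \eqn{\sigma_\theta}.
#' @param nodes Gauss-Hermite nodes (default 61).
#' @param lambda Shape-penalty weight for common-basis B-spline models.
#' @param start_from_data Derive starting values from the data?
#' @param se Compute the observed-information covariance?
#' @param control Optimizer control: `maxit`, `reltol`, `grad_tol`
#'   (convergence is declared when the score max-norm falls below it),
#'   `restarts`.
#' @param verbose Print one line per optimizer pass?
#' @return An object of class `irt_fit` with elements `model` (fitted
#'   `thresholds_model`), `estimates` (named vector of natural parameters),
#'   `se`, `cov`, `loglik`, `n_params`, `aic`, `converged`,
#'   `gradient_norm`, `n_iter`.  Non-convergence is reported through
#'   `converged = FALSE`, not an error.
#' @export
fit_mml <- function(data, items, response = "normal", vary_alpha = FALSE,
                    common_slope = FALSE, sigma_start = 1, nodes = 61,
                    lambda = 0, start_from_data = TRUE, se = TRUE,
                    control = list(), verbose = FALSE) {
  if (inherits(items, "irt_item")) items <- list(items)
  rf <- if (is.character(response)) response_function(response) else response
  data <- .check_data(data, items)
  if (start_from_data) items <- .start_items(items, data, rf)
  eng <- .engine_new(items, rf, data, gh_rule(nodes))
  layout <- .build_layout(items, vary_alpha = vary_alpha,
                          common_slope = common_slope)
  template <- list(
    pars = lapply(items, function(it) .difficulty_params(it$difficulty)),
    alphas = vapply(items, `[[`, numeric(1), "discrimination"),
    gammas = NULL, sigma = sigma_start)
  v0 <- .pack_nat(layout, template)
  # under a common slope the shared start is the mean of the item slopes
  for (b in layout$blocks) {
    if (b$role == "diff" && b$kind == "log" && length(b$items) > 1L) {
      v0[b$nat_idx] <- mean(vapply(b$items, function(i) {
        template$pars[[i]][2]
      }, numeric(1)))
    }
  }
  core <- .fit_core(eng, layout, template, v0, lambda = lambda, se = se,
                    control = control, verbose = verbose)
  .make_fit(core, eng, layout, items, rf, lambda, nodes,
            match.call())
}

.make_fit <- function(core, eng, layout, items, rf, lambda, nodes, call) {
  st <- core$state
  fitted_items <- items
  for (i in seq_along(items)) {
    fitted_items[[i]]$difficulty <-
      .difficulty_set_params(items[[i]]$difficulty, st$pars[[i]])
    fitted_items[[i]]$discrimination <- st$alphas[i]
  }
  model <- thresholds_model(fitted_items, rf, st$sigma)
  # unpenalized log-likelihood at the optimum (covariate effects included)
  loglik <- .engine_eval(eng, st$pars, st$alphas, st$sigma, st$gammas)$loglik
  se_vec <- if (!is.null(core$cov)) {
    d <- diag(core$cov)
    sqrt(ifelse(d > 0, d, NA_real_))
  } else rep(NA_real_, layout$npar)
  names(se_vec) <- layout$names
  structure(list(model = model, estimates = core$v_hat, se = se_vec,
                 cov = core$cov, loglik = loglik, n_params = layout$npar,
                 aic = -2 * loglik + 2 * layout$npar,
                 gammas = st$gammas, dif_items = eng$dif_items,
                 converged = core$converged,
                 gradient_norm = core$gradient_norm, n_iter = core$n_iter,
                 nodes = nodes, lambda = lambda, call = call),
            class = "irt_fit")
}

#' @export
print.irt_fit <- function(x, ...) {
  cat("Thresholds model fit (marginal ML, ", x$nodes, " GH nodes)\n",
      sep = "")
  cat("  log-likelihood: ", format(x$loglik, nsmall = 3), "   AIC: ",
      format(x$aic, nsmall = 3), "   parameters: ", x$n_params, "\n",
      sep = "")
  cat("  converged: ", x$converged, " (max|score| = ",
      format(x$gradient_norm, digits = 3), ", ", x$n_iter,
      " evaluations)\n\n", sep = "")
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' @export
logLik.irt_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @export
coef.irt_fit <- function(object, ...) object$estimates

#' @export
vcov.irt_fit <- function(object, ...) object$cov

#' Likelihood-ratio test between nested fits
#'
#' @param full Fit of the larger model.
#' @param reduced Fit of the nested model.
#' @return List with `statistic` \eqn{= 2(\ell_f - \ell_r)}, `df` (parameter
#'   count difference) and `p_value`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "irt_fit"), inherits(reduced, "irt_fit"))
  stat <- 2 * (full$loglik - reduced$loglik)
  df <- full$n_params - reduced$n_params
  if (df < 0) stop("the first argument must be the larger model",
                   call. = FALSE)
  if (stat < -1e-6) {
    stop("the full model fits worse than the reduced model; check nesting ",
         "and convergence", call. = FALSE)
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE)
                 else NA_real_)
}
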