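#' Fit a thresholds model with differential item functioning terms
#'
#' For items under test, the person parameter is replaced by
#' \eqn{\theta_p + x_p^T\gamma_i} inside the response function,
#' \eqn{P(Y > y) = F(\alpha_i(\theta_p + x_p^T\gamma_i - \delta_i(y)))};
#' \eqn{\gamma_i \ne 0} indicates DIF in item \eqn{i}.  All other items keep
#' \eqn{\gamma_i = 0}.  Constant or collinear covariate columns are rejected
#' at configuration time (a constant column is confounded with the item
#' intercept).
#'
#' @inheritParams fit_mml
#' @param covariates Persons x q numeric covariate matrix, rows aligned with
#'   `data`.
#' @param items_under_test Item ids (or indices) receiving free \eqn{\gamma}
#'   vectors; by default items are tested one at a time via
#'   [test_dif_item()].
#' @return An `irt_fit`; the fitted covariate effects are in
#'   `$gammas` (named by item) and in the estimate vector as
#'   `gamma.<item>.<x>`.
#' @export
fit_dif <- function(data, items, covariates, items_under_test,
                    response = "normal", vary_alpha = FALSE,
                    common_slope = FALSE, sigma_start = 1, nodes = 61,
                    start_from_data = TRUE, se = TRUE, control = list(),
                    verbose = FALSE) {
  if (inherits(items, "irt_item")) items <- list(items)
  rf <- if (is.character(response)) response_function(response) else response
  data <- .check_data(data, items)
  X <- as.matrix(covariates)
  ids <- vapply(items, `[[`, character(1), "item_id")
  dif_idx <- if (is.numeric(items_under_test)) {
    as.integer(items_under_test)
  } else {
    match(as.character(items_under_test), ids)
  }
  if (anyNA(dif_idx) || !length(dif_idx)) {
    stop("items_under_test must name items of the model", call. = FALSE)
  }
  if (start_from_data) items <- .start_items(items, data, rf)
  eng <- .engine_new(items, rf, data, gh_rule(nodes), X = X,
                     dif_items = dif_idx)
  layout <- .build_layout(items, vary_alpha = vary_alpha,
                          common_slope = common_slope, dif_items = dif_idx,
                          n_covariates = ncol(X))
  template <- list(
    pars = lapply(items, function(it) .difficulty_params(it$difficulty)),
    alphas = vapply(items, `[[`, numeric(1), "discrimination"),
    gammas = rep(list(numeric(ncol(X))), length(dif_idx)),
    sigma = sigma_start)
  v0 <- .pack_nat(layout, template)
  core <- .fit_core(eng, layout, template, v0, se = se, control = control,
                    verbose = verbose)
  fit <- .make_fit(core, eng, layout, items, rf, lambda = 0, nodes = nodes,
                   match.call())
  names(fit$gammas) <- ids[dif_idx]
  fit
}

#' Likelihood-ratio test for DIF in one item
#'
#' Fits the baseline model (\eqn{\gamma_i = 0}) and the DIF model with a
#' free \eqn{\gamma_i} for the given item, and tests
#' \eqn{H_0: \gamma_i = 0} with a likelihood-ratio test on `q` degrees of
#' freedom.
#'
#' @inheritParams fit_dif
#' @param item Item id (or index) to test.
#' @param baseline_fit Optional pre-computed baseline `irt_fit` (saves
#'   refitting when several items are tested against the same baseline).
#' @return List with `statistic`, `df`, `p_value`, `gamma` (the estimated
#'   effect) and the two fits.
#' @export
test_dif_item <- function(data, items, covariates, item,
                          response = "normal", vary_alpha = FALSE,
                          common_slope = FALSE, nodes = 61,
                          baseline_fit = NULL, control = list()) {
  if (is.null(baseline_fit)) {
    baseline_fit <- fit_mml(data, items, response = response,
                            vary_alpha = vary_alpha,
                            common_slope = common_slope, nodes = nodes,
                            se = FALSE, control = control)
  }
  alt <- fit_dif(data, items, covariates, items_under_test = item,
                 response = response, vary_alpha = vary_alpha,
                 common_slope = common_slope, nodes = nodes, se = FALSE,
                 control = control)
  test <- lrt(alt, baseline_fit)
  list(statistic = test$statistic, df = test$df, p_value = test$p_value,
       gamma = alt$gammas[[1]], fit_alt = alt, fit_null = baseline_fit)
}

#' Item-by-item DIF screen
#'
#' Runs [test_dif_item()] for each requested item against one shared
#' baseline fit and adjusts the p-values for multiple testing
#' (Benjamini-Hochberg by default).
#'
#' @inheritParams fit_dif
#' @param items_under_test Item ids to screen (default: all).
#' @param alpha_level Flagging level applied to the adjusted p-values.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()].
#' @return Data frame with one row per tested item: `item`, `statistic`,
#'   `df`, `p_value`, `p_adjusted`, `flagged`.
#' @export
dif_screen <- function(data, items, covariates, items_under_test = NULL,
                       response = "normal", vary_alpha = FALSE,
                       common_slope = FALSE, nodes = 61, alpha_level = 0.05,
                       p_adjust = "BH", control = list()) {
  if (inherits(items, "irt_item")) items <- list(items)
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (is.null(items_under_test)) items_under_test <- ids
  base <- fit_mml(data, items, response = response, vary_alpha = vary_alpha,
                  common_slope = common_slope, nodes = nodes, se = FALSE,
                  control = control)
  rows <- lapply(items_under_test, function(id) {
    tt <- test_dif_item(data, items, covariates, id, response = response,
                        vary_alpha = vary_alpha, common_slope = common_slope,
                        nodes = nodes, baseline_fit = base, control = control)
    data.frame(item = id, statistic = tt$statistic, df = tt$df,
               p_value = tt$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out$flagged <- out$p_adjusted < alpha_level
  out
}
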