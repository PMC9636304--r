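test_that("GH marginal log-likelihood matches a fine-grid trapezoid oracle", {
  m <- mixed_model()
  dat <- generate_dataset(m, 20, seed = 42)$responses
  dat[3, 2] <- NA
  ll <- marginal_loglik(m, dat, nodes = 61)
  expect_lt(abs(ll - trapezoid_loglik(m, dat)), 1e-6)
  # invariant to item order
  perm <- c(3, 1, 4, 2)
  m2 <- thresholds_model(m$items[perm], m$response, m$sigma_theta)
  expect_equal(marginal_loglik(m2, dat[, perm], nodes = 61), ll,
               tolerance = 1e-12)
})

test_that("the Gauss-Hermite approximation is converged at the default resolution", {
  sim <- simulate_preset("count", seed = 7)
  fit <- fit_mml(sim$responses, sim$model$items, nodes = 41, se = FALSE)
  expect_lt(abs(marginal_loglik(fit$model, sim$responses, nodes = 41) -
                marginal_loglik(fit$model, sim$responses, nodes = 81)), 1e-6)
  # mixed formats have sharper continuous densities and need the 61-node
  # default; at that resolution doubling the nodes changes nothing material
  m <- mixed_model()
  dat <- generate_dataset(m, 80, seed = 42)$responses
  fit2 <- fit_mml(dat, m$items, nodes = 61, se = FALSE)
  expect_lt(abs(marginal_loglik(fit2$model, dat, nodes = 61) -
                marginal_loglik(fit2$model, dat, nodes = 121)), 1e-6)
})

test_that("a degenerate latent distribution reduces to the fixed-theta likelihood", {
  m <- thresholds_model(
    item_spec("b", support_binary(), difficulty_binary(0)), "normal",
    sigma_theta = 1e-8)
  expect_equal(marginal_loglik(m, matrix(1, 1, 1, dimnames = list(NULL, "b"))),
               log(0.5), tolerance = 1e-8)
})

test_that("the analytic score matches finite differences on a mixed dataset", {
  m <- mixed_model()
  dat <- generate_dataset(m, 30, seed = 9)$responses
  dat[c(2, 11), 3] <- NA
  sc <- score_function(m, dat, nodes = 61)
  num <- numeric_score(m, dat, nodes = 61)
  expect_lt(max(abs(sc - num) / pmax(abs(num), 1e-3)), 1e-5)
  # logistic response too
  ml <- mixed_model("logistic", sigma = 0.9)
  sc <- score_function(ml, dat, nodes = 61)
  num <- numeric_score(ml, dat, nodes = 61)
  expect_lt(max(abs(sc - num) / pmax(abs(num), 1e-3)), 1e-5)
})

test_that("score components of an all-missing item vanish", {
  m <- mixed_model()
  dat <- generate_dataset(m, 15, seed = 2)$responses
  dat[, "cnt"] <- NA
  sc <- score_function(m, dat)
  expect_equal(unname(sc[c("cnt.d1", "cnt.d2", "alpha.cnt")]), rep(0, 3))
})

test_that("the score is small at the generating parameters of a large sample", {
  p <- preset_model("count")
  for (seed in 1:3) {
    dat <- generate_dataset(p$model, 1000, seed = seed)$responses
    sc <- score_function(p$model, dat)
    expect_lt(max(abs(sc)) / 1000, 0.5)
  }
})

test_that("fit_mml recovers parameters and is a fixed point of refitting", {
  sim <- simulate_preset("count", seed = 7)
  fit <- fit_mml(sim$responses, sim$model$items, se = TRUE)
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-5)
  expect_identical(fit$n_params, 11L)  # 5 intercepts + 5 slopes + sigma
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  truth <- c(vapply(sim$model$items, function(it) {
    c(it$difficulty$intercept, it$difficulty$slope)
  }, numeric(2)))
  est <- unname(fit$estimates[1:10])
  expect_lt(max(abs(est - truth)), 0.6)
  # refitting from the optimum does not move the log-likelihood
  refit <- fit_mml(sim$responses, fit$model$items, sigma_start =
                     fit$model$sigma_theta, start_from_data = FALSE,
                   se = FALSE)
  expect_lt(abs(refit$loglik - fit$loglik), 1e-6)
})

test_that("common-slope fits tie slopes and are nested in varying-slope fits", {
  sim <- simulate_preset("count", seed = 12)
  f_var <- fit_mml(sim$responses, sim$model$items, se = FALSE)
  f_com <- fit_mml(sim$responses, sim$model$items, common_slope = TRUE,
                   se = FALSE)
  expect_identical(f_com$n_params, 7L)  # 5 intercepts + 1 slope + sigma
  slopes <- vapply(f_com$model$items, function(it) it$difficulty$slope,
                   numeric(1))
  expect_equal(unname(slopes), rep(slopes[[1]], 5))
  tst <- lrt(f_var, f_com)
  expect_identical(tst$df, 4L)
  expect_gte(tst$statistic, 0)
  # identical fits give a null test
  tst0 <- lrt(f_var, f_var)
  expect_equal(tst0$statistic, 0)
  expect_identical(tst0$df, 0L)
})

test_that("varying discriminations separate alpha from intercepts and slopes", {
  p <- preset_model("count")
  items <- p$model$items
  alphas <- c(1, 1.4, 0.7, 1.2, 0.9)
  for (i in seq_along(items)) items[[i]]$discrimination <- alphas[i]
  m <- thresholds_model(items, "normal", 1)
  ests <- sapply(1:4, function(seed) {
    dat <- generate_dataset(m, 400, seed = 100 + seed)$responses
    fit <- fit_mml(dat, p$model$items, vary_alpha = TRUE, se = FALSE)
    fit$estimates[paste0("alpha.item", 2:5)]
  })
  expect_gt(cor(rowMeans(ests), alphas[2:5]), 0.7)
})

test_that("AIC bookkeeping counts free parameters plus sigma", {
  fit <- list(loglik = -1445.832, n_params = 13L)
  expect_equal(-2 * fit$loglik + 2 * fit$n_params, 2917.664)
  expect_equal(-2 * 0 + 2 * 0, 0)
  sim <- simulate_preset("count", n_persons = 60, seed = 3)
  f1 <- fit_mml(sim$responses, sim$model$items, se = FALSE)
  expect_equal(AIC(f1), f1$aic)
  expect_equal(unclass(logLik(f1)), f1$loglik, ignore_attr = TRUE)
})

test_that("the shape penalty vanishes at lambda 0 or equal coefficients and shows in fits", {
  rng <- c(0, 4)
  items <- lapply(1:3, function(i) {
    item_spec(paste0("s", i), support_ordinal(5),
              difficulty_bspline(seq(-2, 2, length.out = 5) + 0.4 * i, rng))
  })
  m <- thresholds_model(items, "normal", 1)
  dat <- generate_dataset(m, 80, seed = 4)$responses
  expect_equal(penalized_loglik(m, dat, lambda = 0),
               marginal_loglik(m, dat))
  # identical shapes (shifted coefficients) have zero penalty
  expect_equal(penalized_loglik(m, dat, lambda = 1e5),
               marginal_loglik(m, dat))
  items_mix <- items
  items_mix[[2]] <- item_spec("s2", support_ordinal(5),
                              difficulty_bspline(c(-2, -1, 0, 2, 3), rng))
  m2 <- thresholds_model(items_mix, "normal", 1)
  expect_lt(penalized_loglik(m2, dat, lambda = 10),
            marginal_loglik(m2, dat))
  # mixed bases are a configuration error
  m3 <- thresholds_model(list(items[[1]],
    item_spec("t", support_ordinal(5), difficulty_log1p(0, 1))), "normal", 1)
  expect_error(penalized_loglik(m3, dat[, 1:2], lambda = 1), "B-spline")
})

test_that("nesting violations in lrt are caught", {
  sim <- simulate_preset("count", n_persons = 50, seed = 8)
  f <- fit_mml(sim$responses, sim$model$items, se = FALSE)
  g <- fit_mml(sim$responses, sim$model$items, common_slope = TRUE,
               se = FALSE)
  expect_error(lrt(g, f), "larger model")
})
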