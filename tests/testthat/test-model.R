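test_that("prob_exceed implements F(alpha (theta - delta(y)))", {
  it <- item_spec("x", support_real(), difficulty_linear(0, 1))
  m <- thresholds_model(it, "normal", 1)
  expect_equal(prob_exceed(m, "x", theta = 0, y = 0), 0.5)
  expect_equal(prob_exceed(m, "x", theta = 2, y = 0), pnorm(2))
  expect_equal(prob_exceed(m, "x", theta = 2, y = 0), 0.97725,
               tolerance = 1e-5)
  # discrete item at y = -1 has probability one
  mm <- mixed_model()
  expect_equal(prob_exceed(mm, "ord", theta = 0.3, y = -1), 1)
  expect_equal(prob_exceed(mm, "bin", theta = -5, y = 1), 0)
  expect_error(prob_exceed(mm, "nope", 0, 0), "unknown item")
})

test_that("latent monotonicity: non-increasing in y, non-decreasing in theta", {
  m <- mixed_model("logistic")
  th <- seq(-4, 4, length.out = 41)
  for (id in names(m$items)) {
    it <- m$items[[id]]
    ys <- if (irthresh:::is_discrete_item(it)) {
      0:(min(irthresh:::.support_top(it$support), 12))
    } else seq(-3, 3, length.out = 21)
    P <- sapply(ys, function(y) prob_exceed(m, id, th, y))
    expect_true(all(apply(P, 1, diff) <= 1e-12))   # in y
    expect_true(all(apply(P, 2, diff) >= -1e-12))  # in theta
  }
})

test_that("IC functions share the response-function shape and never cross under common alpha", {
  items <- list(
    item_spec("e", support_real(), difficulty_linear(-1, 0.8)),
    item_spec("h", support_real(), difficulty_linear(1.5, 1.4)))
  m <- thresholds_model(items, "normal", 1)
  th <- seq(-5, 5, length.out = 201)
  y <- 1
  ic_e <- ic_function(m, "e", y, th)
  ic_h <- ic_function(m, "h", y, th)
  expect_true(all(diff(ic_e) > 0))
  d <- ic_e - ic_h  # easier item dominates everywhere: curves do not cross
  expect_true(all(d > 0))
  expect_lt(ic_function(m, "e", y, -30), 1e-12)
  expect_gt(ic_function(m, "e", y, 30), 1 - 1e-12)
  expect_equal(ic_function(m, "e", 1, theta = delta_eval(m$items$e$difficulty, 1)),
               0.5)
})

test_that("cdf complements prob_exceed and recovers closed forms", {
  it <- item_spec("x", support_real(), difficulty_linear(0, 1))
  m <- thresholds_model(it, "normal", 1)
  y <- seq(-3, 3, length.out = 25)
  expect_equal(model_cdf(m, "x", 0.3, y) + prob_exceed(m, "x", 0.3, y),
               rep(1, 25))
  # with linear delta(y) = y and alpha = 1 the response is standard normal
  # around theta
  expect_equal(model_cdf(m, "x", 0, y), pnorm(y), tolerance = 1e-12)
  itl <- item_spec("p", support_positive(), difficulty_log(0, 1))
  ml <- thresholds_model(itl, "normal", 1)
  expect_lt(model_cdf(ml, "p", 0, 1e-9), 1e-12)
})

test_that("continuous densities match the implied normal and log-normal closed forms", {
  # linear difficulty: Y ~ N((theta - d0)/d, 1/(alpha d))
  it <- item_spec("x", support_real(), difficulty_linear(2, 3), 1.4)
  m <- thresholds_model(it, "normal", 1)
  theta <- 0.5
  y <- seq(-2, 1.5, length.out = 41)
  mu <- (theta - 2) / 3
  expect_equal(density_continuous(m, "x", theta, y),
               dnorm(y, mu, 1 / (1.4 * 3)), tolerance = 1e-12)
  m0 <- thresholds_model(item_spec("z", support_real(),
                                   difficulty_linear(0, 1)), "normal", 1)
  expect_equal(density_continuous(m0, "z", 0, 0), dnorm(0),
               tolerance = 1e-12)  # 0.39894
  # log difficulty: Y is log-normal
  itl <- item_spec("p", support_positive(), difficulty_log(-0.4, 1.7), 1.2)
  ml <- thresholds_model(itl, "normal", 1)
  yy <- seq(0.05, 6, length.out = 60)
  mu_bar <- (theta + 0.4) / 1.7
  sd_bar <- 1 / (1.2 * 1.7)
  expect_equal(density_continuous(ml, "p", theta, yy),
               dlnorm(yy, mu_bar, sd_bar), tolerance = 1e-12)
  mq <- thresholds_model(item_spec("q", support_positive(),
                                   difficulty_log(0, 1)), "normal", 1)
  expect_equal(density_continuous(mq, "q", 0, 1), dnorm(0),
               tolerance = 1e-12)  # log-normal density at y = 1
  # densities integrate to one
  for (mm in list(list(m, "x"), list(ml, "p"))) {
    tot <- stats::integrate(function(z) {
      density_continuous(mm[[1]], mm[[2]], theta, z)
    }, if (mm[[2]] == "p") 1e-10 else -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(tot, 1, tolerance = 1e-6)
  }
  expect_error(density_continuous(mixed_model(), "bin", 0, 0), "discrete")
})

test_that("discrete pmf is the telescoping difference of exceedance probabilities", {
  bin <- thresholds_model(
    item_spec("b", support_binary(), difficulty_binary(0)), "normal", 1)
  expect_equal(pmf_discrete(bin, "b", 0, 1), 0.5)
  # binary reduction: P(Y = 1) = F(alpha (theta - delta0)) exactly
  bin2 <- thresholds_model(
    item_spec("b", support_binary(), difficulty_binary(0.6), 1.7),
    "logistic", 1)
  th <- seq(-3, 3, length.out = 21)
  expect_equal(pmf_discrete(bin2, "b", th, 1), plogis(1.7 * (th - 0.6)))
  # ordinal logistic example
  ord <- thresholds_model(
    item_spec("o", support_ordinal(2), difficulty_free_ordinal(c(-1, 1))),
    "logistic", 1)
  expect_equal(pmf_discrete(ord, "o", 0, 0:2),
               c(0.26894, 0.46212, 0.26894), tolerance = 1e-5)
  expect_equal(sum(pmf_discrete(ord, "o", 0.7, 0:2)), 1, tolerance = 1e-12)
  # graded-response reduction: P(Y >= r) = F(alpha (theta - delta_r))
  ord2 <- thresholds_model(
    item_spec("o", support_ordinal(3),
              difficulty_free_ordinal(c(-1, 0.2, 1.4)), 1.3), "normal", 1)
  for (r in 1:3) {
    expect_equal(prob_exceed(ord2, "o", th, r - 1),
                 pnorm(1.3 * (th - c(-1, 0.2, 1.4)[r])))
  }
  # count pmf sums to one (numerically)
  cnt <- mixed_model()
  expect_equal(sum(pmf_discrete(cnt, "cnt", 1.2, 0:1000)), 1,
               tolerance = 1e-12)
  expect_error(pmf_discrete(cnt, "ord", 0, 9), "outside the support")
  expect_error(pmf_discrete(cnt, "cont", 0, 1), "continuous")
})

test_that("linear_moments matches closed form and Monte Carlo", {
  it <- item_spec("x", support_real(), difficulty_linear(2, 3), 1)
  m <- thresholds_model(it, "normal", 1)
  mom <- linear_moments(m, "x", theta = 0.5)
  expect_equal(mom[["mean"]], -0.5)
  expect_equal(mom[["variance"]], 1 / 9, tolerance = 1e-8)
  # symmetric F with unit slope and alpha: E(Y) = theta - delta0
  it2 <- item_spec("y", support_real(), difficulty_linear(0.8, 1), 1)
  m2 <- thresholds_model(it2, "logistic", 1)
  expect_equal(linear_moments(m2, "y", 1.3)[["mean"]], 1.3 - 0.8)
  # doubling alpha quarters the variance
  it4 <- item_spec("z", support_real(), difficulty_linear(0.8, 1), 2)
  m4 <- thresholds_model(it4, "logistic", 1)
  expect_equal(linear_moments(m4, "z", 0)[["variance"]],
               linear_moments(m2, "y", 0)[["variance"]] / 4)
  # Monte-Carlo cross-check for the logistic response
  set.seed(99)
  draws <- sample_continuous(it2, m2$response, rep(1.3, 1e5))
  mom2 <- linear_moments(m2, "y", 1.3)
  se_mean <- sqrt(mom2[["variance"]] / 1e5)
  expect_lt(abs(mean(draws) - mom2[["mean"]]), 4 * se_mean)
  se_var <- mom2[["variance"]] * sqrt(2 / 1e5) * 2  # conservative
  expect_lt(abs(var(draws) - mom2[["variance"]]), 4 * se_var)
  expect_error(linear_moments(mixed_model(), "cnt", 0), "linear")
})

test_that("categorization at any cut points yields the matching graded response model", {
  it <- item_spec("x", support_real(), difficulty_linear(-0.5, 1.3), 1.2)
  m <- thresholds_model(it, "normal", 1)
  taus <- c(-1, 0.2, 0.7, 1.5)
  cat_item <- categorize_item(m, "x", taus)
  expect_s3_class(cat_item, "irt_item")
  expect_identical(cat_item$support$kind, "ordinal")
  expect_equal(irthresh:::.difficulty_params(cat_item$difficulty),
               delta_eval(it$difficulty, taus))
  mc <- thresholds_model(cat_item, "normal", 1)
  th <- c(-1.5, 0, 0.8)
  bounds <- c(-Inf, taus, Inf)
  for (theta in th) {
    pmf <- pmf_discrete(mc, cat_item$item_id, theta, 0:length(taus))
    intervals <- diff(model_cdf(m, "x", theta,
                                pmin(pmax(bounds, -1e10), 1e10)))
    expect_equal(pmf, intervals, tolerance = 1e-12)
  }
  # a single threshold gives a binary item with P(Y=1) = F(alpha(theta - delta(tau)))
  b <- categorize_item(m, "x", 0.4)
  mb <- thresholds_model(b, "normal", 1)
  expect_equal(pmf_discrete(mb, b$item_id, 0.3, 1),
               pnorm(1.2 * (0.3 - delta_eval(it$difficulty, 0.4))),
               tolerance = 1e-12)
  expect_error(categorize_item(m, "x", c(1, 0)), "strictly increasing")
})
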