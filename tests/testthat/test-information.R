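test_that("binary logistic information reduces to pi0 * pi1", {
  m <- thresholds_model(
    item_spec("b", support_binary(), difficulty_binary(0.4)), "logistic", 1)
  # at theta = delta(0) both categories have probability one half
  expect_equal(item_information_discrete(m, "b", 0.4), 0.25,
               tolerance = 1e-12)
  th <- seq(-2, 2, length.out = 11)
  p1 <- pmf_discrete(m, "b", th, 1)
  info <- vapply(th, function(t) item_information_discrete(m, "b", t),
                 numeric(1))
  expect_equal(info, p1 * (1 - p1), tolerance = 1e-10)
})

test_that("general and finite-category information forms agree", {
  vals <- cumsum(c(-2.5, rep(0.55, 9)))  # 10-category item
  m <- thresholds_model(
    item_spec("o", support_ordinal(10), difficulty_free_ordinal(vals), 1.2),
    "normal", 1)
  for (th in seq(-3, 3, length.out = 13)) {
    expect_equal(item_information_discrete(m, "o", th, form = "general"),
                 item_information_discrete(m, "o", th, form = "finite"),
                 tolerance = 1e-10)
  }
})

test_that("information matches the curvature of the log-likelihood", {
  # discrete: compare with numeric expectation of -d2 log pmf
  m <- thresholds_model(
    item_spec("o", support_ordinal(4),
              difficulty_free_ordinal(c(-1.5, -0.4, 0.5, 1.6)), 1.3),
    "logistic", 1)
  th0 <- 0.6
  h <- 1e-4
  num <- sum(vapply(0:4, function(r) {
    f <- function(t) log(pmf_discrete(m, "o", t, r))
    -pmf_discrete(m, "o", th0, r) *
      (f(th0 + h) - 2 * f(th0) + f(th0 - h)) / h^2
  }, numeric(1)))
  expect_equal(item_information_discrete(m, "o", th0), num,
               tolerance = 1e-5)
  # continuous observed information vs finite differences of log density
  mc <- thresholds_model(
    item_spec("x", support_positive(), difficulty_log(0.3, 1.4), 1.2),
    "logistic", 1)
  for (y in c(0.5, 1, 3)) {
    f <- function(t) log(density_continuous(mc, "x", t, y))
    num <- -(f(th0 + h) - 2 * f(th0) + f(th0 - h)) / h^2
    expect_equal(observed_information_continuous(mc, "x", th0, y), num,
                 tolerance = 1e-4)
  }
})

test_that("normal response functions give constant observed information alpha^2", {
  m <- thresholds_model(
    item_spec("x", support_real(), difficulty_linear(0.2, 1.7), 2),
    "normal", 1)
  expect_equal(observed_information_continuous(m, "x", 0.3, 1.2), 4,
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:50) {
    expect_equal(observed_information_continuous(m, "x", rnorm(1), rnorm(1)),
                 4, tolerance = 1e-10)
  }
  m1 <- thresholds_model(
    item_spec("x", support_real(), difficulty_linear(0, 1), 1), "normal", 1)
  expect_equal(observed_information_continuous(m1, "x", 0.7, -0.3), 1,
               tolerance = 1e-12)
  expect_equal(expected_information_continuous(m, "x", 0.5), 4,
               tolerance = 1e-8)
})

test_that("logistic expected information is finite, positive and grid-stable", {
  m <- thresholds_model(
    item_spec("x", support_real(), difficulty_linear(0.2, 1.1), 1.3),
    "logistic", 1)
  v <- expected_information_continuous(m, "x", 0.4)
  expect_gt(v, 0)
  expect_true(is.finite(v))
  # independent trapezoid cross-check at two resolutions
  for (n in c(2001, 8001)) {
    y <- seq(-12, 12, length.out = n)
    f <- density_continuous(m, "x", 0.4, y)
    io <- observed_information_continuous(m, "x", 0.4, y)
    num <- sum((f * io)[-1] * diff(y))
    expect_equal(v, num, tolerance = 1e-4)
  }
  # test information adds over items
  mm <- mixed_model()
  expect_equal(test_information(mm, 0.3),
               sum(vapply(names(mm$items), function(id) {
                 it <- mm$items[[id]]
                 if (irthresh:::is_discrete_item(it)) {
                   item_information_discrete(mm, id, 0.3)
                 } else {
                   expected_information_continuous(mm, id, 0.3)
                 }
               }, numeric(1))))
})

test_that("information is translation invariant and ordered by difficulty and discrimination", {
  # shifting theta and the intercept together leaves information unchanged
  m <- function(d0) thresholds_model(
    item_spec("o", support_ordinal(9), difficulty_log1p(d0, 1), 1),
    "normal", 1)
  expect_equal(item_information_discrete(m(-3), "o", 0.5),
               item_information_discrete(m(-2), "o", 1.5), tolerance = 1e-10)
  # 10-category items, log1p difficulties, common intercept -3: the hardest
  # item (largest slope) peaks at larger theta; with varying alpha the most
  # discriminating item yields the largest information
  slopes <- c(1.2, 1.0, 0.8)
  th <- seq(-4, 6, length.out = 141)
  items <- lapply(1:3, function(i) {
    item_spec(paste0("i", i), support_ordinal(9),
              difficulty_log1p(-3, slopes[i]))
  })
  mf <- thresholds_model(items, "normal", 1)
  peaks <- vapply(1:3, function(i) {
    th[which.max(vapply(th, function(t) {
      item_information_discrete(mf, paste0("i", i), t)
    }, numeric(1)))]
  }, numeric(1))
  expect_true(peaks[1] > peaks[2] && peaks[2] > peaks[3])
  alphas <- c(1.2, 1.0, 0.8)
  items_a <- lapply(1:3, function(i) {
    item_spec(paste0("i", i), support_ordinal(9),
              difficulty_log1p(-3, slopes[i]), alphas[i])
  })
  ma <- thresholds_model(items_a, "normal", 1)
  maxima <- vapply(1:3, function(i) {
    max(vapply(th, function(t) {
      item_information_discrete(ma, paste0("i", i), t)
    }, numeric(1)))
  }, numeric(1))
  expect_true(maxima[1] > maxima[2] && maxima[2] > maxima[3])
})
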