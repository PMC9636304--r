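# Shared fixtures and independent oracles for the test suite.

# small mixed-format model used across tests: ordinal + continuous + count +
# binary items
mixed_model <- function(response = "normal", sigma = 1.1) {
  items <- list(
    item_spec("ord", support_ordinal(3),
              difficulty_free_ordinal(c(-1, 0, 1)), 1),
    item_spec("cont", support_real(), difficulty_linear(0.5, 1.2), 1.3),
    item_spec("cnt", support_count(), difficulty_log1p(-1, 1.5), 1),
    item_spec("bin", support_binary(), difficulty_binary(0.3), 0.8))
  thresholds_model(items, response, sigma)
}

# independent marginal log-likelihood oracle: fine-grid trapezoid over theta
trapezoid_loglik <- function(m, data, lim = 9, n_grid = 6001) {
  th <- seq(-lim, lim, length.out = n_grid)
  total <- 0
  for (p in seq_len(nrow(data))) {
    f <- rep(1, length(th))
    for (i in seq_along(m$items)) {
      y <- data[p, i]
      if (is.na(y)) next
      it <- m$items[[i]]
      f <- f * if (irthresh:::is_discrete_item(it)) {
        pmf_discrete(m, it, th, y)
      } else {
        density_continuous(m, it, th, y)
      }
    }
    f <- f * stats::dnorm(th, 0, m$sigma_theta)
    total <- total + log(sum((f[-1] + f[-length(f)]) / 2 * diff(th)))
  }
  total
}

# rebuild a model with one natural parameter perturbed; names follow
# score_function(): "<id>.d<j>", "alpha.<id>", "sigma_theta"
perturb_model <- function(m, name, h) {
  if (name == "sigma_theta") {
    m$sigma_theta <- m$sigma_theta + h
    return(m)
  }
  if (startsWith(name, "alpha.")) {
    id <- sub("^alpha\\.", "", name)
    m$items[[id]]$discrimination <- m$items[[id]]$discrimination + h
    return(m)
  }
  id <- sub("\\.d[0-9]+$", "", name)
  j <- as.integer(sub("^.*\\.d", "", name))
  par <- irthresh:::.difficulty_params(m$items[[id]]$difficulty)
  par[j] <- par[j] + h
  m$items[[id]]$difficulty <-
    irthresh:::.difficulty_set_params(m$items[[id]]$difficulty, par)
  m
}

numeric_score <- function(m, data, nodes = 61, h = 1e-6) {
  sc <- score_function(m, data, nodes = nodes)
  vapply(names(sc), function(nm) {
    (marginal_loglik(perturb_model(m, nm, h), data, nodes = nodes) -
       marginal_loglik(perturb_model(m, nm, -h), data, nodes = nodes)) /
      (2 * h)
  }, numeric(1))
}

# central finite difference of a scalar function
fd_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
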