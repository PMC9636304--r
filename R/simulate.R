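#' Sample a continuous response
#'
#' Uses the inverse construction implied by the model: with
#' \eqn{V \sim F}, the variable \eqn{Y = \delta^{-1}(\theta - V/\alpha)}
#' satisfies \eqn{P(Y > y) = F(\alpha(\theta - \delta(y)))} for every
#' \eqn{y}, because \eqn{\delta} is strictly increasing.
#'
#' @param item A continuous [item_spec()].
#' @param rf The model's response function.
#' @param theta Ability value(s); one draw is produced per element.
#' @return Numeric draws on the item's support.
#' @export
sample_continuous <- function(item, rf, theta) {
  if (is_discrete_item(item)) {
    stop("sample_continuous() needs a continuous item", call. = FALSE)
  }
  v <- rf$quantile(stats::runif(length(theta)))
  delta_inverse(item$difficulty, theta - v / item$discrimination)
}

#' Sample a discrete response
#'
#' Inversion sampling of the discrete pmf: a uniform draw is compared with
#' the cumulative category probabilities.  For count items the category walk
#' stops once the cumulative mass exceeds \eqn{1 - 10^{-12}}; the remainder
#' is assigned to the next category.
#'
#' @inheritParams sample_continuous
#' @param item A discrete [item_spec()].
#' @return Integer draws on the item's support.
#' @export
sample_discrete <- function(item, rf, theta) {
  if (!is_discrete_item(item)) {
    stop("sample_discrete() needs a discrete item", call. = FALSE)
  }
  a <- item$discrimination
  u <- stats::runif(length(theta))
  top <- .support_top(item$support)
  if (is.finite(top)) {
    # cdf at r is 1 - F(alpha (theta - delta(r))); compare against u
    out <- integer(length(theta))
    surv <- rep(1, length(theta))       # P(Y > r - 1)
    for (r in 0:top) {
      d <- item_delta(item, r)
      s_next <- rf$cdf(a * (theta - d)) # P(Y > r)
      if (is.infinite(d)) s_next[] <- if (d > 0) 0 else 1
      sel <- u > s_next & u <= surv
      out[sel] <- r
      surv <- s_next
    }
    out
  } else {
    out <- rep(NA_integer_, length(theta))
    r <- 0L
    repeat {
      s_next <- rf$cdf(a * (theta - item_delta(item, r)))
      sel <- is.na(out) & u > s_next
      out[sel] <- r
      if (!anyNA(out)) break
      # truncate the walk once the remaining upper-tail mass is negligible
      if (all(s_next[is.na(out)] < 1e-12)) { out[is.na(out)] <- r + 1L; break }
      r <- r + 1L
      if (r > 1e6) stop("count sampler failed to terminate", call. = FALSE)
    }
    out
  }
}

#' Simulate a dataset from a thresholds model
#'
#' Draws abilities \eqn{\theta_p \sim N(0, \sigma_\theta^2)} (or uses a
#' supplied vector) and simulates one response per person and item with the
#' per-item format honoured, using [sample_continuous()] and
#' [sample_discrete()].
#'
#' @param model A `thresholds_model`.
#' @param n_persons Number of persons (ignored when `theta` is given).
#' @param theta Optional fixed ability vector.
#' @param seed Optional integer seed; the seed fully determines the output.
#' @return A list with `responses` (persons x items matrix with item-id
#'   column names), `theta` (the generating abilities) and `model`.
#' @export
generate_dataset <- function(model, n_persons, theta = NULL, seed = NULL) {
  stopifnot(inherits(model, "thresholds_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(theta)) {
    theta <- stats::rnorm(n_persons, 0, model$sigma_theta)
  }
  n <- length(theta)
  resp <- matrix(NA_real_, n, length(model$items),
                 dimnames = list(NULL, names(model$items)))
  for (j in seq_along(model$items)) {
    it <- model$items[[j]]
    resp[, j] <- if (is_discrete_item(it)) {
      sample_discrete(it, model$response, theta)
    } else {
      sample_continuous(it, model$response, theta)
    }
  }
  list(responses = resp, theta = theta, model = model)
}

#' Simulation presets
#'
#' Ready-made generating models for simulation studies and examples:
#'
#' * `"person_recovery"`: 10 continuous items with linear difficulties,
#'   intercepts \eqn{\delta_{0i} = -2.25 + (i-1)\,0.5}, slopes
#'   `(1,1,1,1,2,2,2,2,3,3)`, \eqn{\alpha_i = 1}, \eqn{\sigma_\theta = 1} -
#'   the person-parameter recovery design;
#' * `"count"`: 5 count items with `log1p` difficulties and varying slopes,
#'   \eqn{\sigma_\theta = 1}, intended for `P = 200` persons - the item
#'   recovery design for count data;
#' * `"cognition"`: 6 ordinal rating items (7 categories, internally
#'   `{0..6}`) with linear difficulty functions; intercepts and slopes are
#'   the published varying-slopes estimates for a 194-child self-regulation
#'   rating scale, and item 2 carries discrimination 1.630 with the matching
#'   reparameterized intercept/slope pair; synthetic stand-in for that
#'   rating dataset;
#' * `"fears"`: 5 ordinal rating items (7 categories) with logarithmic
#'   difficulties at published estimates for a political-fears survey
#'   sample of 200; synthetic stand-in;
#' * `"fluency"`: 4 count items with `log1p` difficulties emulating verbal
#'   fluency tasks of 202 participants (one-minute word counts),
#'   \eqn{\sigma_\theta = 1.09}; synthetic stand-in;
#' * `"mixed"`: the cognition model with items 1 and 5 collapsed to three
#'   categories at thresholds 4 and 6 of the 1-7 rating scale - a
#'   mixed-format test.
#'
#' The rating presets are conveniences whose parameters make the synthetic
#' data resemble the corresponding applications; they are not the real data.
#'
#' @param name Preset label.
#' @return A list with `model`, the intended `n_persons`, and `shift`
#'   (the offset between internal `{0..k}` coding and the original response
#'   labels, e.g. 1 for 1-7 rating scales).
#' @export
preset_model <- function(name = c("person_recovery", "count", "cognition",
                                  "fears", "fluency", "mixed")) {
  name <- match.arg(name)
  norm <- response_function("normal")
  out <- switch(name,
    person_recovery = {
      int <- -2.25 + (0:9) * 0.5
      slp <- c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3)
      items <- lapply(1:10, function(i) {
        item_spec(paste0("item", i), support_real(),
                  difficulty_linear(int[i], slp[i]))
      })
      list(model = thresholds_model(items, norm, 1), n_persons = 100,
           shift = 0)
    },
    count = {
      int <- c(-2.0, -2.8, -3.4, -2.4, -3.0)
      slp <- c(1.4, 1.8, 2.2, 1.2, 1.6)
      items <- lapply(1:5, function(i) {
        item_spec(paste0("item", i), support_count(),
                  difficulty_log1p(int[i], slp[i]))
      })
      list(model = thresholds_model(items, norm, 1), n_persons = 200,
           shift = 0)
    },
    cognition = {
      int <- c(-6.302662, -2.236756, -2.635715, -3.149895, -5.747873,
               -3.367810)
      slp <- c(1.1934046, 0.9694296, 0.8577245, 1.0391432, 1.0304311,
               1.5432459)
      alp <- c(1, 1.630, 1, 1, 1, 1)
      items <- lapply(1:6, function(i) {
        item_spec(paste0("item", i), support_ordinal(6),
                  difficulty_linear(int[i], slp[i]), alp[i])
      })
      list(model = thresholds_model(items, norm, 1.5), n_persons = 194,
           shift = 1)
    },
    fears = {
      int <- c(-4.840, -6.661, -7.569, -4.571, -5.716)
      slp <- c(3.056, 3.807, 4.093, 3.040, 3.400)
      items <- lapply(1:5, function(i) {
        item_spec(paste0("item", i), support_ordinal(6),
                  difficulty_log1p(int[i], slp[i]))
      })
      list(model = thresholds_model(items, norm, 1.5), n_persons = 200,
           shift = 1)
    },
    fluency = {
      int <- c(-7.8, -6.3, -6.9, -7.6)
      slp <- c(2.5, 2.4, 2.5, 2.5)
      items <- lapply(1:4, function(i) {
        item_spec(paste0("item", i), support_count(),
                  difficulty_log1p(int[i], slp[i]))
      })
      list(model = thresholds_model(items, norm, 1.09), n_persons = 202,
           shift = 0)
    },
    mixed = {
      cg <- preset_model("cognition")
      items <- cg$model$items
      # collapse items 1 and 5 at original-scale thresholds 4 and 6,
      # i.e. internal thresholds 3 and 5: categories 0 (<=4), 1 (5..6), 2 (7)
      for (i in c(1L, 5L)) {
        vals <- delta_eval(items[[i]]$difficulty, c(3, 5))
        items[[i]] <- item_spec(items[[i]]$item_id, support_ordinal(2),
                                difficulty_free_ordinal(vals),
                                items[[i]]$discrimination)
      }
      list(model = thresholds_model(items, norm, cg$model$sigma_theta),
           n_persons = 194, shift = NA)
    })
  out
}

#' Simulate from a preset
#'
#' Convenience wrapper: builds the preset model and simulates the preset's
#' sample size (or `n_persons`) with the given seed.
#'
#' @inheritParams preset_model
#' @param n_persons Optional override of the preset sample size.
#' @param seed Optional integer seed.
#' @return As [generate_dataset()], with the preset's `shift` attached.
#' @export
simulate_preset <- function(name, n_persons = NULL, seed = NULL) {
  p <- preset_model(name)
  n <- if (is.null(n_persons)) p$n_persons else n_persons
  out <- generate_dataset(p$model, n, seed = seed)
  out$shift <- p$shift
  out
}
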