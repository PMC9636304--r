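#' Read / write wide response matrices
#'
#' The primary data format is a wide CSV: a header row of item ids, one row
#' per person, empty cells for missing responses.
#'
#' @param path CSV file path.
#' @return `read_responses()`: a numeric persons x items matrix with item
#'   ids as column names.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (anyDuplicated(colnames(df))) {
    stop("duplicated item ids in ", path, ": ",
         paste(unique(colnames(df)[duplicated(colnames(df))]),
               collapse = ", "), call. = FALSE)
  }
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    stop("non-numeric responses in column \"", colnames(df)[bad[1]],
         "\" of ", path, call. = FALSE)
  }
  as.matrix(df)
}

#' @rdname read_responses
#' @param data Persons x items response matrix.
#' @export
write_responses <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert long-format responses to the wide matrix
#'
#' @param df Data frame with person, item and value columns.
#' @param person,item,value Column names.
#' @return Wide persons x items matrix.
#' @export
responses_from_long <- function(df, person = "person", item = "item",
                                value = "value") {
  stopifnot(all(c(person, item, value) %in% colnames(df)))
  persons <- unique(df[[person]])
  items <- unique(df[[item]])
  out <- matrix(NA_real_, length(persons), length(items),
                dimnames = list(NULL, as.character(items)))
  out[cbind(match(df[[person]], persons), match(df[[item]], items))] <-
    df[[value]]
  out
}

.default_family <- function(kind) {
  switch(kind, real = "linear", positive = "log",
         unit_interval = "inverse_cdf", count = "log1p", ordinal = "log1p",
         binary = "binary")
}

#' Read an item configuration file
#'
#' Parses a JSON or YAML item configuration (format chosen by file
#' extension).  The schema has a top-level `items` list; each entry has
#' `id`, `support` (`real`, `positive`, `unit_interval`, `binary`,
#' `ordinal`, `count`), plus `k` (ordinal), `bounds` (unit_interval),
#' optional `family` (defaulting by support: linear / log / inverse_cdf /
#' log1p), `n_basis` and `range` for B-splines, and the flags
#' `free_discrimination` and `common_slope`.  Top-level `response` and
#' `sigma_theta` are optional.
#'
#' @param path Configuration file (`.json`, `.yaml` or `.yml`).
#' @return An object of class `irt_item_config`.
#' @export
read_item_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  item_config(raw)
}

#' Build an item configuration from a list
#'
#' @param raw List with the schema of [read_item_config()].
#' @return Validated `irt_item_config`.
#' @export
item_config <- function(raw) {
  if (is.null(raw$items) || !length(raw$items)) {
    stop("item configuration needs a non-empty 'items' list", call. = FALSE)
  }
  items <- lapply(raw$items, function(e) {
    if (is.null(e$id) || is.null(e$support)) {
      stop("every item entry needs 'id' and 'support'", call. = FALSE)
    }
    e$support <- match.arg(e$support,
      c("real", "positive", "unit_interval", "binary", "ordinal", "count"))
    if (e$support == "ordinal" && is.null(e$k)) {
      stop("ordinal item \"", e$id, "\" needs 'k'", call. = FALSE)
    }
    if (e$support == "binary" && !is.null(e$family) &&
        e$family != "binary") {
      warning("binary item \"", e$id, "\": the difficulty transform is ",
              "irrelevant for binary items; 'family' ignored")
      e$family <- NULL
    }
    if (!is.null(e$slope) && e$support == "binary") {
      warning("binary item \"", e$id, "\": slope ignored")
      e$slope <- NULL
    }
    if (is.null(e$family)) e$family <- .default_family(e$support)
    e$free_discrimination <- isTRUE(e$free_discrimination)
    e$common_slope <- isTRUE(e$common_slope)
    e
  })
  ids <- vapply(items, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicated item ids in configuration",
                               call. = FALSE)
  structure(list(items = items,
                 response = raw$response %||na% "normal",
                 sigma_theta = raw$sigma_theta %||na% 1),
            class = "irt_item_config")
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Instantiate item specifications from a configuration
#'
#' Turns an `irt_item_config` into a list of [item_spec()] skeletons (unit
#' intercepts/slopes; [fit_mml()] replaces them with data-driven starting
#' values), plus the fit-level flags implied by the per-item entries.
#'
#' @param config An `irt_item_config`.
#' @param data Response matrix (needed to set B-spline knot ranges).
#' @return List with `items`, `vary_alpha`, `common_slope`, `response`,
#'   `sigma_theta`.
#' @export
items_from_config <- function(config, data = NULL) {
  stopifnot(inherits(config, "irt_item_config"))
  rf <- response_function(config$response)
  items <- lapply(config$items, function(e) {
    sup <- switch(e$support,
      real = support_real(), positive = support_positive(),
      unit_interval = support_unit(e$bounds %||na% c(0, 1)),
      binary = support_binary(), ordinal = support_ordinal(e$k),
      count = support_count())
    d <- switch(e$family,
      binary = difficulty_binary(0),
      linear = difficulty_linear(0, 1),
      log = difficulty_log(0, 1),
      log1p = difficulty_log1p(0, 1),
      adapted_logit = difficulty_adapted_logit(0, 1, k = e$k),
      inverse_cdf = difficulty_inverse_cdf(0, 1, a = e$a %||na% 1, rf = rf,
                                           bounds = e$bounds %||na% c(0, 1)),
      free_ordinal = difficulty_free_ordinal(seq(-1, 1, length.out = e$k)),
      bspline = {
        nb <- e$n_basis %||na% 6L
        rng <- e$range %||na% {
          if (e$support == "ordinal") c(0, e$k - 1) else {
            if (is.null(data)) stop("B-spline item \"", e$id,
                                    "\" needs 'range' or data", call. = FALSE)
            y <- data[, e$id]
            y <- y[!is.na(y)]
            if (e$support == "count") c(0, max(y)) else {
              eps <- 1e-3 * (max(y) - min(y))
              c(min(y) - eps, max(y) + eps)
            }
          }
        }
        difficulty_bspline(seq(-1.5, 1.5, length.out = nb), rng, sup)
      },
      stop("unknown difficulty family \"", e$family, "\" for item \"",
           e$id, "\"", call. = FALSE))
    item_spec(e$id, sup, d, 1)
  })
  list(items = items,
       vary_alpha = any(vapply(config$items, `[[`, logical(1),
                               "free_discrimination")),
       common_slope = any(vapply(config$items, `[[`, logical(1),
                                 "common_slope")),
       response = config$response, sigma_theta = config$sigma_theta)
}

# serializable description of a model (used by the fit report)
model_to_list <- function(m) {
  list(response = m$response$name, sigma_theta = m$sigma_theta,
       items = lapply(m$items, function(it) {
         d <- it$difficulty
         e <- list(id = it$item_id, support = it$support$kind,
                   family = d$family, discrimination = it$discrimination)
         if (!is.null(it$support$k)) e$k <- it$support$k
         if (!is.null(it$support$bounds)) e$bounds <- it$support$bounds
         e$params <- .difficulty_params(d)
         if (d$family == "bspline") e$range <- d$range
         if (d$family == "adapted_logit") e$logit_k <- d$k
         if (d$family == "inverse_cdf") {
           e$a <- d$a
           e$inv_bounds <- d$bounds
         }
         e
       }))
}

model_from_list <- function(x) {
  rf <- response_function(x$response)
  items <- lapply(x$items, function(e) {
    sup <- switch(e$support,
      real = support_real(), positive = support_positive(),
      unit_interval = support_unit(e$bounds), binary = support_binary(),
      ordinal = support_ordinal(e$k), count = support_count())
    p <- as.numeric(e$params)
    d <- switch(e$family,
      binary = difficulty_binary(p[1]),
      linear = difficulty_linear(p[1], p[2]),
      log = difficulty_log(p[1], p[2]),
      log1p = difficulty_log1p(p[1], p[2]),
      adapted_logit = difficulty_adapted_logit(p[1], p[2], k = e$logit_k),
      inverse_cdf = difficulty_inverse_cdf(p[1], p[2], a = e$a, rf = rf,
                                           bounds = e$inv_bounds),
      free_ordinal = difficulty_free_ordinal(p),
      bspline = difficulty_bspline(p, as.numeric(e$range), sup))
    item_spec(e$id, sup, d, e$discrimination)
  })
  thresholds_model(items, rf, x$sigma_theta)
}

#' Write / read a fit report
#'
#' Serializes an `irt_fit` to JSON: the full model description, natural
#' parameter estimates with standard errors, log-likelihood, AIC, parameter
#' count and the convergence block.  Reading the report back reconstructs
#' the fitted model and the numeric fields exactly (keys are written in a
#' stable order, so reports diff cleanly).
#'
#' @param fit An `irt_fit`.
#' @param path Output JSON path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "irt_fit"))
  rep <- list(
    model = model_to_list(fit$model),
    estimates = as.list(fit$estimates),
    se = as.list(fit$se),
    loglik = fit$loglik, n_params = fit$n_params, aic = fit$aic,
    nodes = fit$nodes, lambda = fit$lambda,
    convergence = list(converged = fit$converged,
                       gradient_norm = fit$gradient_norm,
                       n_iter = fit$n_iter))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_report
#' @return `read_fit_report()`: an object of class `irt_fit_report` - a
#'   list with the reconstructed `model` and the numeric report fields.
#' @export
read_fit_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  rep$model <- model_from_list(rep$model)
  rep$estimates <- unlist(rep$estimates)
  rep$se <- unlist(rep$se)
  class(rep) <- "irt_fit_report"
  rep
}
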