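#' Response supports
#'
#' A support specification describes the set of values an item's response can
#' take.  It drives which difficulty families are legal (see
#' [item_spec()]), whether the likelihood uses a density or a probability
#' mass function, and the boundary conventions \eqn{\delta(-1) = -\infty}
#' and, for finite discrete supports, \eqn{\delta(k) = +\infty}.
#'
#' * `support_real()` - continuous responses on the whole real line;
#' * `support_positive()` - continuous responses \eqn{y > 0};
#' * `support_unit(bounds)` - continuous responses in an open interval
#'   `(a, b)`, affinely identified with `(0, 1)`;
#' * `support_binary()` - responses in `{0, 1}`;
#' * `support_ordinal(k)` - ordered responses in `{0, ..., k}` (`k + 1`
#'   categories, `k >= 2`);
#' * `support_count()` - counts `{0, 1, 2, ...}`.
#'
#' @param bounds Numeric length-2 vector `(a, b)` with `a < b`.
#' @param k Number of thresholds of an ordinal item; responses live in
#'   `{0, ..., k}`.
#' @return An object of class `irt_support`.
#' @name supports
NULL

.support <- function(kind, k = NULL, bounds = NULL) {
  structure(list(kind = kind, k = k, bounds = bounds), class = "irt_support")
}

#' @rdname supports
#' @export
support_real <- function() .support("real")

#' @rdname supports
#' @export
support_positive <- function() .support("positive")

#' @rdname supports
#' @export
support_unit <- function(bounds = c(0, 1)) {
  stopifnot(is.numeric(bounds), length(bounds) == 2L, bounds[1] < bounds[2])
  .support("unit_interval", bounds = as.numeric(bounds))
}

#' @rdname supports
#' @export
support_binary <- function() .support("binary", k = 1L)

#' @rdname supports
#' @export
support_ordinal <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 2, k == round(k))
  .support("ordinal", k = as.integer(k))
}

#' @rdname supports
#' @export
support_count <- function() .support("count")

#' @export
print.irt_support <- function(x, ...) {
  extra <- switch(x$kind,
    ordinal = paste0(" {0..", x$k, "}"),
    unit_interval = paste0(" (", x$bounds[1], ", ", x$bounds[2], ")"),
    "")
  cat("<irt_support> ", x$kind, extra, "\n", sep = "")
  invisible(x)
}

is_discrete_support <- function(s) {
  s$kind %in% c("binary", "ordinal", "count")
}

# largest threshold index with a finite difficulty value, or Inf for counts
.support_top <- function(s) {
  switch(s$kind, binary = 1L, ordinal = s$k, count = Inf,
         stop("not a discrete support"))
}

# check observed values against the support; returns logical vector
support_contains <- function(s, y) {
  switch(s$kind,
    real = is.finite(y),
    positive = is.finite(y) & y > 0,
    unit_interval = is.finite(y) & y > s$bounds[1] & y < s$bounds[2],
    binary = y %in% c(0, 1),
    ordinal = y %in% 0:s$k,
    count = is.finite(y) & y >= 0 & y == round(y))
}
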