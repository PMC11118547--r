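#' Create a parameter vector for a one-hot model
#'
#' A `param_vec` is a tibble with columns `feature`, `order`, `value` (one
#' row per active feature, in the canonical feature order) carrying its
#' [model_spec()] as an attribute. It prints, filters, and joins like any
#' tibble, and round-trips through the TSV readers/writers.
#'
#' @param spec A [model_spec()].
#' @param values Parameter values: a numeric vector of length `M` in
#'   canonical feature order, a named numeric vector keyed by feature label
#'   (missing features default to 0), or a data frame with columns
#'   `feature` and `value`.
#' @return A `param_vec` tibble.
#' @examples
#' spec <- model_spec("01", 2, "additive")
#' theta <- param_vec(spec, rnorm(spec$M))
#' @export
param_vec <- function(spec, values = 0) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.data.frame(values)) {
    if (!all(c("feature", "value") %in% names(values))) {
      abort("A data-frame `values` needs columns `feature` and `value`.")
    }
    values <- setNames(as.numeric(values$value), values$feature)
  }
  if (!is.null(names(values))) {
    unknown <- setdiff(names(values), spec$features)
    if (base::length(unknown) > 0) {
      abort(sprintf("Feature \"%s\" is not active in this spec.", unknown[1]))
    }
    v <- setNames(rep(0, spec$M), spec$features)
    v[names(values)] <- as.numeric(values)
  } else {
    if (base::length(values) == 1) values <- rep(values, spec$M)
    if (base::length(values) != spec$M) {
      abort(sprintf(
        "`values` has length %d; the spec has M = %d features.",
        base::length(values), spec$M
      ))
    }
    v <- setNames(as.numeric(values), spec$features)
  }
  if (any(!is.finite(v))) abort("Parameter values must all be finite.")
  new_param_vec(spec, v)
}

new_param_vec <- function(spec, v, extra = NULL) {
  out <- tibble::tibble(
    feature = spec$features,
    order = spec$order,
    value = as.numeric(v)
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  structure(out,
    spec = spec,
    class = c("param_vec", class(tibble::tibble()))
  )
}

#' Extract the numeric parameter vector
#'
#' @param theta A `param_vec`.
#' @return Named numeric vector of length `M` in canonical feature order.
#' @export
pv_vector <- function(theta) {
  stopifnot(inherits(theta, "param_vec"))
  setNames(theta$value, theta$feature)
}

#' Extract the model spec of a parameter vector
#'
#' @param theta A `param_vec`.
#' @return The [model_spec()] attached to `theta`.
#' @export
pv_spec <- function(theta) {
  spec <- attr(theta, "spec")
  if (is.null(spec)) abort("This object carries no model spec.")
  spec
}

# replace values, keeping spec and any extra columns
pv_replace <- function(theta, v) {
  out <- theta
  out$value <- as.numeric(v)
  out
}

#' @export
print.param_vec <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf(
    "# A param_vec: M = %d features (alphabet {%s}, L = %d, %s)\n",
    spec$M, paste(spec$alphabet, collapse = ""), spec$L, spec$interactions
  ))
  NextMethod()
}

#' @method tidy param_vec
#' @export
tidy.param_vec <- function(x, ...) {
  tibble::as_tibble(unclass2_tbl(x))
}

unclass2_tbl <- function(x) {
  attr(x, "spec") <- NULL
  class(x) <- class(tibble::tibble())
  x
}
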