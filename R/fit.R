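#' Fit a one-hot model to a sequence-activity table by least squares
#'
#' Ordinary (or ridge-penalized) least squares of activity on the one-hot
#' features of a spec. With `ridge = 0` the minimum-norm solution is
#' returned (computed through the singular value decomposition), which
#' lies in the Euclidean gauge — the row space of the design matrix. With
#' `ridge > 0` the unique minimizer of
#' `||y - X theta||^2 + ridge * ||theta||^2` is returned; an identity
#' penalizer likewise lands the estimate in the Euclidean gauge as
#' `ridge -> 0`.
#'
#' @param data Data frame with columns `sequence` and `activity`.
#' @param spec A [model_spec()] declaring the features to fit.
#' @param ridge Nonnegative ridge penalty on the identity (default 0).
#' @return An object of class `gauge_fit`: a list with `theta` (the
#'   fitted [param_vec()]), `spec`, `ridge`, `fitted`, `residuals`,
#'   `r.squared`, `sigma`, and `nobs`. Supports [predict()],
#'   [generics::tidy()], and [generics::glance()].
#' @examples
#' sim <- simulate_landscape("01", 3, "random_all_order", seed = 1)
#' fit <- fit_least_squares(sim$data, sim$spec)
#' glance(fit)
#' @export
fit_least_squares <- function(data, spec, ridge = 0) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(c("sequence", "activity") %in% names(data))) {
    abort("`data` needs columns `sequence` and `activity`.")
  }
  if (nrow(data) == 0) abort("`data` is empty.")
  if (ridge < 0) abort("`ridge` must be nonnegative.")
  X <- build_design_matrix(spec, data$sequence)
  y <- as.numeric(data$activity)
  if (ridge > 0) {
    coef <- solve(
      crossprod(X) + diag(ridge, spec$M),
      crossprod(X, y)
    )[, 1]
  } else {
    coef <- as.numeric(pinv(X) %*% y)
  }
  theta <- param_vec(spec, setNames(coef, spec$features))
  fitted <- as.numeric(X %*% coef)
  resid <- y - fitted
  ssr <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(
      theta = theta, spec = spec, ridge = ridge,
      fitted = fitted, residuals = resid,
      r.squared = if (sst > 0) 1 - ssr / sst else NA_real_,
      sigma = sqrt(ssr / max(1, nrow(data) - 1)),
      nobs = nrow(data)
    ),
    class = "gauge_fit"
  )
}

#' @export
print.gauge_fit <- function(x, ...) {
  cat(sprintf(
    "<gauge_fit> %d observations, M = %d features, ridge = %g, R^2 = %.4f\n",
    x$nobs, x$spec$M, x$ridge, x$r.squared
  ))
  invisible(x)
}

#' @export
predict.gauge_fit <- function(object, newdata, ...) {
  seqs <- if (is.data.frame(newdata)) newdata$sequence else newdata
  evaluate_model(object$theta, seqs)
}

#' Tidy the coefficients of a least-squares fit
#'
#' @param x A `gauge_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` (feature label), `order`, and
#'   `estimate`.
#' @method tidy gauge_fit
#' @export
tidy.gauge_fit <- function(x, ...) {
  tibble::tibble(
    term = x$spec$features,
    order = x$spec$order,
    estimate = x$theta$value
  )
}

#' One-row summary of a least-squares fit
#'
#' @param x A `gauge_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `r.squared`, `sigma`, `nobs`, `n_features`,
#'   and `ridge`.
#' @method glance gauge_fit
#' @export
glance.gauge_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared,
    sigma = x$sigma,
    nobs = x$nobs,
    n_features = x$spec$M,
    ridge = x$ridge
  )
}
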