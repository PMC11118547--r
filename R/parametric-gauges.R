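#' Parameters of the two-parameter gauge family
#'
#' A gauge in the parametric family is fixed by a penalization strength
#' `lambda` in `[0, Inf]` and a factorized position-specific distribution
#' `p`. `lambda` sets how strongly higher-order features are penalized
#' relative to lower-order ones; `p` sets how strongly specific characters
#' at each position are penalized. The derived quantity
#' `eta = lambda / (1 + lambda)` in `[0, 1]` is the natural coordinate of
#' the family (`lambda = Inf` maps to `eta = 1` and is always handled
#' through `eta`, never as a floating-point infinity).
#'
#' @param lambda Penalization strength, `0 <= lambda <= Inf`. Exactly one
#'   of `lambda` and `eta` must be given.
#' @param p A [position_dist][position_dist] (or `L x alpha` matrix); when
#'   constructed via [named_gauge()] a uniform default is filled in.
#' @param eta Alternative parameterization, `0 <= eta <= 1`.
#' @return An object of class `gauge_params` with fields `lambda`, `eta`,
#'   and `p`.
#' @examples
#' gauge_params(lambda = 1, p = uniform_dist(model_spec("01", 3)))
#' @export
gauge_params <- function(lambda = NULL, p = NULL, eta = NULL) {
  if (is.null(lambda) == is.null(eta)) {
    abort("Supply exactly one of `lambda` and `eta`.")
  }
  if (is.null(eta)) {
    if (!is.numeric(lambda) || lambda < 0) abort("`lambda` must be in [0, Inf].")
    eta <- if (is.infinite(lambda)) 1 else lambda / (1 + lambda)
  } else {
    if (!is.numeric(eta) || eta < 0 || eta > 1) abort("`eta` must be in [0, 1].")
    lambda <- if (eta == 1) Inf else eta / (1 - eta)
  }
  structure(list(lambda = lambda, eta = eta, p = p), class = "gauge_params")
}

#' @export
print.gauge_params <- function(x, ...) {
  cat(sprintf(
    "<gauge_params> lambda = %s, eta = %.6g%s\n",
    format(x$lambda), x$eta,
    if (is.null(x$p)) ", p unset" else ""
  ))
  invisible(x)
}

#' Named gauges of the parametric family
#'
#' Returns the `(lambda, p)` pair of a commonly used gauge:
#' * `trivial` — `lambda = 0`: only full-order parameters survive; each
#'   equals the activity of its sequence.
#' * `euclidean` — `lambda = alpha`, uniform `p`: the penalizing norm is
#'   the ordinary Euclidean norm, and the gauge space equals the row space
#'   of the design matrix.
#' * `equitable` — `lambda = 1`: each parameter is penalized in proportion
#'   to the fraction of sequences it applies to.
#' * `hierarchical` — `lambda = Inf` with `p` free: parameters become
#'   p-weighted conditional means and differences (ANOVA-like).
#' * `zero_sum` — the hierarchical gauge with uniform `p`: parameter groups
#'   sum to zero over characters at each position.
#' * `wild_type` — the hierarchical gauge with `p` the indicator of a
#'   wild-type sequence `wt`: parameters measure mutational effects
#'   relative to `wt`.
#' * `generalized_wild_type` — hierarchical gauge with a `p` that may put
#'   zero probability on some characters (e.g. a [region_dist()]).
#'
#' @param name One of the gauge names above.
#' @param spec A [model_spec()].
#' @param p Distribution for gauges that need one (required for
#'   `hierarchical` and `generalized_wild_type`; defaults to uniform for
#'   `equitable`).
#' @param wt Wild-type sequence (required for `wild_type`).
#' @return A [gauge_params()].
#' @examples
#' named_gauge("euclidean", model_spec("01", 3))$eta # 2/3
#' @export
named_gauge <- function(name, spec, p = NULL, wt = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  name <- match.arg(name, c(
    "trivial", "euclidean", "equitable", "zero_sum",
    "hierarchical", "wild_type", "generalized_wild_type"
  ))
  switch(name,
    trivial = gauge_params(lambda = 0, p = as_position_dist(spec, p)),
    euclidean = gauge_params(lambda = spec$alpha, p = uniform_dist(spec)),
    equitable = gauge_params(lambda = 1, p = as_position_dist(spec, p)),
    zero_sum = gauge_params(eta = 1, p = uniform_dist(spec)),
    hierarchical = {
      if (is.null(p)) abort("The hierarchical gauge needs a distribution `p`.")
      gauge_params(eta = 1, p = as_position_dist(spec, p))
    },
    wild_type = {
      if (is.null(wt)) abort("The wild-type gauge needs a wild-type sequence `wt`.")
      gauge_params(eta = 1, p = wildtype_dist(spec, wt))
    },
    generalized_wild_type = {
      if (is.null(p)) {
        abort("The generalized wild-type gauge needs a distribution `p`.")
      }
      gauge_params(eta = 1, p = as_position_dist(spec, p))
    }
  )
}

#' Single-position block of the parametric projection matrix
#'
#' The `(alpha+1) x (alpha+1)` projection block for one position, indexed
#' by the augmented alphabet `("*", c1, ..., c_alpha)`:
#' row `"*"` is `(eta, p_c1 * eta, ..., p_calpha * eta)`; row `c` is
#' `(1 - eta, delta_cc' - p_c' * eta)`. The Kronecker product of these
#' blocks over positions is the full projection matrix of the all-order
#' model. Each block is itself idempotent.
#'
#' @param alphabet Alphabet characters (string or character vector).
#' @param eta Gauge coordinate in `[0, 1]`.
#' @param p_l Probability vector over the alphabet at this position.
#' @return An `(alpha+1) x (alpha+1)` matrix with augmented-alphabet
#'   dimnames.
#' @examples
#' single_position_block("01", eta = 1, p_l = c(0.5, 0.5))
#' @export
single_position_block <- function(alphabet, eta, p_l) {
  alphabet <- as_alphabet(alphabet)
  alpha <- base::length(p_l)
  if (alpha != base::length(alphabet)) {
    abort("`p_l` must have one entry per alphabet character.")
  }
  if (abs(sum(p_l) - 1) > 1e-12) abort("`p_l` must sum to 1.")
  if (eta < 0 || eta > 1) abort("`eta` must be in [0, 1].")
  B <- matrix(0, alpha + 1, alpha + 1)
  B[1, ] <- c(eta, p_l * eta)
  B[-1, 1] <- 1 - eta
  B[-1, -1] <- diag(alpha) - matrix(p_l * eta, alpha, alpha, byrow = TRUE)
  dimnames(B) <- list(c(SG_WILDCARD, alphabet), c(SG_WILDCARD, alphabet))
  B
}

#' Projection matrix of a parametric-family gauge
#'
#' The M x M matrix `P` that carries any parameter vector of the all-order
#' model to its representative in the gauge `(lambda, p)`, moving only
#' along gauge freedoms (predictions are untouched). Two equivalent
#' construction routes are provided: the Kronecker product of
#' [single_position_block()]s (default), and direct elementwise evaluation
#' of the product formula over augmented-sequence pairs; they agree to
#' machine precision and are cross-checked in the test suite.
#'
#' Only all-order specs admit this matrix; hierarchical (`eta = 1`) gauges
#' of lower-order models are applied with [project_hierarchical()].
#'
#' @param spec An all-order [model_spec()].
#' @param gauge A [gauge_params()] (its `p` defaults to uniform).
#' @param method `"kronecker"` or `"elementwise"`.
#' @return An M x M numeric matrix with feature dimnames.
#' @export
projection_matrix <- function(spec, gauge, method = c("kronecker", "elementwise")) {
  stopifnot(inherits(spec, "model_spec"), inherits(gauge, "gauge_params"))
  method <- match.arg(method)
  if (spec$interactions != "all_order") {
    abort(paste(
      "Parametric projection matrices exist for all-order specs only;",
      "for hierarchical (eta = 1) gauges of lower-order models use",
      "project_hierarchical()."
    ))
  }
  p <- as_position_dist(spec, gauge$p)
  eta <- gauge$eta
  if (method == "kronecker") {
    blocks <- lapply(seq_len(spec$L), function(l) {
      single_position_block(spec$alphabet, eta, p[l, ])
    })
    P <- Reduce(kronecker, blocks)
  } else {
    # elementwise product formula: for each position the factor is
    #   s'_l, t'_l both chars : delta(s'_l, t'_l) - p_{l,t'_l} * eta
    #   s'_l = *, t'_l char   : p_{l,t'_l} * eta
    #   s'_l char, t'_l = *   : 1 - eta
    #   both stars            : eta
    fc <- spec$feature_chars
    P <- matrix(1, spec$M, spec$M)
    for (l in seq_len(spec$L)) {
      s_star <- fc[, l] == SG_WILDCARD
      t_star <- s_star # columns share the feature list
      pt <- ifelse(t_star, NA_real_, p[l, ][match(fc[, l], spec$alphabet)])
      Fl <- matrix(0, spec$M, spec$M)
      cc <- outer(!s_star, !t_star, `&`)
      Fl[cc] <- (outer(fc[, l], fc[, l], `==`) -
        matrix(pt * eta, spec$M, spec$M, byrow = TRUE))[cc]
      sc <- outer(s_star, !t_star, `&`)
      Fl[sc] <- matrix(pt * eta, spec$M, spec$M, byrow = TRUE)[sc]
      cs <- outer(!s_star, t_star, `&`)
      Fl[cs] <- 1 - eta
      ss <- outer(s_star, t_star, `&`)
      Fl[ss] <- eta
      P <- P * Fl
    }
    P
  }
  dimnames(P) <- list(spec$features, spec$features)
  P
}

#' Diagonal penalization matrix of a parametric-family gauge
#'
#' For `0 < lambda < Inf` and strictly positive `p`, the gauge `(lambda,
#' p)` is the minimizer of the quadratic norm `theta' Lambda theta` over
#' each gauge orbit, with the diagonal penalizer
#' `Lambda_s's' = p(s') * lambda^o(s')`, where `p(s')` multiplies the
#' per-position probabilities of the non-star characters of `s'` (star
#' positions contribute a factor 1). The limit gauges (`lambda` 0 or
#' `Inf`, or zero probabilities) have no such matrix and are refused;
#' project them with [projection_matrix()] or [project_hierarchical()].
#'
#' @param spec A [model_spec()].
#' @param gauge A [gauge_params()] with finite positive `lambda` and
#'   strictly positive `p`.
#' @return A list of class `penalization_matrix` with `diagonal` (named
#'   numeric of length M) and the gauge; `as.matrix()` yields the dense
#'   M x M diagonal matrix.
#' @export
penalization_matrix <- function(spec, gauge) {
  stopifnot(inherits(spec, "model_spec"), inherits(gauge, "gauge_params"))
  if (gauge$lambda <= 0 || is.infinite(gauge$lambda)) {
    abort("limit gauge (lambda 0 or Inf); use the projection route instead.")
  }
  p <- as_position_dist(spec, gauge$p)
  if (any(p <= 0)) {
    abort("limit gauge (zero-probability characters); use the projection route instead.")
  }
  d <- feature_probability(spec, p) * gauge$lambda^spec$order
  structure(
    list(diagonal = setNames(d, spec$features), gauge = gauge, spec = spec),
    class = "penalization_matrix"
  )
}

#' @export
as.matrix.penalization_matrix <- function(x, ...) {
  m <- diag(x$diagonal, nrow = base::length(x$diagonal))
  dimnames(m) <- list(names(x$diagonal), names(x$diagonal))
  m
}

#' @export
print.penalization_matrix <- function(x, ...) {
  cat(sprintf(
    "<penalization_matrix> diagonal, M = %d, lambda = %g\n",
    base::length(x$diagonal), x$gauge$lambda
  ))
  invisible(x)
}

# p(s') with star positions marginalized out (factor 1)
feature_probability <- function(spec, p) {
  fc <- spec$feature_chars
  w <- rep(1, spec$M)
  for (l in seq_len(spec$L)) {
    star <- fc[, l] == SG_WILDCARD
    pl <- p[l, ][match(fc[, l], spec$alphabet)]
    w <- w * ifelse(star, 1, pl)
  }
  w
}

#' Fix the gauge of a parameter vector
#'
#' Projects `theta` to its representative in a chosen gauge, preserving
#' every model prediction. Dispatches on the gauge: hierarchical (`eta =
#' 1`) gauges go through the closed-form conditional-mean projection
#' (works for any hierarchical spec, including additive and pairwise
#' models); other members of the parametric family require an all-order
#' spec and go through the projection matrix.
#'
#' @param theta A [param_vec()].
#' @param gauge A [gauge_params()] or a gauge name accepted by
#'   [named_gauge()].
#' @param p,wt Passed to [named_gauge()] when `gauge` is a name.
#' @return A gauge-fixed `param_vec` on the same gauge orbit as `theta`.
#' @examples
#' spec <- model_spec("01", 3, "all_order")
#' theta <- param_vec(spec, rnorm(spec$M))
#' zs <- fix_gauge(theta, "zero_sum")
#' @export
fix_gauge <- function(theta, gauge, p = NULL, wt = NULL) {
  spec <- pv_spec(theta)
  if (is.character(gauge)) gauge <- named_gauge(gauge, spec, p = p, wt = wt)
  stopifnot(inherits(gauge, "gauge_params"))
  if (gauge$eta == 1) {
    return(project_hierarchical(theta, as_position_dist(spec, gauge$p)))
  }
  P <- projection_matrix(spec, gauge)
  pv_replace(theta, as.numeric(P %*% pv_vector(theta)))
}

#' Convergence of smoothed hierarchical gauges to the wild-type limit
#'
#' Generalized wild-type gauges (hierarchical gauges whose `p` has
#' zero-probability characters) arise as the limit of hierarchical gauges
#' with the smoothed distributions of [smooth_dist()]. This check projects
#' a parameter vector with the smoothed gauge for each `eps` and reports
#' its max-norm distance from the direct `eta = 1` projection under `p`;
#' distances must shrink toward zero.
#'
#' @param spec An all-order [model_spec()].
#' @param p Target distribution (zeros allowed).
#' @param eps_list Positive, decreasing smoothing weights.
#' @param theta Optional [param_vec()]; defaults to a standard-normal
#'   vector drawn under `seed`.
#' @param seed Seed for the default `theta`.
#' @return A tibble with columns `eps` and `distance`.
#' @export
wildtype_limit_check <- function(spec, p, eps_list = 10^(-(1:4)),
                                 theta = NULL, seed = 20240512) {
  stopifnot(inherits(spec, "model_spec"))
  p <- as_position_dist(spec, p)
  if (is.null(theta)) {
    theta <- with_seed(seed, param_vec(spec, rnorm(spec$M)))
  }
  target <- pv_vector(fix_gauge(theta, gauge_params(eta = 1, p = p)))
  dist <- vapply(eps_list, function(eps) {
    sm <- smooth_dist(p, eps)
    max(abs(pv_vector(fix_gauge(theta, gauge_params(eta = 1, p = sm))) - target))
  }, numeric(1))
  tibble::tibble(eps = as.numeric(eps_list), distance = dist)
}

#' Trajectories of gauge-fixed parameters across the parametric family
#'
#' Projects one gauge orbit into the gauge `(eta, p)` for every `eta` on a
#' grid and records each parameter's value. For an all-order model on
#' length-`L` sequences every trajectory is a polynomial in `eta` of
#' degree at most `L` (the projection-matrix entries are products of `L`
#' factors each affine in `eta`).
#'
#' @param theta A [param_vec()] on an all-order spec (any representative
#'   of the orbit).
#' @param p Distribution shared across the sweep (default uniform).
#' @param eta_grid Grid of `eta` values in `[0, 1]`.
#' @return A tibble of class `eta_sweep` with columns `feature`, `order`,
#'   `eta`, `value`.
#' @export
eta_sweep <- function(theta, p = NULL, eta_grid = seq(0, 1, length.out = 21)) {
  spec <- pv_spec(theta)
  p <- as_position_dist(spec, p)
  v <- pv_vector(theta)
  rows <- purrr::map(eta_grid, function(eta) {
    P <- projection_matrix(spec, gauge_params(eta = eta, p = p))
    tibble::tibble(
      feature = spec$features, order = spec$order,
      eta = eta, value = as.numeric(P %*% v)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eta_sweep", class(out))
  attr(out, "spec") <- spec
  out
}
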