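#' Conditional mean activity under a factorized distribution
#'
#' Closed-form expectation of the model output when sequences are drawn
#' from `p` and a chosen set of positions is then fixed to chosen
#' characters. Each active feature contributes its coefficient times the
#' product, over its non-star positions, of the match indicator (at fixed
#' positions) or the character probability (at free positions); no
#' sequence enumeration is performed. Fixing a position overrides `p`
#' there, so characters of zero probability may be conditioned on.
#'
#' In a hierarchical gauge these conditional means are plain parameter
#' sums: the unconditional mean is the constant parameter, conditioning on
#' `c` at `l` adds `theta_lc`, conditioning on a pair adds the two
#' additive terms plus their pairwise term, and so on.
#'
#' @param theta A [param_vec()] on a hierarchical spec (zero-pattern
#'   closed).
#' @param p A [position_dist][position_dist] (or matrix).
#' @param fixed Positions to fix: a named character vector like
#'   `c("2" = "A", "4" = "G")` (names are 1-based positions), a data frame
#'   with columns `position` and `character`, or `NULL` for the
#'   unconditional mean.
#' @return A single number.
#' @export
conditional_mean <- function(theta, p, fixed = NULL) {
  spec <- pv_spec(theta)
  if (!isTRUE(spec$hierarchical)) {
    abort("`theta` must live on a hierarchical spec (zero-pattern closure).")
  }
  p <- as_position_dist(spec, p)
  fixed <- parse_fixed(spec, fixed)
  sum(pv_vector(theta) * feature_weights(spec, p, fixed))
}

# fixed -> named character vector, names = positions
parse_fixed <- function(spec, fixed) {
  if (is.null(fixed) || base::length(fixed) == 0) {
    return(character(0))
  }
  if (is.data.frame(fixed)) {
    fixed <- setNames(as.character(fixed$character), fixed$position)
  }
  pos <- as.integer(names(fixed))
  if (any(is.na(pos)) || any(pos < 1) || any(pos > spec$L)) {
    abort(sprintf("Fixed positions must lie in 1..%d.", spec$L))
  }
  if (anyDuplicated(pos)) abort("Fixed positions must be distinct.")
  if (!all(fixed %in% spec$alphabet)) {
    abort(sprintf(
      "Fixed character \"%s\" is not in the alphabet.",
      setdiff(fixed, spec$alphabet)[1]
    ))
  }
  setNames(as.character(fixed), pos)
}

# per-feature expectation weights under p with some positions fixed
feature_weights <- function(spec, p, fixed) {
  fc <- spec$feature_chars
  w <- rep(1, spec$M)
  fixed_pos <- as.integer(names(fixed))
  for (l in seq_len(spec$L)) {
    star <- fc[, l] == SG_WILDCARD
    if (l %in% fixed_pos) {
      w <- w * (star | fc[, l] == fixed[[as.character(l)]])
    } else {
      pl <- p[l, ][match(fc[, l], spec$alphabet)]
      w <- w * ifelse(star, 1, pl)
    }
  }
  w
}

#' Project a hierarchical model into a hierarchical gauge
#'
#' The hierarchical gauge of a distribution `p` is the `lambda -> Inf`
#' member of the parametric family. Its coefficients are built here by
#' inclusion-exclusion over conditional means: the new coefficient of a
#' feature with fixed set `F` is `sum over subsets F' of F of
#' (-1)^(|F| - |F'|) * conditional_mean(theta, p, F')`. This closed form
#' needs no all-order feature space, so it scales to additive, pairwise,
#' and other hierarchical models directly. The output is on the same
#' gauge orbit, satisfies the marginalization property (each parameter
#' group has zero p-weighted sum over characters at each of its
#' positions), and preserves the zero pattern of the spec.
#'
#' @param theta A [param_vec()] on a hierarchical spec.
#' @param p A [position_dist][position_dist] (zeros allowed: indicator
#'   distributions give the wild-type gauge, region distributions give
#'   generalized wild-type gauges).
#' @return A `param_vec` in the hierarchical gauge of `p`, with the
#'   distribution recorded in attribute `"gauge_p"`.
#' @export
project_hierarchical <- function(theta, p) {
  spec <- pv_spec(theta)
  if (!isTRUE(spec$hierarchical)) {
    abort(paste(
      "The spec's zero pattern is not closed (an inactive feature has an",
      "active refinement); hierarchical gauges are not defined for it."
    ))
  }
  p <- as_position_dist(spec, p)
  v <- pv_vector(theta)
  fc <- spec$feature_chars
  idx_of <- setNames(seq_len(spec$M), spec$features)

  # conditional mean for the fixed set of every active feature (each
  # subset of an active feature's fixed set is itself an active feature,
  # by downward closure)
  m <- vapply(seq_len(spec$M), function(j) {
    fixed_pos <- which(fc[j, ] != SG_WILDCARD)
    fixed <- setNames(fc[j, fixed_pos], fixed_pos)
    sum(v * feature_weights(spec, p, fixed))
  }, numeric(1))

  out <- numeric(spec$M)
  star_run <- strrep(SG_WILDCARD, spec$L)
  for (j in seq_len(spec$M)) {
    pos <- which(fc[j, ] != SG_WILDCARD)
    k <- base::length(pos)
    if (k == 0) {
      out[j] <- m[j]
      next
    }
    acc <- 0
    for (size in 0:k) {
      subs <- if (size == 0) {
        matrix(integer(0), nrow = 0, ncol = 1)
      } else {
        # index through seq_along to dodge combn's scalar-x expansion
        matrix(pos[combn(seq_along(pos), size)], nrow = size)
      }
      sgn <- (-1)^(k - size)
      for (ci in seq_len(ncol(subs))) {
        lab <- star_run
        for (l in subs[, ci]) substr(lab, l, l) <- fc[j, l]
        acc <- acc + sgn * m[idx_of[[lab]]]
      }
    }
    out[j] <- acc
  }
  res <- pv_replace(theta, out)
  attr(res, "gauge_p") <- p
  res
}

#' Marginalization residuals of a hierarchical-gauge parameter vector
#'
#' In a hierarchical gauge every parameter group — features sharing a star
#' pattern and all but one of their characters — has a zero p-weighted sum
#' over the character at the remaining position. Returns the largest
#' absolute group sum, relative to the parameter scale (sums run over the
#' active members, so zero-probability characters contribute nothing).
#'
#' @param theta A [param_vec()].
#' @param p A [position_dist][position_dist].
#' @return Largest relative group-sum magnitude (0 for an order-0 model).
#' @export
marginalization_residual <- function(theta, p) {
  spec <- pv_spec(theta)
  p <- as_position_dist(spec, p)
  v <- pv_vector(theta)
  fc <- spec$feature_chars
  scale <- max(abs(v), 1e-300)
  worst <- 0
  for (l in seq_len(spec$L)) {
    idx <- which(fc[, l] != SG_WILDCARD)
    if (base::length(idx) == 0) next
    keys <- spec$features[idx]
    substr(keys, l, l) <- "#"
    vals <- p[l, ][match(fc[idx, l], spec$alphabet)] * v[idx]
    sums <- rowsum(vals, keys)
    worst <- max(worst, max(abs(sums)))
  }
  worst / scale
}

#' Variance decomposition of a landscape by interaction order
#'
#' In a hierarchical gauge the landscape components of different star
#' patterns are mutually p-orthogonal, so the p-variance of the landscape
#' splits exactly across interaction orders:
#' `var_p(f_k) = sum over order-k features of p(s') * theta_s'^2` (star
#' positions marginalized out of `p(s')`), and the order variances sum to
#' the total. The constant component has variance 0 by convention.
#'
#' @param theta A [param_vec()] already in the hierarchical gauge of `p`
#'   (checked via the marginalization residuals).
#' @param p A [position_dist][position_dist]. When `p` has
#'   zero-probability characters the variance is with respect to the
#'   supported region of sequence space.
#' @param auto_project Project `theta` first when it is not in gauge
#'   (default `FALSE`: fail loudly instead of silently reinterpreting).
#' @param tol Residual tolerance for the in-gauge check.
#' @return A tibble of class `variance_table` with columns `order`,
#'   `variance`, `fraction`, and the total in attribute `"total"`.
#' @export
variance_decomposition <- function(theta, p, auto_project = FALSE,
                                   tol = 1e-8) {
  spec <- pv_spec(theta)
  p <- as_position_dist(spec, p)
  res <- marginalization_residual(theta, p)
  if (res > tol) {
    if (!auto_project) {
      abort(sprintf(
        "`theta` is not in the hierarchical gauge of `p` (marginalization residual %.3g); project first or set `auto_project = TRUE`.",
        res
      ))
    }
    message("Projecting into the hierarchical gauge before decomposing.")
    theta <- project_hierarchical(theta, p)
  }
  v <- pv_vector(theta)
  w <- feature_probability(spec, p)
  per_feature <- w * v^2
  per_feature[spec$order == 0] <- 0 # constant component carries no variance
  var_k <- vapply(0:spec$L, function(k) {
    sum(per_feature[spec$order == k])
  }, numeric(1))
  total <- sum(var_k)
  out <- tibble::tibble(
    order = 0:spec$L,
    variance = var_k,
    fraction = if (total > 0) var_k / total else rep(0, spec$L + 1)
  )
  class(out) <- c("variance_table", class(out))
  attr(out, "total") <- total
  out
}

#' Truncate a hierarchical-gauge model to a maximum interaction order
#'
#' Drops every feature of order above `max_order` from a model expressed
#' in the hierarchical gauge of some `p`. Because hierarchical-gauge
#' components of different orders are p-orthogonal, the truncated model
#' is the p-weighted least-squares approximation of the original
#' landscape among models of that order — e.g. `max_order = 1` yields the
#' best additive approximation within the region weighted by `p`, and
#' `max_order = 0` yields the constant model at the p-mean activity.
#'
#' @param theta A [param_vec()] previously produced by
#'   [project_hierarchical()] (or otherwise in a hierarchical gauge).
#' @param max_order Highest interaction order to keep, `0..L`.
#' @return A `param_vec` on a spec restricted to orders `<= max_order`.
#' @export
truncate_to_order <- function(theta, max_order) {
  spec <- pv_spec(theta)
  max_order <- as.integer(max_order)
  if (is.na(max_order) || max_order < 0 || max_order > spec$L) {
    abort(sprintf("`max_order` must be in 0..%d.", spec$L))
  }
  keep <- spec$order <= max_order
  if (all(keep)) {
    return(theta)
  }
  sub <- model_spec(spec$alphabet, spec$L,
    interactions = "custom",
    features = spec$features[keep]
  )
  out <- param_vec(sub, setNames(theta$value[keep], theta$feature[keep]))
  attr(out, "gauge_p") <- attr(theta, "gauge_p")
  out
}

#' Maximum gauge of an additive model
#'
#' Anchors the constant parameter at the activity of the best sequence:
#' per position the maximum additive value is moved into the constant, so
#' every additive parameter is `<= 0` with at least one exact 0 per
#' position, and each parameter reads as the cost of deviating from the
#' optimal character. The underlying constraint set is nonlinear, so this
#' gauge exists outside the parametric family and is defined here for
#' additive models only.
#'
#' @param theta A [param_vec()] on an additive spec (constant plus all
#'   order-1 features).
#' @return A `param_vec` in the maximum gauge.
#' @export
maximum_gauge_additive <- function(theta) {
  spec <- pv_spec(theta)
  is_additive <- max(spec$order) <= 1 &&
    sum(spec$order == 1) == spec$L * spec$alpha &&
    any(spec$order == 0)
  if (!is_additive) {
    abort("The maximum gauge is implemented for additive specs only.")
  }
  v <- pv_vector(theta)
  fc <- spec$feature_chars
  shift <- 0
  for (l in seq_len(spec$L)) {
    idx <- which(fc[, l] != SG_WILDCARD & spec$order == 1)
    ml <- max(v[idx])
    v[idx] <- v[idx] - ml
    shift <- shift + ml
  }
  v[spec$order == 0] <- v[spec$order == 0] + shift
  pv_replace(theta, v)
}
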