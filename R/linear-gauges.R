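#' Specify an arbitrary linear gauge
#'
#' A linear gauge is a subspace `Theta` of feature space that intersects
#' every gauge orbit exactly once. It can be given either by a spanning
#' basis, or implicitly by a positive-definite penalization matrix
#' `Lambda`, in which case `Theta` is the set of minimum-`Lambda`-norm
#' representatives and the projection is
#' `P = Lambda^{-1/2} (X Lambda^{-1/2})^+ X` (Moore-Penrose pseudoinverse).
#'
#' Validity checks: a basis must have `dim(Theta) = rank(X)` and be
#' transversal to the gauge space `G` (smallest principal angle above a
#' tolerance); a penalizer must be symmetric positive-definite with
#' condition number at most `1e12`.
#'
#' @param spec A [model_spec()].
#' @param basis M x r matrix whose columns span `Theta` (r = rank of the
#'   design matrix).
#' @param penalizer Positive-definite M x M matrix, a
#'   [penalization_matrix()], or a length-M numeric diagonal.
#' @return An object of class `linear_gauge` carrying the projection
#'   matrix `P` and an orthonormal basis `Q` of `Theta`.
#' @export
linear_gauge <- function(spec, basis = NULL, penalizer = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(basis) == is.null(penalizer)) {
    abort("Supply exactly one of `basis` and `penalizer`.")
  }
  X <- build_design_matrix(spec)
  if (!is.null(penalizer)) {
    if (inherits(penalizer, "penalization_matrix")) {
      penalizer <- as.matrix(penalizer)
    }
    if (is.numeric(penalizer) && is.null(dim(penalizer))) {
      if (base::length(penalizer) != spec$M) {
        abort("A diagonal penalizer must have length M.")
      }
      penalizer <- diag(penalizer, nrow = spec$M)
    }
    if (!isTRUE(all.equal(penalizer, t(penalizer), tolerance = 1e-10))) {
      abort("The penalizer must be symmetric.")
    }
    e <- eigen((penalizer + t(penalizer)) / 2, symmetric = TRUE)
    if (min(e$values) <= 0) abort("The penalizer must be positive-definite.")
    if (max(e$values) / min(e$values) > 1e12) {
      abort("Penalizer condition number exceeds 1e12; refusing on numerical grounds.")
    }
    Lih <- e$vectors %*% (t(e$vectors) / sqrt(e$values)) # Lambda^{-1/2}
    P <- Lih %*% pinv(X %*% Lih) %*% X
    Q <- orthonormalize(P)
  } else {
    basis <- as.matrix(basis)
    if (nrow(basis) != spec$M) abort("Basis vectors must have length M.")
    if (qr(basis)$rank < ncol(basis)) {
      abort("Basis vectors must be linearly independent.")
    }
    r <- qr(X)$rank
    if (ncol(basis) != r) {
      abort(sprintf(
        "Gauge space dimension %d does not match rank(X) = %d; Theta cannot intersect every orbit exactly once.",
        ncol(basis), r
      ))
    }
    Q <- qr.Q(qr(basis))
    G <- gauge_freedom_basis(spec)$basis
    if (ncol(G) > 0) {
      sv <- svd(crossprod(Q, G), nu = 0, nv = 0)$d
      # principal angle ~ sqrt(2 (1 - s)); an angle below ~1e-8 rad is
      # indistinguishable from overlap in double precision
      if (max(sv) > 1 - 1e-14) {
        abort("Theta is not transversal to the gauge space G (principal angle below tolerance).")
      }
    }
    # solve X B a = X theta in the least-squares sense: P = B (X B)^+ X
    P <- basis %*% pinv(X %*% basis) %*% X
  }
  dimnames(P) <- list(spec$features, spec$features)
  structure(list(spec = spec, P = P, Q = Q), class = "linear_gauge")
}

#' @export
print.linear_gauge <- function(x, ...) {
  cat(sprintf(
    "<linear_gauge> dim(Theta) = %d on M = %d features\n",
    ncol(x$Q), x$spec$M
  ))
  invisible(x)
}

# Moore-Penrose pseudoinverse, relative singular-value cutoff 1e-10
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# orthonormal basis of the column space of a projection matrix
orthonormalize <- function(P, tol = 1e-10) {
  s <- svd(P)
  s$u[, s$d > tol * max(s$d), drop = FALSE]
}

#' Project a parameter vector into a linear gauge
#'
#' Moves `theta` along the gauge space `G` to the unique equivalent vector
#' in `Theta`: predictions are unchanged and the result lies in the span
#' of the gauge's basis. Idempotent, and the identity on vectors already
#' in `Theta`.
#'
#' @param theta A [param_vec()].
#' @param gauge A [linear_gauge()] built on the same spec.
#' @return A gauge-fixed `param_vec`.
#' @export
project_linear <- function(theta, gauge) {
  stopifnot(inherits(gauge, "linear_gauge"))
  spec <- pv_spec(theta)
  if (!identical(spec$features, gauge$spec$features)) {
    abort("`theta` and `gauge` are built on different specs.")
  }
  pv_replace(theta, as.numeric(gauge$P %*% pv_vector(theta)))
}

#' Do two parameter vectors lie on the same gauge orbit?
#'
#' Two parameter vectors are gauge-equivalent when they give identical
#' predictions on every sequence, i.e. their difference lies in the null
#' space of the design matrix. The check evaluates predictions on all
#' sequences when sequence space is enumerable, otherwise on a seeded
#' random sample.
#'
#' @param theta_a,theta_b Two [param_vec()]s on the same spec.
#' @param tol Max allowed absolute prediction discrepancy.
#' @param n_sample Sample size when `alpha^L` exceeds the enumeration cap.
#' @param seed Seed for the sampled case.
#' @return A list with `same` (logical) and `max_discrepancy`.
#' @export
same_orbit <- function(theta_a, theta_b, tol = 1e-9, n_sample = 1000,
                       seed = 20240512) {
  spec <- pv_spec(theta_a)
  if (!identical(spec$features, pv_spec(theta_b)$features)) {
    abort("The two parameter vectors are built on different specs.")
  }
  seqs <- if (spec$N <= SG_MAX_SEQUENCES) {
    enumerate_sequences(spec)
  } else {
    with_seed(seed, vapply(
      seq_len(n_sample),
      function(i) paste0(sample(spec$alphabet, spec$L, replace = TRUE), collapse = ""),
      character(1)
    ))
  }
  d <- evaluate_model(theta_a, seqs) - evaluate_model(theta_b, seqs)
  scale <- max(1, max(abs(pv_vector(theta_a))), max(abs(pv_vector(theta_b))))
  disc <- max(abs(d))
  list(same = disc <= tol * scale, max_discrepancy = disc)
}
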