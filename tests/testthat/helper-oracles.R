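# Independent oracles used across the suite. All work by brute-force
# enumeration or generic linear algebra and never call the code paths they
# check.

# probability of each sequence under a factorized position distribution
oracle_seq_prob <- function(spec, p, sequences) {
  w <- rep(1, length(sequences))
  for (l in seq_len(spec$L)) {
    w <- w * p[l, ][match(substr(sequences, l, l), colnames(p))]
  }
  w
}

# expectation of activities under p, optionally conditioned on fixed
# positions (conditioning by restriction + renormalization over the
# enumerated table; `fixed` is a named character vector)
oracle_conditional_mean <- function(spec, p, activities, sequences, fixed = NULL) {
  w <- oracle_seq_prob(spec, p, sequences)
  if (!is.null(fixed)) {
    for (nm in names(fixed)) {
      l <- as.integer(nm)
      sel <- substr(sequences, l, l) == fixed[[nm]]
      # fixing overrides p at that position
      w <- ifelse(sel, w / max(p[l, fixed[[nm]]], .Machine$double.xmin), 0)
      if (p[l, fixed[[nm]]] == 0) {
        # zero-probability conditioning: redo weight from the other positions
        w <- rep(1, length(sequences))
        for (l2 in seq_len(spec$L)) {
          if (as.character(l2) %in% names(fixed)) {
            w <- w * (substr(sequences, l2, l2) == fixed[[as.character(l2)]])
          } else {
            w <- w * p[l2, ][match(substr(sequences, l2, l2), colnames(p))]
          }
        }
        break
      }
    }
  }
  sum(w * activities)
}

# minimum Lambda-norm vector on the gauge orbit of theta, via the KKT
# system of the equality-constrained quadratic program
oracle_qp_minimizer <- function(X, Lambda, theta) {
  y <- X %*% theta
  M <- ncol(X)
  K <- rbind(
    cbind(2 * Lambda, t(X)),
    cbind(X, matrix(0, nrow(X), nrow(X)))
  )
  sol <- MASS::ginv(K) %*% c(rep(0, M), y)
  as.numeric(sol[seq_len(M)])
}

# p-weighted least-squares fit of a given spec to enumerated activities
# (normal equations with pseudoinverse; weights may contain zeros)
oracle_weighted_fit <- function(fit_spec, p, sequences, activities) {
  X <- build_design_matrix(fit_spec, sequences)
  w <- oracle_seq_prob(fit_spec, p, sequences)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * activities)
  as.numeric(MASS::ginv(A) %*% b)
}

# number of augmented sequences a given sequence matches, by brute force
oracle_match_count <- function(spec, s) {
  schars <- strsplit(s, "", fixed = TRUE)[[1]]
  sum(vapply(spec$features, function(f) {
    fchars <- strsplit(f, "", fixed = TRUE)[[1]]
    all(fchars == "*" | fchars == schars)
  }, logical(1)))
}

random_theta <- function(spec, seed) {
  set.seed(seed)
  param_vec(spec, rnorm(spec$M))
}

expect_orbit_equal <- function(theta_a, theta_b, tol = 1e-9) {
  res <- same_orbit(theta_a, theta_b, tol = tol)
  expect_true(res$same,
    label = sprintf("same gauge orbit (discrepancy %.3g)", res$max_discrepancy)
  )
}
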