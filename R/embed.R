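#' Embed a sequence in feature space
#'
#' Computes the binary feature vector `x(s)`: component `x_s'(s)` is 1 when
#' `s` matches the augmented sequence `s'` at every non-star position. For
#' the all-order preset this equals the Kronecker product over positions of
#' the per-position vectors `(1, e_{s_l})` (constant slot plus one-hot).
#'
#' @param spec A [model_spec()].
#' @param s A sequence string of length `L` over the alphabet.
#' @return Named numeric vector of length `M` (names are feature labels).
#' @examples
#' embed_sequence(model_spec("01", 2), "01")
#' @export
embed_sequence <- function(spec, s) {
  stopifnot(inherits(spec, "model_spec"))
  sm <- sequence_matrix(spec, s)
  if (nrow(sm) != 1) abort("`s` must be a single sequence; see build_design_matrix().")
  x <- rep(1, spec$M)
  fc <- spec$feature_chars
  for (l in seq_len(spec$L)) {
    x <- x * ((fc[, l] == SG_WILDCARD) + (fc[, l] == sm[1, l]))
  }
  setNames(x, spec$features)
}

#' Build the design matrix of a one-hot model
#'
#' The N x M binary matrix `X` with one row per sequence (the embedding
#' `x(s)`) and one column per active feature. By default rows run over all
#' `alpha^L` sequences in lexicographic alphabet order; a subset can be
#' supplied. Dense construction is guarded by size caps.
#'
#' @param spec A [model_spec()].
#' @param sequences Optional character vector of sequences for the rows;
#'   default enumerates all of sequence space.
#' @return Numeric matrix with rownames = sequences, colnames = features.
#' @examples
#' build_design_matrix(model_spec("01", 1, "additive"))
#' @export
build_design_matrix <- function(spec, sequences = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(sequences)) {
    if (spec$N > SG_MAX_SEQUENCES) {
      abort(sprintf(
        "Refusing to build a dense design with N = %g rows (cap %g).",
        spec$N, SG_MAX_SEQUENCES
      ))
    }
    sequences <- enumerate_sequences(spec)
  }
  if (spec$M > SG_MAX_FEATURES) {
    abort(sprintf(
      "Refusing to build a dense design with M = %d columns (cap %g).",
      spec$M, SG_MAX_FEATURES
    ))
  }
  sm <- sequence_matrix(spec, sequences)
  fc <- spec$feature_chars
  X <- matrix(1, nrow = nrow(sm), ncol = spec$M)
  for (l in seq_len(spec$L)) {
    is_star <- fc[, l] == SG_WILDCARD
    X <- X * (outer(sm[, l], fc[, l], `==`) + rep(is_star, each = nrow(sm)))
  }
  dimnames(X) <- list(sequences, spec$features)
  X
}

#' Evaluate a one-hot model on sequences
#'
#' Computes `f(s; theta) = sum_s' theta_s' x_s'(s)` for each sequence.
#'
#' @param theta A [param_vec()].
#' @param sequences Character vector of sequences.
#' @return Numeric vector of predicted activities.
#' @export
evaluate_model <- function(theta, sequences) {
  spec <- pv_spec(theta)
  v <- pv_vector(theta)
  sm <- sequence_matrix(spec, sequences)
  fc <- spec$feature_chars
  out <- numeric(nrow(sm))
  # accumulate per sequence to avoid materializing N x M for long inputs
  chunk <- max(1L, floor(5e6 / spec$M))
  for (start in seq(1L, nrow(sm), by = chunk)) {
    idx <- start:min(nrow(sm), start + chunk - 1L)
    Xc <- matrix(1, nrow = base::length(idx), ncol = spec$M)
    for (l in seq_len(spec$L)) {
      is_star <- fc[, l] == SG_WILDCARD
      Xc <- Xc * (outer(sm[idx, l], fc[, l], `==`) +
        rep(is_star, each = base::length(idx)))
    }
    out[idx] <- as.numeric(Xc %*% v)
  }
  out
}

#' Orthonormal basis of the gauge freedoms
#'
#' Gauge freedoms are vectors `g` with `X g = 0`: directions in parameter
#' space that leave every model prediction unchanged. The basis is computed
#' from the Gram matrix `X'X` over the full factorial sequence space, whose
#' entries have the closed form `prod_l m_l` with `m_l = alpha` when both
#' features have a star at `l`, `0` when they carry different characters,
#' and `1` otherwise. This avoids enumerating `alpha^L` sequences, so large
#' `L` additive/pairwise specs are handled directly.
#'
#' @param spec A [model_spec()].
#' @param tol Relative eigenvalue threshold separating the null space
#'   (default `1e-10`; the spectra of these binary designs are integer
#'   separated at supported sizes).
#' @return A list of class `gauge_basis`: `basis` (M x dim matrix with
#'   orthonormal columns), `dim`, `rank`, and `M`.
#' @examples
#' gauge_freedom_basis(model_spec("ACGT", 3, "additive"))$dim # L = 3
#' @export
gauge_freedom_basis <- function(spec, tol = 1e-10) {
  G <- feature_gram(spec)
  e <- eigen(G, symmetric = TRUE)
  null_idx <- which(e$values <= tol * max(e$values))
  basis <- e$vectors[, null_idx, drop = FALSE]
  rownames(basis) <- spec$features
  structure(
    list(
      basis = basis,
      dim = base::length(null_idx),
      rank = spec$M - base::length(null_idx),
      M = spec$M
    ),
    class = "gauge_basis"
  )
}

#' @export
print.gauge_basis <- function(x, ...) {
  cat(sprintf(
    "<gauge_basis> %d gauge freedoms (M = %d, rank(X) = %d)\n",
    x$dim, x$M, x$rank
  ))
  invisible(x)
}

# closed-form X'X over the full factorial: number of sequences matching two
# augmented sequences simultaneously
feature_gram <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$M > 5000) {
    abort(sprintf(
      "Gram matrix for M = %d features is beyond the supported dense size.",
      spec$M
    ))
  }
  fc <- spec$feature_chars
  G <- matrix(1, spec$M, spec$M)
  for (l in seq_len(spec$L)) {
    star <- fc[, l] == SG_WILDCARD
    both_star <- outer(star, star, `&`)
    equal_char <- outer(fc[, l], fc[, l], `==`) & !both_star
    one_star <- xor(outer(star, star, `|`), both_star)
    G <- G * (spec$alpha * both_star + equal_char + one_star)
  }
  dimnames(G) <- list(spec$features, spec$features)
  G
}
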