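#' Position-specific probability distributions over sequences
#'
#' The parametric gauge family is defined for factorized distributions
#' `p(s) = prod_l p_{l, s_l}`: independent per-position character
#' probabilities. They are represented as an `L x alpha` matrix with rows
#' indexed by position and columns by alphabet character; each row sums to
#' 1, and zero entries are permitted (generalized wild-type gauges).
#'
#' @param spec A [model_spec()].
#' @return An `L x alpha` matrix of class `position_dist`.
#' @name position_dist
NULL

new_position_dist <- function(spec, m) {
  dimnames(m) <- list(seq_len(spec$L), spec$alphabet)
  if (any(m < -1e-12)) abort("Probabilities must be nonnegative.")
  m[m < 0] <- 0
  sums <- rowSums(m)
  if (any(abs(sums - 1) > 1e-12)) {
    abort(sprintf(
      "Probabilities at position %d sum to %.15g, not 1.",
      which(abs(sums - 1) > 1e-12)[1], sums[abs(sums - 1) > 1e-12][1]
    ))
  }
  structure(m, class = c("position_dist", "matrix", "array"))
}

#' @rdname position_dist
#' @export
uniform_dist <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  new_position_dist(spec, matrix(1 / spec$alpha, spec$L, spec$alpha))
}

#' @rdname position_dist
#' @param wt A wild-type sequence; the distribution is its indicator
#'   (probability 1 on `wt`'s character at each position).
#' @export
wildtype_dist <- function(spec, wt) {
  stopifnot(inherits(spec, "model_spec"))
  sm <- sequence_matrix(spec, wt)
  m <- matrix(0, spec$L, spec$alpha, dimnames = list(NULL, spec$alphabet))
  m[cbind(seq_len(spec$L), match(sm[1, ], spec$alphabet))] <- 1
  new_position_dist(spec, m)
}

#' Distribution uniform on a region of sequence space
#'
#' Builds the factorized distribution that is uniform over the sequences of
#' a region defined by per-position allowed character sets, and zero
#' outside. Positions not named in `allowed` admit every character.
#'
#' @param spec A [model_spec()].
#' @param allowed A named list: names are 1-based positions, values are
#'   character vectors (or single strings like `"LF"`) of allowed
#'   characters at that position.
#' @return A `position_dist`.
#' @examples
#' spec <- model_spec("ACGT", 4, "pairwise")
#' region_dist(spec, list(`3` = "G")) # "G fixed at position 3" region
#' @export
region_dist <- function(spec, allowed = list()) {
  stopifnot(inherits(spec, "model_spec"))
  m <- matrix(1 / spec$alpha, spec$L, spec$alpha,
    dimnames = list(NULL, spec$alphabet)
  )
  if (base::length(allowed) > 0 && is.null(names(allowed))) {
    abort("`allowed` must be a named list (names are positions).")
  }
  for (nm in names(allowed)) {
    l <- as.integer(nm)
    if (is.na(l) || l < 1 || l > spec$L) {
      abort(sprintf("Position \"%s\" is outside 1..%d.", nm, spec$L))
    }
    chars <- allowed[[nm]]
    if (is.character(chars) && base::length(chars) == 1 && nchar(chars) > 1) {
      chars <- strsplit(chars, "", fixed = TRUE)[[1]]
    }
    if (base::length(chars) == 0) {
      abort(sprintf("Empty allowed character set at position %d.", l))
    }
    if (!all(chars %in% spec$alphabet)) {
      abort(sprintf(
        "Character \"%s\" at position %d is not in the alphabet.",
        setdiff(chars, spec$alphabet)[1], l
      ))
    }
    m[l, ] <- 0
    m[l, chars] <- 1 / base::length(chars)
  }
  new_position_dist(spec, m)
}

#' Smooth a distribution toward uniform
#'
#' The epsilon-regularized distribution with per-position factors
#' `(1 - eps) * p_lc + eps / alpha`. As `eps` decreases to 0 the associated
#' hierarchical gauges converge to the (generalized) wild-type gauge of
#' `p`; see [wildtype_limit_check()].
#'
#' @param p A `position_dist`.
#' @param eps Mixing weight in `[0, 1]`.
#' @return A `position_dist`.
#' @export
smooth_dist <- function(p, eps) {
  stopifnot(inherits(p, "position_dist"), eps >= 0, eps <= 1)
  alpha <- ncol(p)
  m <- (1 - eps) * unclass(p) + eps / alpha
  structure(m, class = class(p))
}

as_position_dist <- function(spec, p) {
  if (is.null(p)) {
    return(uniform_dist(spec))
  }
  if (inherits(p, "position_dist")) {
    if (nrow(p) != spec$L || ncol(p) != spec$alpha) {
      abort("Distribution dimensions do not match the spec.")
    }
    return(p)
  }
  if (is.matrix(p)) {
    return(new_position_dist(spec, p))
  }
  abort("`p` must be a position_dist or an L x alpha matrix.")
}
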