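#' Define a one-hot model specification
#'
#' A model spec fixes the alphabet (alpha characters), the sequence length
#' `L`, and the set of active features. Features are indexed by augmented
#' sequences: length-`L` strings over the augmented alphabet
#' `{"*", c1, ..., c_alpha}`, where `"*"` is a wildcard matching any
#' character. An augmented sequence `s'` acts as a match pattern; its
#' feature `x_s'(s)` is 1 when sequence `s` matches `s'` at every non-star
#' position. The order `o(s')` of a feature is its number of non-star
#' positions; the constant feature is the all-star string.
#'
#' Available presets:
#' * `"constant"`: only the constant feature;
#' * `"additive"`: constant plus all order-1 features;
#' * `"pairwise"`: additive plus all order-2 features;
#' * `"all_order"`: every augmented sequence, `(alpha+1)^L` features;
#' * `"custom"`: an explicit set of feature labels via `features`.
#'
#' Features are kept in a canonical tensor-product order: per position the
#' symbol order is `("*", c1, ..., c_alpha)` and the full order is the
#' mixed-radix order with position 1 most significant. This makes the
#' parametric-family projection matrix an exact Kronecker product of
#' per-position blocks (see [projection_matrix()]).
#'
#' @param alphabet Characters of the alphabet: a single string (e.g.
#'   `"ACGT"`) or a character vector of single characters. Order matters
#'   (it fixes feature and sequence ordering). Must not contain `"*"`.
#' @param length Sequence length `L` (positive integer).
#' @param interactions Preset name (see Details), or `"custom"`.
#' @param features For `interactions = "custom"`, a character vector of
#'   augmented-sequence labels (length `L`, symbols from the augmented
#'   alphabet). Sorted into canonical order internally.
#'
#' @return An object of class `model_spec` with elements `alphabet`,
#'   `alpha`, `L`, `interactions`, `features` (labels in canonical order),
#'   `order` (per-feature interaction order), `feature_chars` (M x L
#'   character matrix), `M`, `N = alpha^L`, and `hierarchical` (`TRUE` when
#'   the zero pattern is closed: every star-replacement of an inactive
#'   feature is also inactive).
#'
#' @examples
#' spec <- model_spec("01", 3, "all_order")
#' spec$M # 27
#' head(spec$features)
#' @export
model_spec <- function(alphabet, length,
                       interactions = c(
                         "all_order", "additive", "pairwise",
                         "constant", "custom"
                       ),
                       features = NULL) {
  interactions <- match.arg(interactions)
  alphabet <- as_alphabet(alphabet)
  alpha <- base::length(alphabet)
  L <- as.integer(length)
  if (is.na(L) || L < 1) abort("`length` must be a positive integer.")

  labels <- switch(interactions,
    constant = strrep(SG_WILDCARD, L),
    additive = enumerate_upto_order(alphabet, L, 1L),
    pairwise = enumerate_upto_order(alphabet, L, 2L),
    all_order = enumerate_all_order(alphabet, L),
    custom = {
      if (is.null(features)) {
        abort("`features` must be supplied when `interactions = \"custom\"`.")
      }
      validate_feature_labels(features, alphabet, L)
    }
  )
  labels <- sort_features(labels, alphabet, L)
  fc <- label_matrix(labels, L)
  ord <- as.integer(rowSums(fc != SG_WILDCARD))

  spec <- structure(
    list(
      alphabet = alphabet,
      alpha = alpha,
      L = L,
      interactions = interactions,
      features = labels,
      order = ord,
      feature_chars = fc,
      M = base::length(labels),
      N = alpha^L,
      hierarchical = NA
    ),
    class = "model_spec"
  )
  spec$hierarchical <- is_zero_pattern_closed(spec)
  spec
}

as_alphabet <- function(alphabet) {
  if (is.character(alphabet) && base::length(alphabet) == 1 && nchar(alphabet) > 1) {
    alphabet <- strsplit(alphabet, "", fixed = TRUE)[[1]]
  }
  alphabet <- as.character(alphabet)
  if (base::length(alphabet) < 2) abort("The alphabet needs at least 2 characters.")
  if (any(nchar(alphabet) != 1)) abort("Alphabet symbols must be single characters.")
  if (anyDuplicated(alphabet)) abort("Alphabet characters must be unique.")
  if (SG_WILDCARD %in% alphabet) {
    abort("\"*\" is reserved for the wildcard and cannot be an alphabet character.")
  }
  alphabet
}

# all (alpha+1)^L augmented sequences in canonical tensor-product order
enumerate_all_order <- function(alphabet, L) {
  symbols <- c(SG_WILDCARD, alphabet)
  if (base::length(symbols)^L > SG_MAX_FEATURES * 20) {
    abort(sprintf(
      "All-order enumeration would produce %g features; beyond the supported size.",
      base::length(symbols)^L
    ))
  }
  g <- expand.grid(rep(list(symbols), L),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  # expand.grid varies its first factor fastest; position L must vary fastest
  m <- as.matrix(g)[, L:1, drop = FALSE]
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# constant + all features of order 1..k, generated without touching (alpha+1)^L
enumerate_upto_order <- function(alphabet, L, k) {
  labels <- strrep(SG_WILDCARD, L)
  for (ord in seq_len(k)) {
    pos_sets <- combn(L, ord)
    chars <- expand.grid(rep(list(alphabet), ord),
      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
    )
    for (j in seq_len(ncol(pos_sets))) {
      pos <- pos_sets[, j]
      base_lab <- rep(strrep(SG_WILDCARD, L), nrow(chars))
      for (i in seq_along(pos)) {
        substr(base_lab, pos[i], pos[i]) <- chars[[i]]
      }
      labels <- c(labels, base_lab)
    }
  }
  labels
}

validate_feature_labels <- function(labels, alphabet, L) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    abort(sprintf(
      "Duplicate feature label: \"%s\".",
      labels[duplicated(labels)][1]
    ))
  }
  bad_len <- nchar(labels) != L
  if (any(bad_len)) {
    abort(sprintf(
      "Feature label \"%s\" has length %d; expected %d.",
      labels[bad_len][1], nchar(labels[bad_len][1]), L
    ))
  }
  m <- label_matrix(labels, L)
  ok <- m %in% c(SG_WILDCARD, alphabet)
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow = nrow(m)), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Feature label \"%s\": character \"%s\" at position %d is not in the alphabet.",
      labels[bad[1]], m[bad[1], bad[2]], bad[2]
    ))
  }
  labels
}

label_matrix <- function(labels, L) {
  matrix(unlist(strsplit(labels, "", fixed = TRUE), use.names = FALSE),
    ncol = L, byrow = TRUE
  )
}

# canonical tensor-product (mixed-radix) order, "*" first at each position,
# position 1 most significant
sort_features <- function(labels, alphabet, L) {
  m <- label_matrix(labels, L)
  symbols <- c(SG_WILDCARD, alphabet)
  idx <- as.data.frame(matrix(match(m, symbols), ncol = L),
    stringsAsFactors = FALSE
  )
  labels[do.call(order, idx)]
}

# zero-pattern closure: replacing any non-star character of an active
# feature by "*" must give another active feature (equivalently: zeroing a
# feature zeroes every higher-order feature containing it)
is_zero_pattern_closed <- function(spec) {
  have <- spec$features
  fc <- spec$feature_chars
  for (l in seq_len(spec$L)) {
    idx <- which(fc[, l] != SG_WILDCARD)
    if (base::length(idx) == 0) next
    parent <- have[idx]
    substr(parent, l, l) <- SG_WILDCARD
    if (!all(parent %in% have)) return(FALSE)
  }
  TRUE
}

#' Enumerate the active features of a model
#'
#' Returns the augmented-sequence features of a spec as a tibble in the
#' canonical tensor-product order (deterministic across runs).
#'
#' @param spec A [model_spec()].
#' @return A tibble with columns `feature` (augmented-sequence label) and
#'   `order` (number of non-star positions).
#' @examples
#' enumerate_features(model_spec("01", 2, "additive"))
#' @export
enumerate_features <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  tibble::tibble(feature = spec$features, order = spec$order)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> alphabet={%s} (alpha=%d), L=%d, %s: M=%d features, N=%g sequences%s\n",
    paste(x$alphabet, collapse = ""), x$alpha, x$L, x$interactions,
    x$M, x$N, if (isTRUE(x$hierarchical)) ", hierarchical" else ""
  ))
  invisible(x)
}

#' Enumerate all sequences of a model spec
#'
#' All `alpha^L` sequences over the alphabet, lexicographic in the declared
#' alphabet order (position 1 most significant). Guarded by a dense
#' enumeration cap.
#'
#' @param spec A [model_spec()].
#' @return Character vector of length `alpha^L`.
#' @examples
#' enumerate_sequences(model_spec("01", 2))
#' @export
enumerate_sequences <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$N > SG_MAX_SEQUENCES) {
    abort(sprintf(
      "Refusing to enumerate N = %g sequences (cap %g).", spec$N, SG_MAX_SEQUENCES
    ))
  }
  g <- expand.grid(rep(list(spec$alphabet), spec$L),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  m <- as.matrix(g)[, spec$L:1, drop = FALSE]
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# split sequences into an n x L character matrix, validating the alphabet;
# the offending position is reported on failure
sequence_matrix <- function(spec, sequences) {
  sequences <- as.character(sequences)
  bad_len <- nchar(sequences) != spec$L
  if (any(bad_len)) {
    abort(sprintf(
      "Sequence \"%s\" has length %d; expected %d.",
      sequences[bad_len][1], nchar(sequences[bad_len][1]), spec$L
    ))
  }
  m <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
    ncol = spec$L, byrow = TRUE
  )
  ok <- matrix(m %in% spec$alphabet, nrow = nrow(m))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Sequence \"%s\": character \"%s\" at position %d is not in the alphabet.",
      sequences[bad[1]], m[bad[1], bad[2]], bad[2]
    ))
  }
  m
}
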