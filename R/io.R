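#' Read and write parameter tables
#'
#' Parameter tables are TSV files with columns `feature`
#' (augmented-sequence label, e.g. `"*D*V"`), `order`, and `value`.
#' Values are written at 17 significant digits so doubles round-trip
#' bit-exactly; unknown extra columns are preserved.
#'
#' @param theta A [param_vec()].
#' @param path File path.
#' @return `write_parameter_table()` returns `theta` invisibly;
#'   `read_parameter_table()` returns a `param_vec`.
#' @name parameter_table
NULL

#' @rdname parameter_table
#' @export
write_parameter_table <- function(theta, path) {
  stopifnot(inherits(theta, "param_vec"))
  out <- unclass2_tbl(theta)
  out$value <- sprintf("%.17g", out$value)
  readr::write_tsv(out, path)
  invisible(theta)
}

#' @rdname parameter_table
#' @param alphabet Alphabet of the model the table belongs to (string or
#'   character vector).
#' @param spec Optionally, a full [model_spec()]; the table's features
#'   must then match its active set exactly. When omitted, a custom spec
#'   is built from the table's feature labels.
#' @export
read_parameter_table <- function(path, alphabet = NULL, spec = NULL) {
  tab <- readr::read_tsv(path,
    col_types = readr::cols(
      feature = readr::col_character(),
      # parsed via base R below: exact round-trip of 17-digit decimals
      value = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  if ("value" %in% names(tab)) tab$value <- as.numeric(tab$value)
  if (!all(c("feature", "value") %in% names(tab))) {
    abort("A parameter table needs columns `feature` and `value`.")
  }
  if (anyDuplicated(tab$feature)) {
    abort(sprintf(
      "Duplicate feature label \"%s\" in %s.",
      tab$feature[duplicated(tab$feature)][1], path
    ))
  }
  L <- nchar(tab$feature[1])
  if (is.null(spec)) {
    if (is.null(alphabet)) {
      abort("Supply `alphabet` (or a full `spec`) to interpret the labels.")
    }
    spec <- model_spec(alphabet, L, "custom", features = tab$feature)
  } else {
    if (!setequal(tab$feature, spec$features)) {
      missing_f <- setdiff(spec$features, tab$feature)
      extra_f <- setdiff(tab$feature, spec$features)
      abort(sprintf(
        "Feature set mismatch with the spec (missing: %s; unknown: %s).",
        paste(head(missing_f, 3), collapse = ","),
        paste(head(extra_f, 3), collapse = ",")
      ))
    }
  }
  if ("order" %in% names(tab)) {
    true_order <- nchar(gsub("*", "", tab$feature, fixed = TRUE))
    bad <- which(tab$order != true_order)
    if (base::length(bad) > 0) {
      abort(sprintf(
        "Order column inconsistent with label \"%s\": file says %d, label implies %d.",
        tab$feature[bad[1]], tab$order[bad[1]], true_order[bad[1]]
      ))
    }
  }
  idx <- match(spec$features, tab$feature)
  extra_cols <- setdiff(names(tab), c("feature", "order", "value"))
  new_param_vec(spec, tab$value[idx],
    extra = if (base::length(extra_cols) > 0) tab[idx, extra_cols] else NULL
  )
}

#' Read and write position-specific distributions
#'
#' Distribution tables are TSV files with columns `position` (1-based),
#' `character`, and `probability`. On read, positions with explicit
#' entries treat omitted characters as probability 0; positions with no
#' entries at all default to uniform.
#'
#' @param p A [position_dist][position_dist].
#' @param path File path.
#' @param spec A [model_spec()] declaring alphabet and length.
#' @name distribution_table
NULL

#' @rdname distribution_table
#' @export
write_distribution <- function(p, path) {
  stopifnot(inherits(p, "position_dist"))
  out <- tibble::tibble(
    position = rep(seq_len(nrow(p)), each = ncol(p)),
    character = rep(colnames(p), nrow(p)),
    probability = sprintf("%.17g", as.numeric(t(unclass(p))))
  )
  readr::write_tsv(out, path)
  invisible(p)
}

#' @rdname distribution_table
#' @export
read_distribution <- function(path, spec) {
  stopifnot(inherits(spec, "model_spec"))
  tab <- readr::read_tsv(path,
    col_types = readr::cols(
      position = readr::col_integer(),
      character = readr::col_character(),
      probability = readr::col_character()
    ),
    progress = FALSE
  )
  tab$probability <- as.numeric(tab$probability)
  m <- matrix(1 / spec$alpha, spec$L, spec$alpha,
    dimnames = list(NULL, spec$alphabet)
  )
  if (any(tab$position < 1 | tab$position > spec$L)) {
    abort(sprintf("Distribution positions must lie in 1..%d.", spec$L))
  }
  if (!all(tab$character %in% spec$alphabet)) {
    abort(sprintf(
      "Distribution character \"%s\" is not in the alphabet.",
      setdiff(tab$character, spec$alphabet)[1]
    ))
  }
  for (l in unique(tab$position)) {
    m[l, ] <- 0
    rows <- tab[tab$position == l, ]
    m[l, rows$character] <- rows$probability
  }
  new_position_dist(spec, m)
}

#' Read and write sequence-activity tables
#'
#' Sequence-activity tables are TSV files with columns `sequence` and
#' `activity`.
#'
#' @param data A data frame with columns `sequence` and `activity`.
#' @param path File path.
#' @name activity_table
NULL

#' @rdname activity_table
#' @export
write_activity_table <- function(data, path) {
  stopifnot(all(c("sequence", "activity") %in% names(data)))
  out <- tibble::tibble(
    sequence = data$sequence,
    activity = sprintf("%.17g", data$activity)
  )
  readr::write_tsv(out, path)
  invisible(data)
}

#' @rdname activity_table
#' @export
read_activity_table <- function(path) {
  tab <- readr::read_tsv(path,
    col_types = readr::cols(
      sequence = readr::col_character(),
      activity = readr::col_character()
    ),
    progress = FALSE
  )
  tab$activity <- as.numeric(tab$activity)
  tab
}

#' Read a region definition file
#'
#' Region files are TSV with columns `position` and `allowed_characters`
#' (a string of characters, e.g. `"LF"`). They feed [region_dist()].
#'
#' @param path File path.
#' @return A named list suitable for [region_dist()]'s `allowed`.
#' @export
read_region_file <- function(path) {
  tab <- readr::read_tsv(path,
    col_types = readr::cols(
      position = readr::col_integer(),
      allowed_characters = readr::col_character()
    ),
    progress = FALSE
  )
  setNames(as.list(tab$allowed_characters), tab$position)
}
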