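#' Simulate a synthetic activity landscape
#'
#' Generates a landscape with known true parameters together with its full
#' sequence-activity table. Three designs are available:
#'
#' * `"random_all_order"`: i.i.d. Gaussian activities, one per sequence,
#'   represented as an all-order model in the trivial gauge (full-order
#'   parameters equal the activities). This emulates a random landscape on
#'   short sequences used to study parameter behavior across gauges.
#' * `"additive"`: constant 0 plus i.i.d. Gaussian additive effects.
#' * `"region_structured_pairwise"`: a pairwise model with small random
#'   additive/pairwise background effects plus planted positive effects
#'   for designated character combinations at two anchor positions,
#'   creating up to three disjoint high-activity regions (anchored by
#'   distinct characters at the first anchor position, in the spirit of
#'   empirically observed region structure in protein landscapes). Each
#'   region also gets its own pairwise preferences linking the anchor to
#'   the remaining positions, so the best local additive description
#'   differs between regions.
#'
#' @param alphabet,length Passed to [model_spec()].
#' @param preset One of the designs above.
#' @param effect_scales Named numeric scales: `activity` (all-order
#'   design, default 1), `additive` (default 0.5 for the region design, 1
#'   otherwise), `pairwise` (default 0.2).
#' @param noise_sd Standard deviation of i.i.d. Gaussian measurement noise
#'   added to the activity table (default 0).
#' @param regions For the region design, a named list of region
#'   definitions (each a named list mapping positions to allowed
#'   characters, as in [region_dist()]); `NULL` builds `min(3, alpha)`
#'   default regions anchored at the last two positions.
#' @param region_strength Multiplier on the planted region effects
#'   (default 1).
#' @param seed Mandatory integer seed; the caller's RNG state is left
#'   untouched.
#' @return A list with `theta` (true [param_vec()]), `data` (tibble
#'   `sequence`, `activity` over all `alpha^L` sequences), `spec`, and
#'   `regions` (for the region design).
#' @examples
#' sim <- simulate_landscape("01", 3, "random_all_order", seed = 1)
#' sim$data
#' @export
simulate_landscape <- function(alphabet, length,
                               preset = c(
                                 "random_all_order",
                                 "region_structured_pairwise", "additive"
                               ),
                               effect_scales = NULL, noise_sd = 0,
                               regions = NULL, region_strength = 1,
                               seed) {
  preset <- match.arg(preset)
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  scales <- utils::modifyList(
    list(
      activity = 1,
      additive = if (preset == "region_structured_pairwise") 0.5 else 1,
      pairwise = 0.2
    ),
    as.list(effect_scales %||% list())
  )
  with_seed(seed, {
    out <- switch(preset,
      random_all_order = sim_random_all_order(alphabet, length, scales),
      additive = sim_additive(alphabet, length, scales),
      region_structured_pairwise = sim_region_pairwise(
        alphabet, length, scales, regions, region_strength
      )
    )
    seqs <- enumerate_sequences(out$spec)
    activity <- evaluate_model(out$theta, seqs)
    if (noise_sd > 0) activity <- activity + rnorm(base::length(seqs), sd = noise_sd)
    out$data <- tibble::tibble(sequence = seqs, activity = activity)
    out
  })
}

sim_random_all_order <- function(alphabet, length, scales) {
  spec <- model_spec(alphabet, length, "all_order")
  v <- setNames(rep(0, spec$M), spec$features)
  full <- spec$features[spec$order == spec$L]
  v[full] <- rnorm(base::length(full), sd = scales$activity)
  list(spec = spec, theta = param_vec(spec, v), regions = NULL)
}

sim_additive <- function(alphabet, length, scales) {
  spec <- model_spec(alphabet, length, "additive")
  v <- setNames(rep(0, spec$M), spec$features)
  add <- spec$order == 1
  v[add] <- rnorm(sum(add), sd = scales$additive)
  list(spec = spec, theta = param_vec(spec, v), regions = NULL)
}

# default regions: distinct anchor characters at position L-1; regions
# beyond the first also restrict position L, giving planted epistasis
default_regions <- function(spec) {
  la <- spec$L - 1L
  lb <- spec$L
  a <- spec$alphabet
  n_regions <- min(3L, spec$alpha)
  regs <- list()
  for (r in seq_len(n_regions)) {
    allowed <- list()
    allowed[[as.character(la)]] <- a[r]
    if (r > 1) allowed[[as.character(lb)]] <- a[(r %% spec$alpha) + 1L]
    regs[[paste0("region", r)]] <- allowed
  }
  regs
}

sim_region_pairwise <- function(alphabet, length, scales, regions, strength) {
  spec <- model_spec(alphabet, length, "pairwise")
  if (spec$L < 2) abort("The region design needs L >= 2.")
  if (is.null(regions)) regions <- default_regions(spec)
  v <- setNames(rep(0, spec$M), spec$features)
  add <- spec$order == 1
  pair <- spec$order == 2
  v[add] <- rnorm(sum(add), sd = scales$additive)
  v[pair] <- rnorm(sum(pair), sd = scales$pairwise)

  lab_add <- function(l, c) {
    lab <- strrep(SG_WILDCARD, spec$L)
    substr(lab, l, l) <- c
    lab
  }
  lab_pair <- function(l1, c1, l2, c2) {
    lab <- strrep(SG_WILDCARD, spec$L)
    substr(lab, l1, l1) <- c1
    substr(lab, l2, l2) <- c2
    lab
  }
  for (r in seq_along(regions)) {
    reg <- regions[[r]]
    anchors <- lapply(names(reg), function(nm) {
      chars <- reg[[nm]]
      if (is.character(chars) && base::length(chars) == 1 && nchar(chars) > 1) {
        chars <- strsplit(chars, "", fixed = TRUE)[[1]]
      }
      list(pos = as.integer(nm), chars = chars)
    })
    # main effect on the first anchor, epistatic bonus linking anchor pairs
    a1 <- anchors[[1]]
    for (c1 in a1$chars) {
      v[lab_add(a1$pos, c1)] <- v[lab_add(a1$pos, c1)] + 3 * strength
    }
    if (base::length(anchors) > 1) {
      a2 <- anchors[[2]]
      for (c1 in a1$chars) {
        for (c2 in a2$chars) {
          v[lab_add(a2$pos, c2)] <- v[lab_add(a2$pos, c2)] + 1 * strength
          key <- lab_pair(
            min(a1$pos, a2$pos), if (a1$pos < a2$pos) c1 else c2,
            max(a1$pos, a2$pos), if (a1$pos < a2$pos) c2 else c1
          )
          v[key] <- v[key] + 2 * strength
        }
      }
    }
    # region-specific preference at the free positions: makes the best
    # additive description differ between regions
    free_pos <- setdiff(seq_len(spec$L), vapply(anchors, `[[`, integer(1), "pos"))
    pref <- spec$alphabet[((r - 1) %% spec$alpha) + 1]
    for (fp in free_pos) {
      for (c1 in a1$chars) {
        key <- lab_pair(
          min(fp, a1$pos), if (fp < a1$pos) pref else c1,
          max(fp, a1$pos), if (fp < a1$pos) c1 else pref
        )
        v[key] <- v[key] + 1.5 * strength
      }
    }
  }
  list(spec = spec, theta = param_vec(spec, v), regions = regions)
}
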