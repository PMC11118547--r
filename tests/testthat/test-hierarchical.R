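test_that("conditional means match the enumeration oracle, including sums of gauge-fixed parameters", {
  spec <- model_spec("01", 3, "all_order")
  theta <- random_theta(spec, 13)
  p <- region_dist(spec, list()) # uniform, as a position_dist
  p2 <- seq_p <- matrix(c(.2, .8, .5, .5, .7, .3), 3, 2, byrow = TRUE)
  seqs <- enumerate_sequences(spec)
  f <- evaluate_model(theta, seqs)

  for (pm in list(p, p2)) {
    pd <- if (inherits(pm, "position_dist")) pm else {
      m <- pm
      colnames(m) <- spec$alphabet
      m
    }
    expect_equal(
      conditional_mean(theta, pm),
      oracle_conditional_mean(spec, pd, f, seqs),
      tolerance = 1e-12
    )
    for (fixed in list(c(`1` = "0"), c(`2` = "1"), c(`1` = "1", `3` = "0"))) {
      expect_equal(
        conditional_mean(theta, pm, fixed),
        oracle_conditional_mean(spec, pd, f, seqs, fixed),
        tolerance = 1e-12
      )
    }
  }

  # in the hierarchical gauge, conditional means are parameter sums
  pd <- as.matrix(p2)
  h <- project_hierarchical(theta, p2)
  v <- pv_vector(h)
  expect_equal(conditional_mean(h, p2), unname(v["***"]), tolerance = 1e-12)
  expect_equal(
    conditional_mean(h, p2, c(`2` = "1")),
    unname(v["***"] + v["*1*"]),
    tolerance = 1e-12
  )
  expect_equal(
    conditional_mean(h, p2, c(`1` = "0", `3` = "1")),
    unname(v["***"] + v["0**"] + v["**1"] + v["0*1"]),
    tolerance = 1e-12
  )
})

test_that("conditional_mean validates its inputs", {
  spec <- model_spec("01", 3, "all_order")
  theta <- random_theta(spec, 1)
  p <- uniform_dist(spec)
  expect_error(conditional_mean(theta, p, c(`9` = "0")), "1..3")
  expect_error(conditional_mean(theta, p, c(`1` = "z")), "alphabet")
  broken <- param_vec(
    model_spec("01", 2, "custom", features = c("**", "01")), c(0, 1)
  )
  expect_error(conditional_mean(broken, uniform_dist(pv_spec(broken))), "hierarchical")
})

test_that("hierarchical projection agrees with the eta = 1 tensor projector on all-order specs", {
  for (case in list(c(2, 3), c(3, 2))) {
    spec <- model_spec(paste(0:(case[1] - 1), collapse = ""), case[2], "all_order")
    theta <- random_theta(spec, 100 + case[1])
    set.seed(case[1])
    p <- matrix(rgamma(spec$L * spec$alpha, 1) + .1, spec$L, spec$alpha)
    p <- p / rowSums(p)
    h <- project_hierarchical(theta, p)
    P <- projection_matrix(spec, gauge_params(eta = 1, p = p))
    expect_equal(
      unname(pv_vector(h)),
      as.numeric(P %*% pv_vector(theta)),
      tolerance = 1e-10
    )
  }
})

test_that("hierarchical projection satisfies marginalization and preserves orbit and zero pattern", {
  a20 <- paste(LETTERS[1:20], collapse = "")
  specs <- list(
    model_spec("01", 4, "additive"),
    model_spec("012", 3, "pairwise"),
    model_spec(a20, 4, "pairwise"),
    model_spec("01", 3, "custom", features = c(
      "***", "0**", "1**", "*0*", "*1*", "**0", "**1",
      "00*", "01*", "10*", "11*", "*00", "*01", "*10", "*11"
    )) # nearest-neighbor
  )
  for (spec in specs) {
    theta <- random_theta(spec, spec$M)
    set.seed(spec$M)
    p <- matrix(rgamma(spec$L * spec$alpha, 1) + .1, spec$L, spec$alpha)
    p <- p / rowSums(p)
    h <- project_hierarchical(theta, p)
    expect_lt(marginalization_residual(h, p), 1e-10)
    if (pv_spec(h)$N <= 4096) expect_orbit_equal(theta, h)
    # uniform p: plain zero-sum group sums
    hz <- project_hierarchical(theta, uniform_dist(spec))
    expect_lt(marginalization_residual(hz, uniform_dist(spec)), 1e-10)
  }

  # zero-pattern preservation on a spec with inactive features
  nn <- specs[[4]]
  theta <- random_theta(nn, 3)
  v <- pv_vector(theta)
  v[c("01*", "*10")] <- 0
  # the nn spec stays hierarchical with these zeros because no order-3
  # features are active; projection must keep structural zeros at zero
  h <- project_hierarchical(param_vec(nn, v), uniform_dist(nn))
  all_order_labels <- model_spec("01", 3, "all_order")$features
  inactive <- setdiff(all_order_labels, nn$features)
  expect_false(any(inactive %in% pv_spec(h)$features))
})

test_that("zero-probability distributions give (generalized) wild-type gauges", {
  spec <- model_spec("ACGT", 3, "pairwise")
  theta <- random_theta(spec, 17)
  wt <- "GAT"
  h <- project_hierarchical(theta, wildtype_dist(spec, wt))
  v <- pv_vector(h)
  matches_wt <- vapply(spec$features, function(f) {
    all(mapply(
      function(a, b) a == "*" || a == b,
      strsplit(f, "")[[1]], strsplit(wt, "")[[1]]
    ))
  }, logical(1))
  expect_lt(max(abs(v[matches_wt & spec$order > 0])), 1e-10)
  expect_equal(
    unname(v[spec$order == 0]), evaluate_model(theta, wt),
    tolerance = 1e-10
  )
  expect_orbit_equal(theta, h)

  # region distribution: marginalization holds over supported characters
  p_r <- region_dist(spec, list(`2` = "AC"))
  hr <- project_hierarchical(theta, p_r)
  expect_lt(marginalization_residual(hr, p_r), 1e-10)
  expect_orbit_equal(theta, hr)
})

test_that("landscape components are p-orthogonal and the variance splits by order", {
  spec <- model_spec("01", 3, "all_order")
  theta <- random_theta(spec, 23)
  p <- matrix(c(.3, .7, .5, .5, .6, .4), 3, 2, byrow = TRUE)
  h <- project_hierarchical(theta, p)
  seqs <- enumerate_sequences(spec)
  pm <- p
  colnames(pm) <- spec$alphabet
  w <- oracle_seq_prob(spec, pm, seqs)
  v <- pv_vector(h)

  # component values f_sigma(s) per star pattern, by direct summation
  patterns <- unique(gsub("[01]", "c", spec$features))
  comp <- sapply(patterns, function(pat) {
    members <- which(gsub("[01]", "c", spec$features) == pat)
    rowSums(sapply(members, function(j) {
      vapply(seqs, function(s) {
        ok <- all(mapply(
          function(a, b) a == "*" || a == b,
          strsplit(spec$features[j], "")[[1]], strsplit(s, "")[[1]]
        ))
        if (ok) v[j] else 0
      }, numeric(1))
    }))
  })
  gram <- t(comp) %*% (w * comp)
  offdiag <- gram - diag(diag(gram))
  expect_lt(max(abs(offdiag)), 1e-9)

  vt <- variance_decomposition(h, p)
  f <- evaluate_model(theta, seqs)
  pop_var <- sum(w * (f - sum(w * f))^2)
  expect_equal(attr(vt, "total"), pop_var, tolerance = 1e-10)
  expect_equal(attr(vt, "total"), sum(vt$variance), tolerance = 1e-12)
  expect_equal(vt$variance[1], 0) # constant component
  expect_true(all(vt$variance >= 0))
})

test_that("variance decomposition guards against out-of-gauge input", {
  spec <- model_spec("01", 3, "all_order")
  theta <- random_theta(spec, 29)
  p <- uniform_dist(spec)
  expect_error(variance_decomposition(theta, p), "project first")
  expect_message(
    vt <- variance_decomposition(theta, p, auto_project = TRUE),
    "Projecting"
  )
  direct <- variance_decomposition(project_hierarchical(theta, p), p)
  expect_equal(vt$variance, direct$variance, tolerance = 1e-12)

  # an additive-only model has no variance above order 1
  aspec <- model_spec("ACGT", 3, "additive")
  ath <- project_hierarchical(random_theta(aspec, 4), uniform_dist(aspec))
  avt <- variance_decomposition(ath, uniform_dist(aspec))
  expect_equal(avt$variance[3:4], c(0, 0))
})

test_that("hierarchical-gauge truncation is the p-weighted least-squares fit of that order", {
  set.seed(404)
  for (rep in 1:20) {
    spec <- model_spec("012", 3, "pairwise")
    theta <- param_vec(spec, rnorm(spec$M))
    p <- matrix(rgamma(9, 1) + .1, 3, 3)
    p <- p / rowSums(p)
    h <- project_hierarchical(theta, p)
    tr <- truncate_to_order(h, 1)
    aspec <- model_spec("012", 3, "additive")
    seqs <- enumerate_sequences(spec)
    f <- evaluate_model(theta, seqs)
    pm <- p
    colnames(pm) <- spec$alphabet
    coef <- oracle_weighted_fit(aspec, pm, seqs, f)
    pred_tr <- evaluate_model(tr, seqs)
    pred_or <- as.numeric(build_design_matrix(aspec, seqs) %*% coef)
    expect_lt(max(abs(pred_tr - pred_or)), 1e-8)
  }
})

test_that("truncation endpoints behave as documented", {
  spec <- model_spec("01", 3, "all_order")
  theta <- random_theta(spec, 31)
  p <- uniform_dist(spec)
  h <- project_hierarchical(theta, p)
  expect_identical(truncate_to_order(h, 3), h)
  const <- truncate_to_order(h, 0)
  expect_equal(pv_spec(const)$M, 1)
  expect_equal(
    unname(pv_vector(const)),
    mean(evaluate_model(theta, enumerate_sequences(spec))),
    tolerance = 1e-12
  )
  expect_error(truncate_to_order(h, 4), "0..3")
  expect_error(truncate_to_order(h, -1), "0..3")
})

test_that("the maximum gauge anchors the constant at the best sequence", {
  spec1 <- model_spec("01", 1, "additive")
  mx <- maximum_gauge_additive(param_vec(spec1, c("*" = 0, "0" = 1, "1" = 3)))
  expect_equal(unname(pv_vector(mx)), c(3, -2, 0))

  # already anchored: unchanged
  anchored <- param_vec(spec1, c("*" = 2, "0" = -1, "1" = 0))
  expect_equal(
    pv_vector(maximum_gauge_additive(anchored)), pv_vector(anchored)
  )

  spec <- model_spec("ACGT", 3, "additive")
  theta <- random_theta(spec, 55)
  mx <- maximum_gauge_additive(theta)
  v <- pv_vector(mx)
  seqs <- enumerate_sequences(spec)
  expect_equal(
    unname(v[spec$order == 0]),
    max(evaluate_model(theta, seqs)),
    tolerance = 1e-12
  )
  add <- v[spec$order == 1]
  expect_true(all(add <= 1e-12))
  fc <- pv_spec(mx)$feature_chars
  for (l in 1:3) {
    expect_lt(min(abs(add[fc[pv_spec(mx)$order == 1, l] != "*"])), 1e-12)
  }
  expect_orbit_equal(theta, mx)

  expect_error(
    maximum_gauge_additive(random_theta(model_spec("01", 2, "pairwise"), 2)),
    "additive"
  )
})

test_that("region distributions are uniform on the allowed sets and zero outside", {
  spec <- model_spec("ACGT", 4, "pairwise")
  expect_equal(unname(unclass(region_dist(spec, list()))),
    matrix(0.25, 4, 4),
    tolerance = 1e-15
  )
  r1 <- region_dist(spec, list(`3` = "G"))
  expect_equal(unname(r1[3, ]), c(0, 0, 1, 0))
  expect_equal(unname(r1[1, ]), rep(.25, 4))
  r2 <- region_dist(spec, list(`3` = c("T", "A"), `4` = "G"))
  expect_equal(unname(r2[3, ]), c(.5, 0, 0, .5))
  expect_equal(unname(r2[4, ]), c(0, 0, 1, 0))
  expect_error(region_dist(spec, list(`3` = character(0))), "Empty")
  expect_error(region_dist(spec, list(`9` = "A")), "outside")
  expect_error(region_dist(spec, list(`2` = "X")), "alphabet")
})
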