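test_that("measure values follow the Moebius expansion", {
  cap <- capacity(c("0" = 0.5, "1" = 0.5))
  expect_equal(measure_value(cap, c(0, 1)), 1.0)
  expect_equal(measure_value(cap, integer(0)), 0.0)
  expect_error(measure_value(cap, 5), "outside the ground set")

  set.seed(101)
  for (rep in 1:10) {
    cap <- rand_capacity_positive(4, order = 2)
    for (A in oracle_subsets(0:3)) {
      expect_equal(measure_value(cap, A), oracle_mu(cap$mobius, A),
                   tolerance = 1e-12)
    }
  }
})

test_that("capacity construction validates and canonicalizes", {
  expect_error(capacity(c(0.5, 0.5)), "named")
  expect_error(capacity(c("0" = 0.8, "1" = 0.8, "0,1" = -0.9)), "monotonicity")
  # unordered keys are canonicalized
  cap <- capacity(c("2,0" = 0.4, "1" = 0.6), n_elements = 3)
  expect_true("0,2" %in% names(cap$mobius))
  expect_equal(measure_value(cap, c(0, 2)), 0.4)
  # coalition beyond order is rejected
  expect_error(capacity(c("0" = 1, "0,1" = 0.1), order = 1), "larger than")
})

test_that("mobius_support_size counts k-additive coefficients", {
  expect_identical(mobius_support_size(6, 2), 21L)
  expect_identical(mobius_support_size(6, 6), 63L)
  expect_identical(mobius_support_size(6, 1), 6L)
  expect_error(mobius_support_size(6, 0), "\\[1, n\\]")
  expect_error(mobius_support_size(6, 7), "\\[1, n\\]")
})

test_that("Choquet integral matches hand-computable cases", {
  add <- capacity_additive(c(0.5, 0.5))
  expect_equal(choquet_integral(add, c(0.2, 0.8)), 0.5)
  # max-like capacity: mu(A) = 1 for every nonempty A
  mu_max <- sapply(choqfuse:::enumerate_coalitions(3), function(A) 1)
  names(mu_max) <- sapply(choqfuse:::enumerate_coalitions(3), coalition_key)
  cap_max <- capacity_from_measure(mu_max, 3)
  expect_equal(choquet_integral(cap_max, c(0.3, 0.7, 0.1)), 0.7)
  # min-like capacity: mu(X) = 1, everything else 0
  mu_min <- mu_max * 0
  mu_min[["0,1,2"]] <- 1
  cap_min <- capacity_from_measure(mu_min, 3)
  expect_equal(choquet_integral(cap_min, c(0.3, 0.7, 0.1)), 0.1)
  expect_error(choquet_integral(add, c(-0.1, 0.2)), "non-negative")
  expect_error(choquet_integral(add, c(0.1, 0.2, 0.3)), "length")
})

test_that("Choquet integral equals the literal sorted level-set oracle", {
  set.seed(202)
  for (rep in 1:200) {
    n <- sample(2:5, 1)
    cap <- rand_capacity(n, order = sample(seq_len(n), 1))
    f <- round(runif(n), 2) # rounding forces frequent ties
    expect_equal(choquet_integral(cap, f), oracle_choquet(cap$mobius, n, f),
                 tolerance = 1e-12)
  }
})

test_that("Choquet integral is bounded, idempotent and comonotone-monotone", {
  set.seed(303)
  for (rep in 1:50) {
    n <- sample(2:5, 1)
    cap <- rand_capacity(n)
    f <- runif(n)
    v <- choquet_integral(cap, f)
    expect_gte(v, min(f) - 1e-12)
    expect_lte(v, max(f) + 1e-12)
    cc <- runif(1)
    expect_equal(choquet_integral(cap, rep(cc, n)), cc, tolerance = 1e-12)
    g <- pmin(f + runif(n, 0, 0.3), 1)
    expect_gte(choquet_integral(cap, g), v - 1e-12)
  }
})

test_that("Shapley values match the definitional oracle and are efficient", {
  expect_equal(shapley_values(capacity_additive(c(0.2, 0.3, 0.5))),
               c(0.2, 0.3, 0.5))
  # symmetric capacity: mu depends only on |A|
  coals <- choqfuse:::enumerate_coalitions(3)
  mu_sym <- sapply(coals, function(A) (length(A) / 3)^2)
  names(mu_sym) <- sapply(coals, coalition_key)
  expect_equal(shapley_values(capacity_from_measure(mu_sym, 3)), rep(1 / 3, 3))

  set.seed(404)
  for (rep in 1:30) {
    n <- sample(2:4, 1)
    cap <- rand_capacity(n)
    v <- shapley_values(cap)
    expect_equal(v, oracle_shapley(cap$mobius, n), tolerance = 1e-12)
    expect_equal(sum(v), measure_value(cap, 0:(n - 1)), tolerance = 1e-12)
  }
})

test_that("extended interaction index generalizes Shapley and detects synergy", {
  set.seed(505)
  for (rep in 1:30) {
    n <- sample(2:4, 1)
    cap <- rand_capacity(n)
    v <- shapley_values(cap)
    for (x in 0:(n - 1)) {
      expect_equal(extended_interaction_index(cap, x), v[x + 1], tolerance = 1e-12)
    }
    # full oracle on pairs, plus Murofushi-Soneda agreement
    pair <- sort(sample(0:(n - 1), 2))
    expect_equal(extended_interaction_index(cap, pair),
                 oracle_interaction(cap$mobius, n, pair), tolerance = 1e-12)
    expect_equal(extended_interaction_index(cap, pair),
                 oracle_pairwise_ms(cap$mobius, n, pair[1], pair[2]),
                 tolerance = 1e-12)
  }
  add <- capacity_additive(c(0.2, 0.3, 0.5))
  expect_equal(extended_interaction_index(add, c(0, 2)), 0)
  expect_error(extended_interaction_index(add, integer(0)), "nonempty")
})

test_that("interaction oracle covers coalitions beyond pairs", {
  set.seed(606)
  for (rep in 1:10) {
    n <- sample(3:5, 1)
    cap <- rand_capacity(n)
    size <- sample(3:n, 1)
    S <- sort(sample(0:(n - 1), size))
    expect_equal(extended_interaction_index(cap, S),
                 oracle_interaction(cap$mobius, n, S), tolerance = 1e-12)
  }
})

test_that("1-additive capacities reduce to weighted means with zero interaction", {
  set.seed(707)
  w <- rexp(4); w <- w / sum(w)
  cap <- capacity_additive(w)
  f <- runif(4)
  expect_equal(choquet_integral(cap, f), sum(w * f), tolerance = 1e-12)
  expect_equal(shapley_values(cap), w)
  for (pair in list(c(0, 1), c(1, 3), c(0, 2, 3))) {
    expect_equal(extended_interaction_index(cap, pair), 0)
  }
})

test_that("check_monotonicity reports violating (element, subset) pairs", {
  expect_identical(nrow(check_monotonicity(capacity_additive(c(0.3, 0.7)))), 0L)
  bad <- capacity(c("0" = 0.8, "1" = 0.8, "0,1" = -0.9), validate = FALSE)
  viol <- check_monotonicity(bad)
  expect_gt(nrow(viol), 0)
  expect_true(any(viol$element == 0 & viol$subset == "1"))
  expect_equal(viol$margin[viol$element == 0 & viol$subset == "1"], -0.1,
               tolerance = 1e-12)
})

test_that("tidy and glance summarize capacities", {
  cap <- capacity(c("0" = 0.5, "1" = 0.3, "0,1" = 0.2))
  td <- tidy(cap)
  expect_identical(td$coalition, c("0", "1", "0,1"))
  expect_equal(td$measure[3], 1.0)
  gl <- glance(cap)
  expect_true(gl$normalized)
  expect_gte(gl$min_monotonicity_margin, 0)
})
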