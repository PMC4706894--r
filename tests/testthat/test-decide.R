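# small deterministic model shared across decision tests
make_toy_model <- function(n_samples = 80, seed = 51) {
  sim <- simulate_scores(n_samples, n_classes = 3, k_classifiers = 4,
                         skills = c(0.5, 1, 1.5, 2), seed = seed)
  fit_fusion(sim, s = 2)
}

test_that("singleton ensembles with identity capacities pass beliefs through", {
  model <- make_toy_model()
  # force singleton ensembles on classifier j with the identity capacity
  for (ci in seq_along(model$classes)) {
    cls <- model$classes[ci]
    model$ensembles[[cls]]$members <- ci - 1L
    model$class_capacities[[cls]] <- capacity_additive(1)
  }
  beliefs <- matrix(runif(4 * 3), 4, 3)
  lik <- aggregate_class_likelihoods(model, beliefs)
  expect_equal(unname(lik), diag(beliefs[1:3, ]))
})

test_that("uniform additive pair capacities average the two beliefs", {
  model <- make_toy_model()
  for (cls in model$classes) {
    model$ensembles[[cls]]$members <- c(0L, 2L)
    model$class_capacities[[cls]] <- capacity_additive(c(0.5, 0.5))
  }
  beliefs <- matrix(runif(4 * 3), 4, 3)
  lik <- aggregate_class_likelihoods(model, beliefs)
  expect_equal(unname(lik), as.numeric((beliefs[1, ] + beliefs[3, ]) / 2))
})

test_that("fused likelihoods equal the per-class Choquet oracle", {
  set.seed(52)
  model <- make_toy_model()
  for (rep in 1:20) {
    beliefs <- matrix(runif(4 * 3), 4, 3)
    lik <- aggregate_class_likelihoods(model, beliefs)
    for (ci in seq_along(model$classes)) {
      cls <- model$classes[ci]
      cap <- model$class_capacities[[cls]]
      f <- beliefs[model$ensembles[[cls]]$members + 1L, ci]
      expect_equal(unname(lik[ci]), oracle_choquet(cap$mobius, cap$n_elements, f),
                   tolerance = 1e-12)
    }
  }
  expect_error(aggregate_class_likelihoods(model, matrix(0, 2, 2)), "matrix")
})

test_that("the margin rule decides or abstains as specified", {
  d <- choqfuse:::decide_from_likelihoods(c(A = 0.9, B = 0.2, C = 0.1), 0.1)
  expect_identical(d$label, "A")
  expect_equal(d$margin, 0.7)
  d <- choqfuse:::decide_from_likelihoods(c(A = 0.55, B = 0.50), 0.1)
  expect_identical(d$label, abstain_label())
  expect_equal(d$margin, 0.05, tolerance = 1e-12)
  # threshold above 1 always abstains on [0,1] likelihoods
  set.seed(53)
  for (rep in 1:20) {
    lik <- stats::setNames(runif(4), paste0("C", 1:4))
    expect_identical(choqfuse:::decide_from_likelihoods(lik, 1.001)$label,
                     abstain_label())
  }
  # exact tie at threshold 0 goes to the lowest class index
  d <- choqfuse:::decide_from_likelihoods(c(C1 = 0.4, C2 = 0.4), 0)
  expect_identical(d$label, "C1")
})

test_that("predict returns one decision row per sample with likelihood columns", {
  model <- make_toy_model()
  test <- simulate_scores(30, n_classes = 3, k_classifiers = 4,
                          skills = c(0.5, 1, 1.5, 2), seed = 54)
  dec <- predict(model, test)
  expect_identical(nrow(dec), 30L)
  expect_true(all(c("sample_id", "decision", "margin", "true_class",
                    paste0("lik_", model$classes)) %in% names(dec)))
  expect_true(all(dec$margin >= 0))
  # with threshold 0 nothing abstains on continuous scores
  expect_false(any(dec$decision == abstain_label()))
  # a huge threshold abstains everywhere
  dec_all <- predict(model, test, threshold = 2)
  expect_true(all(dec_all$decision == abstain_label()))
})

test_that("errors fall and abstentions rise monotonically along the grid", {
  model <- make_toy_model(n_samples = 120)
  test <- simulate_scores(150, n_classes = 3, k_classifiers = 4,
                          skills = c(0.5, 1, 1.5, 2), seed = 55)
  sweep <- threshold_sweep(model, test, grid = seq(0, 1, by = 0.05))
  expect_true(all(diff(sweep$errors) <= 0))
  expect_true(all(diff(sweep$abstentions) >= 0))
  expect_true(all(diff(sweep$correct) <= 0))
  expect_equal(sweep$correct + sweep$errors + sweep$abstentions, rep(150, nrow(sweep)))
})

test_that("grid search matches exhaustive recomputation and breaks ties low", {
  model <- make_toy_model(n_samples = 120)
  val <- simulate_scores(100, n_classes = 3, k_classifiers = 4,
                         skills = c(0.5, 1, 1.5, 2), seed = 56)
  grid <- seq(0, 0.5, by = 0.02)
  res <- search_threshold(model, val, metric = "efficiency", grid = grid)
  # independent recomputation at every grid point
  by_hand <- vapply(grid, function(th) {
    dec <- predict(model, val, threshold = th)
    tab <- confusion_with_abstention(dec$true_class, dec$decision, model$classes)
    val_ <- efficiency(tab)
    if (is.na(val_)) -Inf else val_
  }, 0)
  expect_equal(res$threshold, grid[which.max(by_hand)])
  expect_equal(res$value, max(by_hand))
  # single-point grid returns that point
  expect_equal(search_threshold(model, val, grid = 0.07)$threshold, 0.07)
})

test_that("ND-everywhere efficiency falls back to ITR or errors when forbidden", {
  model <- make_toy_model()
  # relabel validation truth so nothing is ever correct -> efficiency ND
  val <- simulate_scores(40, n_classes = 3, k_classifiers = 4,
                         skills = c(8, 8, 8, 8), correlation = 0, seed = 57)
  wrong <- dplyr::mutate(val, true_class = paste0("C", (as.integer(sub("C", "", true_class)) %% 3) + 1))
  expect_error(search_threshold(model, wrong, metric = "efficiency",
                                grid = c(0, 0.01), allow_fallback = FALSE),
               "ND")
  res <- search_threshold(model, wrong, metric = "efficiency", grid = c(0, 0.01))
  expect_identical(res$metric, "itr")
})

test_that("tidy and glance expose importances and settings", {
  model <- make_toy_model()
  td <- tidy(model)
  expect_identical(nrow(td), model$n * model$k)
  expect_true(all(td$selection_rank[td$in_ensemble] >= 1, na.rm = TRUE))
  per_class_sums <- td |> dplyr::group_by(class) |> dplyr::summarise(s = sum(shapley))
  expect_equal(per_class_sums$s, rep(1, model$n), tolerance = 1e-9)
  gl <- glance(model)
  expect_identical(gl$s, model$s)
})
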