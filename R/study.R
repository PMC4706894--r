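# Seeded simulation study: fused framework versus its base classifiers.

#' Run a seeded fusion-versus-base simulation study
#'
#' For each seed: draws independent training, validation and test sets
#' from [simulate_scores()]; fits the fusion framework on the training
#' set; tunes the abstention threshold on the validation set (efficiency,
#' ITR fallback); and evaluates both the framework and every base
#' classifier (argmax of its own raw scores, no abstention) on the test
#' set. The ND-skipping mean and the maximum of the base metrics are the
#' comparison references.
#'
#' @param seeds Integer vector; one replicate per seed.
#' @param n_train,n_validation,n_test Sample sizes of the three splits.
#' @param s Ensemble size cap.
#' @param grid Threshold grid for tuning.
#' @param ... Passed to [simulate_scores()] (classes, skills, correlation,
#'   noise).
#' @return A tibble with one row per seed: framework efficiency and ITR,
#'   ND-skipping mean and max of the base classifiers' efficiency and ITR,
#'   and the tuned threshold.
#' @export
#' @examples
#' run_fusion_study(seeds = 1, n_train = 120, n_validation = 60, n_test = 60,
#'                  n_classes = 3, k_classifiers = 3, skills = c(0.5, 1, 2))
run_fusion_study <- function(seeds, n_train = 400, n_validation = 200,
                             n_test = 500, s = 4,
                             grid = seq(0, 1, by = 0.01), ...) {
  purrr::map_dfr(seeds, function(seed) {
    train <- simulate_scores(n_train, seed = seed, ...)
    val <- simulate_scores(n_validation, seed = seed + 1000003L, ...)
    test <- simulate_scores(n_test, seed = seed + 2000003L, ...)
    model <- fit_fusion(train, s = s)
    model <- tune_threshold(model, val, grid = grid)
    fw <- evaluate_decisions(predict(model, test), classes = model$classes)

    base <- choqfuse:::classifier_argmax(test) |>
      dplyr::group_by(.data$classifier) |>
      dplyr::group_map(function(g, key) {
        tab <- confusion_with_abstention(g$true_class, g$decision, model$classes)
        tibble::tibble(efficiency = efficiency(tab), itr = nykopp_itr(tab))
      }) |>
      dplyr::bind_rows()

    tibble::tibble(
      seed = seed,
      threshold = model$threshold,
      framework_efficiency = fw$efficiency,
      framework_itr = fw$itr_bits,
      base_mean_efficiency = mean(base$efficiency, na.rm = TRUE),
      base_best_efficiency = max(base$efficiency, na.rm = TRUE),
      base_mean_itr = mean(base$itr, na.rm = TRUE),
      base_best_itr = max(base$itr, na.rm = TRUE)
    )
  })
}
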