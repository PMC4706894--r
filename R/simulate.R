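# Synthetic measurement-level classifier outputs: Gaussian signal plus
# correlated noise, emulating heterogeneous first-level P300 speller
# classifiers with controllable skill and diversity.

#' Simulate measurement-level classifier scores
#'
#' Generates raw scores for `k_classifiers` classifiers on an
#' `n_classes`-way symbol task. For a sample with true class `c`,
#' classifier `j` scores class `i` as
#' `skills[j] * (i == c) + noise_sd * (sqrt(correlation) * z_i +
#' sqrt(1 - correlation) * e_ji)` where `z` is noise shared by all
#' classifiers (their common input signal) and `e` is classifier-specific,
#' both standard normal. `skills` sets each classifier's accuracy;
#' `correlation` sets how much base classifiers agree, i.e. how little
#' diversity the ensemble has to exploit.
#'
#' The defaults emulate the setting the package targets: a 6-symbol
#' session decoded by 6 heterogeneous classifiers spanning weak to strong,
#' with moderate correlation.
#'
#' @param n_samples Number of classification events to draw.
#' @param n_classes Number of classes (>= 2). Default 6.
#' @param k_classifiers Number of base classifiers. Default 6.
#' @param skills Numeric vector of `k_classifiers` non-negative signal
#'   amplitudes. Default `seq(0.6, 2.6, length.out = k_classifiers)`.
#' @param correlation Shared-noise fraction rho in `[0, 1)`. Default 0.3.
#' @param noise_sd Positive noise standard deviation. Default 1.
#' @param seed Optional integer seed; when given, output is fully
#'   reproducible and the caller's RNG state is untouched.
#' @return A long tibble with columns `sample_id`, `true_class`,
#'   `classifier`, `class`, `score`. Classes are labelled `"C1"...`,
#'   classifiers `"D1"...`.
#' @export
#' @examples
#' sim <- simulate_scores(n_samples = 10, seed = 42)
#' accuracy_by_classifier(sim)
simulate_scores <- function(n_samples, n_classes = 6, k_classifiers = 6,
                            skills = seq(0.6, 2.6, length.out = k_classifiers),
                            correlation = 0.3, noise_sd = 1, seed = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (k_classifiers < 1) stop("k_classifiers must be >= 1", call. = FALSE)
  if (length(skills) != k_classifiers || any(skills < 0)) {
    stop("skills must be k_classifiers non-negative amplitudes", call. = FALSE)
  }
  if (correlation < 0 || correlation >= 1) stop("correlation must be in [0, 1)", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)

  draw <- function() {
    truth <- sample.int(n_classes, n_samples, replace = TRUE)
    shared <- matrix(stats::rnorm(n_samples * n_classes), n_samples, n_classes)
    rows <- vector("list", n_samples)
    for (t in seq_len(n_samples)) {
      eps <- matrix(stats::rnorm(k_classifiers * n_classes), k_classifiers, n_classes)
      noise <- noise_sd * (sqrt(correlation) * matrix(shared[t, ], k_classifiers,
                                                      n_classes, byrow = TRUE) +
                             sqrt(1 - correlation) * eps)
      signal <- outer(skills, as.numeric(seq_len(n_classes) == truth[t]))
      sc <- signal + noise
      rows[[t]] <- tibble::tibble(
        sample_id = t,
        true_class = paste0("C", truth[t]),
        classifier = rep(paste0("D", seq_len(k_classifiers)), times = n_classes),
        class = rep(paste0("C", seq_len(n_classes)), each = k_classifiers),
        score = as.numeric(sc)
      )
    }
    dplyr::bind_rows(rows)
  }
  with_local_seed(seed, draw())
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state;
# seed = NULL uses (and advances) the current state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Per-classifier argmax accuracy
#'
#' Each base classifier's own decision is the class with its maximum raw
#' score (ties towards the first class in sorted order); accuracy is the
#' fraction of samples where that matches the true class.
#'
#' @param scores Long score table with `true_class` (see [simulate_scores()]).
#' @return A tibble with columns `classifier` and `accuracy`.
#' @export
accuracy_by_classifier <- function(scores) {
  scores <- validate_scores(scores, require_truth = TRUE)
  picks <- classifier_argmax(scores)
  picks |>
    dplyr::group_by(.data$classifier) |>
    dplyr::summarise(accuracy = mean(.data$decision == .data$true_class),
                     .groups = "drop")
}

# Per (sample, classifier) argmax decision on raw scores; ties broken
# towards the first class in sorted label order.
classifier_argmax <- function(scores) {
  scores |>
    dplyr::arrange(.data$sample_id, .data$classifier, .data$class) |>
    dplyr::group_by(.data$sample_id, .data$classifier) |>
    dplyr::summarise(
      true_class = .data$true_class[1],
      decision = .data$class[which.max(.data$score)],
      .groups = "drop"
    )
}
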