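# Mapping raw, classifier-specific scores into the common belief space
# [0, 1]: per-event min-max rescaling to [-1, 1], then a sigmoid centered
# between the two highest rescaled values.

#' Normalization configuration
#'
#' Controls the raw-score-to-belief mapping applied independently to each
#' classifier's score vector for one classification event. Scores are
#' first affinely mapped so the row minimum hits -1 and the maximum +1,
#' then pushed through a logistic sigmoid whose crossover sits midway
#' between the two highest rescaled values. Centering there deliberately
#' pulls both of the two top beliefs towards 0.5 when the classifier
#' cannot separate its best two classes, so downstream fusion sees the
#' uncertainty.
#'
#' @param slope Positive sigmoid slope factor (lambda). Default 2.
#' @param slope_max Upper cap on the slope. Default 10.
#' @param crossover_rule `"midpoint_top2"` (default) places the crossover
#'   at the midpoint of the two largest rescaled scores. `"optimized"` is
#'   a documented extension point and currently falls back to the midpoint
#'   rule with a warning.
#' @param degenerate_belief Belief assigned to every class when a score
#'   row is constant (no information); default 0.5, absolute uncertainty.
#' @return A list of class `"normalization_config"`.
#' @export
normalize_config <- function(slope = 2, slope_max = 10,
                             crossover_rule = c("midpoint_top2", "optimized"),
                             degenerate_belief = 0.5) {
  crossover_rule <- match.arg(crossover_rule)
  if (!is.numeric(slope) || length(slope) != 1 || !is.finite(slope) || slope <= 0) {
    stop("slope must be a positive number", call. = FALSE)
  }
  if (!is.numeric(slope_max) || slope_max <= 0) {
    stop("slope_max must be positive", call. = FALSE)
  }
  if (slope > slope_max) {
    stop(sprintf("slope %.3g exceeds slope_max %.3g", slope, slope_max), call. = FALSE)
  }
  if (!is.numeric(degenerate_belief) || degenerate_belief < 0 || degenerate_belief > 1) {
    stop("degenerate_belief must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(slope = slope, slope_max = slope_max, crossover_rule = crossover_rule,
         degenerate_belief = degenerate_belief),
    class = "normalization_config"
  )
}

#' Rescale one score row to [-1, 1]
#'
#' Affine map sending the row minimum to -1 and the maximum to +1; a
#' constant row maps to all zeros.
#'
#' @param row Numeric vector of at least 2 finite scores.
#' @return Numeric vector in `[-1, 1]`.
#' @export
linear_rescale <- function(row) {
  row <- as.numeric(row)
  if (length(row) < 2) stop("need at least two scores per row", call. = FALSE)
  if (any(!is.finite(row))) stop("scores must be finite", call. = FALSE)
  lo <- min(row); hi <- max(row)
  if (hi == lo) return(rep(0, length(row)))
  2 * (row - lo) / (hi - lo) - 1
}

#' Project rescaled scores into (0, 1) through a sigmoid
#'
#' `x -> 1 / (1 + exp(-lambda * (x - c)))` with crossover `c` given by the
#' config's rule (default: midpoint of the two largest entries). The map
#' is strictly increasing, hence rank-preserving. A degenerate (constant)
#' row returns `degenerate_belief` for every class.
#'
#' @param rescaled Numeric vector in `[-1, 1]` (output of [linear_rescale()]).
#' @param config A [normalize_config()].
#' @return Numeric vector of beliefs in `[0, 1]`.
#' @export
sigmoid_project <- function(rescaled, config = normalize_config()) {
  if (!inherits(config, "normalization_config")) {
    stop("config must be a normalization_config", call. = FALSE)
  }
  rescaled <- as.numeric(rescaled)
  if (any(rescaled < -1 - 1e-12) || any(rescaled > 1 + 1e-12)) {
    stop("rescaled values must lie in [-1, 1]", call. = FALSE)
  }
  if (max(rescaled) == min(rescaled)) {
    return(rep(config$degenerate_belief, length(rescaled)))
  }
  if (identical(config$crossover_rule, "optimized")) {
    warning("crossover_rule = \"optimized\" is an extension point; using the midpoint rule",
            call. = FALSE)
  }
  top2 <- sort(rescaled, decreasing = TRUE)[1:2]
  crossover <- mean(top2)
  stats::plogis(config$slope * (rescaled - crossover))
}

#' Normalize a long table of classifier scores into beliefs
#'
#' Applies [linear_rescale()] then [sigmoid_project()] to each
#' (sample, classifier) score row independently, producing the degree of
#' belief that the input belongs to each class. Beliefs preserve each
#' classifier's class ranking and are invariant to positive affine
#' transformations of its raw scores, so heterogeneous output spaces
#' (posterior probabilities, margins, distances) become comparable.
#'
#' @param scores Data frame in long format with columns `sample_id`,
#'   `classifier`, `class`, `score` (and optionally `true_class`).
#' @param config A [normalize_config()].
#' @return The input tibble with a `belief` column added.
#' @export
#' @examples
#' sim <- simulate_scores(n_samples = 3, seed = 1)
#' normalize_scores(sim)
normalize_scores <- function(scores, config = normalize_config()) {
  scores <- validate_scores(scores)
  dplyr::mutate(
    dplyr::group_by(scores, .data$sample_id, .data$classifier),
    belief = sigmoid_project(linear_rescale(.data$score), config)
  ) |>
    dplyr::ungroup()
}

# Shared validation of long score tables.
validate_scores <- function(scores, require_truth = FALSE) {
  needed <- c("sample_id", "classifier", "class", "score")
  missing_cols <- setdiff(needed, names(scores))
  if (length(missing_cols) > 0) {
    stop(sprintf("score table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(scores$score)) stop("score column must be numeric", call. = FALSE)
  if (any(!is.finite(scores$score))) stop("scores must be finite", call. = FALSE)
  if (require_truth && (!"true_class" %in% names(scores) || anyNA(scores$true_class))) {
    stop("true_class labels are required", call. = FALSE)
  }
  # every sample must carry the full classifier x class grid
  grid <- dplyr::count(scores, .data$sample_id, name = "rows")
  k <- dplyr::n_distinct(scores$classifier)
  n <- dplyr::n_distinct(scores$class)
  ragged <- grid$rows != k * n
  if (any(ragged)) {
    stop(sprintf("sample %s has %d score rows; expected %d (k = %d classifiers x n = %d classes)",
                 grid$sample_id[ragged][1], grid$rows[ragged][1], k * n, k, n),
         call. = FALSE)
  }
  tibble::as_tibble(scores)
}

# Long belief/score table -> list of k x n matrices (classifier x class),
# plus label bookkeeping. Row/column order: sorted unique labels.
scores_to_matrices <- function(scores, value_col = "belief") {
  classifiers <- sort(unique(scores$classifier))
  classes <- sort(unique(scores$class))
  samples <- unique(scores$sample_id)
  mats <- lapply(samples, function(sid) {
    sub <- scores[scores$sample_id == sid, ]
    m <- matrix(NA_real_, nrow = length(classifiers), ncol = length(classes),
                dimnames = list(classifiers, classes))
    m[cbind(match(sub$classifier, classifiers), match(sub$class, classes))] <-
      sub[[value_col]]
    if (anyNA(m)) {
      stop(sprintf("sample %s is missing classifier/class combinations", sid),
           call. = FALSE)
    }
    m
  })
  names(mats) <- as.character(samples)
  truth <- NULL
  if ("true_class" %in% names(scores) && !anyNA(scores$true_class)) {
    truth <- vapply(samples, function(sid) {
      as.character(scores$true_class[scores$sample_id == sid][1])
    }, "")
  }
  list(matrices = mats, samples = samples, classifiers = classifiers,
       classes = classes, truth = truth)
}
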