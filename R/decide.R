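# Fusion model: Choquet aggregation of per-class ensemble beliefs,
# argmax-with-abstention decisions, and threshold tuning by grid search.

#' Label used for abstentions
#'
#' Decisions tables use this string where the framework withholds a
#' decision.
#' @return The string `"ABSTAIN"`.
#' @export
abstain_label <- function() "ABSTAIN"

#' Fit the Choquet fusion framework
#'
#' End-to-end training on a long score table with true labels:
#' scores are normalized into beliefs, a one-vs-rest s-additive capacity on
#' the full classifier set is learned per class, class ensembles of at
#' most `s` classifiers are grown by interaction maximization, per-class
#' capacities are learned on the ensemble members, and (optionally) the
#' abstention threshold is tuned on held-out data with [search_threshold()].
#'
#' @param scores Long score table (`sample_id`, `true_class`,
#'   `classifier`, `class`, `score`).
#' @param s Ensemble size cap (default 4, the study setting for k = 6).
#' @param global_order Additivity order of the global capacities
#'   (default `s`).
#' @param class_order Additivity order of ensemble capacities (default:
#'   unrestricted, i.e. the ensemble size).
#' @param ridge Ridge weight for the learning QP.
#' @param normalization A [normalize_config()].
#' @param threshold Abstention threshold (margin below it abstains).
#'   Default 0: never abstain. Tune afterwards with [search_threshold()].
#' @param early_stop Passed to the ensemble builder.
#' @return An object of class `"fusion_model"`.
#' @export
#' @examples
#' train <- simulate_scores(n_samples = 60, n_classes = 3, k_classifiers = 3,
#'                          skills = c(0.5, 1, 2), seed = 7)
#' model <- fit_fusion(train, s = 2)
#' predict(model, simulate_scores(n_samples = 5, n_classes = 3,
#'                                k_classifiers = 3, skills = c(0.5, 1, 2),
#'                                seed = 8))
fit_fusion <- function(scores, s = 4, global_order = s, class_order = NULL,
                       ridge = 1e-6, normalization = normalize_config(),
                       threshold = 0, early_stop = FALSE) {
  scores <- validate_scores(scores, require_truth = TRUE)
  k <- dplyr::n_distinct(scores$classifier)
  s <- min(s, k)
  beliefs <- normalize_scores(scores, normalization)
  fit <- learn_all(beliefs, s = s, global_order = min(global_order, k),
                   class_order = class_order, ridge = ridge,
                   early_stop = early_stop)
  structure(
    list(
      k = length(fit$classifiers), n = length(fit$classes),
      classifiers = fit$classifiers, classes = fit$classes,
      s = s, global_order = min(global_order, k), ridge = ridge,
      normalization = normalization,
      global_capacities = fit$global_capacities,
      ensembles = fit$ensembles,
      class_capacities = fit$class_capacities,
      threshold = threshold
    ),
    class = "fusion_model"
  )
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> k = %d classifiers, n = %d classes, s = %d, threshold = %.3g\n",
              x$k, x$n, x$s, x$threshold))
  for (cls in x$classes) {
    cat(sprintf("  %s: ensemble {%s}\n", cls,
                paste(x$classifiers[x$ensembles[[cls]]$members + 1L], collapse = ", ")))
  }
  invisible(x)
}

#' Per-class fused likelihoods for one belief matrix
#'
#' For each class, the beliefs of that class's ensemble members are
#' aggregated by the Choquet integral with respect to the class capacity.
#'
#' @param model A [fit_fusion()] model.
#' @param beliefs A `k x n` belief matrix (classifiers x classes), rows
#'   and columns in the model's sorted label order.
#' @return Named numeric vector of `n` likelihoods in `[0, 1]`.
#' @export
aggregate_class_likelihoods <- function(model, beliefs) {
  stopifnot(inherits(model, "fusion_model"))
  if (!is.matrix(beliefs) || nrow(beliefs) != model$k || ncol(beliefs) != model$n) {
    stop(sprintf("beliefs must be a %d x %d matrix", model$k, model$n), call. = FALSE)
  }
  out <- vapply(seq_len(model$n), function(ci) {
    cls <- model$classes[ci]
    members <- model$ensembles[[cls]]$members
    choquet_integral(model$class_capacities[[cls]], beliefs[members + 1L, ci])
  }, 0)
  stats::setNames(out, model$classes)
}

# Decision from a likelihood vector: argmax with margin-based abstention.
decide_from_likelihoods <- function(likelihoods, threshold) {
  ord <- order(likelihoods, decreasing = TRUE)
  top <- ord[1] # order() is stable: ties go to the lowest class index
  margin <- if (length(likelihoods) > 1) {
    likelihoods[ord[1]] - likelihoods[ord[2]]
  } else likelihoods[1]
  label <- if (margin < threshold) abstain_label() else names(likelihoods)[top]
  list(label = label, margin = unname(margin))
}

#' Decide a single classification event
#'
#' Outputs the class of maximum fused likelihood, or abstains when the two
#' top likelihoods are closer than the threshold (`margin < threshold`,
#' strictly, so threshold 0 never abstains except on exact ties, which
#' break towards the lowest class index).
#'
#' @param model A [fit_fusion()] model.
#' @param beliefs A `k x n` belief matrix.
#' @param threshold Abstention threshold; default the model's.
#' @return A list with `label` (class or [abstain_label()]),
#'   `class_likelihoods` and `margin`.
#' @export
decide <- function(model, beliefs, threshold = NULL) {
  lik <- aggregate_class_likelihoods(model, beliefs)
  d <- decide_from_likelihoods(lik, threshold %||% model$threshold)
  list(label = d$label, class_likelihoods = lik, margin = d$margin)
}

#' Predict decisions for a long score table
#'
#' @param object A [fit_fusion()] model.
#' @param new_scores Long score table with the model's classifiers and
#'   classes.
#' @param threshold Abstention threshold override; default the model's.
#' @param ... Unused.
#' @return A tibble with one row per sample: `sample_id`, `decision`
#'   (class label or [abstain_label()]), `margin`, one `lik_<class>`
#'   column per class, and `true_class` when present in the input.
#' @export
predict.fusion_model <- function(object, new_scores, threshold = NULL, ...) {
  new_scores <- validate_scores(new_scores)
  beliefs <- normalize_scores(new_scores, object$normalization)
  parts <- scores_to_matrices(beliefs, value_col = "belief")
  if (!identical(parts$classifiers, object$classifiers)) {
    stop("new data's classifiers do not match the model's", call. = FALSE)
  }
  if (!identical(parts$classes, object$classes)) {
    stop("new data's classes do not match the model's", call. = FALSE)
  }
  thr <- threshold %||% object$threshold
  rows <- purrr::map(seq_along(parts$matrices), function(t) {
    lik <- aggregate_class_likelihoods(object, parts$matrices[[t]])
    d <- decide_from_likelihoods(lik, thr)
    out <- tibble::tibble(sample_id = parts$samples[t], decision = d$label,
                          margin = d$margin)
    out[paste0("lik_", names(lik))] <- as.list(unname(lik))
    out
  })
  res <- dplyr::bind_rows(rows)
  if (!is.null(parts$truth)) res$true_class <- unname(parts$truth)
  res
}

#' Sweep the abstention threshold over a grid
#'
#' Computes, for every grid point, the counts of correct decisions,
#' errors and abstentions on a labelled dataset, plus the efficiency and
#' Nykopp ITR of the resulting confusion table. Because a sample abstains
#' exactly when its fixed margin falls below the threshold, errors are
#' non-increasing and abstentions non-decreasing along the grid.
#'
#' @param model A [fit_fusion()] model.
#' @param scores Labelled long score table.
#' @param grid Numeric vector of thresholds. Default `seq(0, 1, 0.01)`.
#' @return A tibble of class `"fusion_sweep"` with columns `threshold`,
#'   `correct`, `errors`, `abstentions`, `efficiency`, `itr`.
#' @export
threshold_sweep <- function(model, scores, grid = seq(0, 1, by = 0.01)) {
  if (length(grid) == 0) stop("grid must be nonempty", call. = FALSE)
  base <- predict(model, scores, threshold = 0)
  if (!"true_class" %in% names(base)) stop("scores must carry true_class", call. = FALSE)
  rows <- purrr::map(sort(grid), function(th) {
    dec <- ifelse(base$margin < th, abstain_label(), base$decision)
    tab <- confusion_with_abstention(base$true_class, dec, classes = model$classes)
    tibble::tibble(
      threshold = th,
      correct = sum(diag(tab[, seq_len(model$n), drop = FALSE])),
      errors = sum(tab[, seq_len(model$n)]) - sum(diag(tab[, seq_len(model$n), drop = FALSE])),
      abstentions = sum(tab[, model$n + 1L]),
      efficiency = efficiency(tab),
      itr = nykopp_itr(tab)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fusion_sweep", class(out))
  out
}

#' Tune the abstention threshold by grid search
#'
#' Evaluates the metric on the validation confusion table at every grid
#' point and returns the maximizing threshold (ties towards the smallest
#' threshold). Grid points where the metric is not defined (ND) are
#' skipped; if it is ND on the whole grid the search either falls back to
#' the ITR (`allow_fallback = TRUE`, the default, since the ITR is always
#' defined) or fails.
#'
#' @param model A [fit_fusion()] model.
#' @param scores Labelled validation score table.
#' @param metric `"efficiency"` (default) or `"itr"`.
#' @param grid Threshold grid; default `seq(0, 1, 0.01)`.
#' @param allow_fallback Fall back to ITR when efficiency is ND on the
#'   entire grid.
#' @return A list with `threshold`, `metric`, `value`, and the full
#'   `sweep` table.
#' @export
search_threshold <- function(model, scores, metric = c("efficiency", "itr"),
                             grid = seq(0, 1, by = 0.01), allow_fallback = TRUE) {
  metric <- match.arg(metric)
  sweep <- threshold_sweep(model, scores, grid)
  vals <- sweep[[metric]]
  if (all(is.na(vals))) {
    if (metric == "efficiency" && allow_fallback) {
      metric <- "itr"
      vals <- sweep[[metric]]
    } else {
      stop(sprintf("%s is not defined (ND) at every grid point", metric), call. = FALSE)
    }
  }
  best <- which(vals == max(vals, na.rm = TRUE))[1] # smallest threshold on ties
  list(threshold = sweep$threshold[best], metric = metric,
       value = vals[best], sweep = sweep)
}

#' Tune a fitted model's threshold in place
#'
#' Convenience wrapper around [search_threshold()] that returns the model
#' with its `threshold` replaced by the tuned value.
#'
#' @inheritParams search_threshold
#' @return The model, with `threshold` updated.
#' @export
tune_threshold <- function(model, scores, metric = c("efficiency", "itr"),
                           grid = seq(0, 1, by = 0.01), allow_fallback = TRUE) {
  res <- search_threshold(model, scores, metric = metric, grid = grid,
                          allow_fallback = allow_fallback)
  model$threshold <- res$threshold
  model
}

#' Tidy a fusion model: classifier importance per class
#'
#' @param x A [fit_fusion()] model.
#' @param ... Unused.
#' @return A tibble with one row per (class, classifier): the Shapley
#'   value of the classifier under that class's global capacity, whether
#'   it entered the ensemble, and its selection rank (NA if unselected).
#' @export
tidy.fusion_model <- function(x, ...) {
  purrr::map_dfr(x$classes, function(cls) {
    v <- shapley_values(x$global_capacities[[cls]])
    members <- x$ensembles[[cls]]$members
    tibble::tibble(
      class = cls,
      classifier = x$classifiers,
      shapley = v,
      in_ensemble = (seq_along(v) - 1L) %in% members,
      selection_rank = match(seq_along(v) - 1L, members)
    )
  })
}

#' One-row summary of a fusion model
#'
#' @param x A [fit_fusion()] model.
#' @param ... Unused.
#' @return A tibble with dimensions, orders, ridge and threshold.
#' @export
glance.fusion_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = x$n, s = x$s, global_order = x$global_order,
    ridge = x$ridge, threshold = x$threshold,
    slope = x$normalization$slope
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
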