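# Class-specific ensembles: greedy coalition growth driven by the
# extended interaction index of the augmented coalition.

#' Build one class ensemble by greedy interaction maximization
#'
#' Starting from the empty ensemble, repeatedly appends the classifier `D`
#' (not yet a member) maximizing the extended interaction index of the
#' augmented coalition `E + D` under the supplied capacity, until `s`
#' members are reached. Because the interaction index of a singleton is
#' the Shapley value, the first member is always the most important
#' classifier. Interaction ties (within 1e-12) break towards the higher
#' Shapley value, then towards the lowest classifier index; a 1-additive
#' capacity — zero interaction for every augmented coalition beyond the
#' first — therefore selects exactly the top-s Shapley ranking, and the
#' selection is deterministic.
#'
#' @param global_capacity A [capacity()] on all `k` classifiers (typically
#'   the class's one-vs-rest s-additive capacity).
#' @param s Target ensemble size, `1 <= s <= k`.
#' @param early_stop If `TRUE`, stop once the best marginal interaction is
#'   negative (the ensemble may then have fewer than `s` members). Default
#'   `FALSE`: always fill to `s`.
#' @return A list of class `"ensemble"` with `members` (0-based classifier
#'   indices in selection order), `s`, and `criterion` (the interaction
#'   index value at each selection step).
#' @export
build_class_ensemble <- function(global_capacity, s, early_stop = FALSE) {
  stopifnot(inherits(global_capacity, "capacity"))
  k <- global_capacity$n_elements
  if (s < 1 || s > k) stop("s must be in [1, k]", call. = FALSE)
  shap <- shapley_values(global_capacity)
  members <- integer(0)
  crit <- numeric(0)
  while (length(members) < s) {
    candidates <- setdiff(0:(k - 1L), members)
    vals <- vapply(candidates, function(d) {
      extended_interaction_index(global_capacity, c(members, d))
    }, 0)
    tied <- which(vals >= max(vals) - 1e-12)
    best <- tied[order(-shap[candidates[tied] + 1L], candidates[tied])][1]
    if (early_stop && length(members) > 0 && vals[best] < 0) break
    members <- c(members, candidates[best])
    crit <- c(crit, vals[best])
  }
  structure(list(members = members, s = as.integer(s), criterion = crit),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> members (selection order): %s\n",
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Build all class ensembles
#'
#' @param global_capacities A list with one capacity per class (each on
#'   the full classifier set).
#' @param s Ensemble size cap; the study setting uses `s = 4` of `k = 6`.
#' @param early_stop Passed to [build_class_ensemble()].
#' @return A named list of `"ensemble"` objects, one per class.
#' @export
build_all_ensembles <- function(global_capacities, s = 4, early_stop = FALSE) {
  lapply(global_capacities, build_class_ensemble, s = s, early_stop = early_stop)
}
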