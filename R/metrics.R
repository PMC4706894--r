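# BCI evaluation metrics: confusion table with an abstention column,
# copy-spelling efficiency with the not-defined (ND) convention, Nykopp's
# information transfer rate (channel capacity of the confusion matrix),
# and percentage-improvement summaries.

#' Confusion table with an abstention column
#'
#' Tallies true labels against decisions into an `n x (n + 1)` count
#' matrix whose last column holds abstentions.
#'
#' @param truth Vector of true class labels.
#' @param decisions Vector of decisions: class labels or [abstain_label()].
#' @param classes Class label set; defaults to the sorted unique truth
#'   labels.
#' @return An integer matrix of class `"confusion_abstention"` with
#'   class-labelled rows and columns plus an `"ABSTAIN"` column.
#' @export
confusion_with_abstention <- function(truth, decisions, classes = NULL) {
  if (length(truth) != length(decisions)) {
    stop("truth and decisions must have equal length", call. = FALSE)
  }
  truth <- as.character(truth)
  decisions <- as.character(decisions)
  if (is.null(classes)) classes <- sort(unique(truth))
  classes <- as.character(classes)
  if (!all(truth %in% classes)) {
    stop("unknown true-class label", call. = FALSE)
  }
  if (!all(decisions %in% c(classes, abstain_label()))) {
    stop(sprintf("unknown decision label: %s",
                 setdiff(decisions, c(classes, abstain_label()))[1]), call. = FALSE)
  }
  n <- length(classes)
  counts <- matrix(0L, n, n + 1L,
                   dimnames = list(classes, c(classes, abstain_label())))
  for (t in seq_along(truth)) {
    counts[truth[t], decisions[t]] <- counts[truth[t], decisions[t]] + 1L
  }
  structure(counts, class = c("confusion_abstention", class(counts)))
}

# correct / error / abstention rates of a confusion table
confusion_rates <- function(table) {
  total <- sum(table)
  if (total == 0) stop("empty confusion table", call. = FALSE)
  n <- nrow(table)
  correct <- sum(diag(table[, seq_len(n), drop = FALSE]))
  decided <- sum(table[, seq_len(n)])
  list(p_c = correct / total, p_e = (decided - correct) / total,
       p_a = sum(table[, n + 1L]) / total)
}

#' Copy-spelling efficiency
#'
#' Net correctly communicated symbols per emission in a copy-spelling
#' task where every error must be undone: `p_c - p_e`, with `p_c`, `p_e`,
#' `p_a` the correct/error/abstention rates. When `p_c <= p_e` the system
#' does not allow effective communication and the metric is not defined
#' (ND), returned as `NA`. Abstentions cost time but need no undo, so they
#' enter only by shrinking `p_c + p_e`.
#'
#' @param table A [confusion_with_abstention()] matrix.
#' @return A number in `(0, 1]`, or `NA` (ND).
#' @export
efficiency <- function(table) {
  r <- confusion_rates(table)
  val <- r$p_c - r$p_e
  if (val <= 0) NA_real_ else val
}

#' Nykopp's information transfer rate (bits per symbol)
#'
#' Treats the row-normalized confusion table (abstention as an extra
#' output symbol, so rejections are credited rather than penalized as
#' errors) as a discrete memoryless channel and returns its capacity: the
#' maximum over input distributions of the mutual information, computed by
#' Blahut-Arimoto alternating maximization. Bounded by `log2(n)`.
#'
#' @param table A [confusion_with_abstention()] matrix (or any
#'   non-negative count/probability matrix; rows summing to zero are
#'   dropped).
#' @param tol Relative convergence tolerance on the capacity. Default 1e-9.
#' @param max_iter Iteration cap.
#' @return Capacity in bits per symbol.
#' @export
nykopp_itr <- function(table, tol = 1e-9, max_iter = 100000L) {
  Q <- unclass(as.matrix(table))
  if (length(Q) == 0 || sum(Q) == 0) stop("empty confusion table", call. = FALSE)
  if (any(Q < 0)) stop("counts must be non-negative", call. = FALSE)
  Q <- Q[rowSums(Q) > 0, , drop = FALSE]
  Q <- Q / rowSums(Q)
  m <- nrow(Q)
  if (m == 1) return(0)
  p <- rep(1 / m, m)
  IL <- 0; IU <- Inf
  for (it in seq_len(max_iter)) {
    q <- as.numeric(p %*% Q)
    # per-input divergence D(Q(.|x) || q), in nats; 0 log 0 = 0
    D <- vapply(seq_len(m), function(x) {
      nz <- Q[x, ] > 0
      sum(Q[x, nz] * log(Q[x, nz] / q[nz]))
    }, 0)
    IL <- sum(p * D)      # lower bound on capacity at current p
    IU <- max(D)          # upper bound
    if (IU - IL <= tol * max(IU, .Machine$double.eps)) break
    p <- p * exp(D)
    p <- p / sum(p)
  }
  # the bounds always bracket the capacity; the midpoint errs by <= gap/2.
  # Convergence is O(1/iter) when the optimal input distribution has
  # boundary support, so a loose residual bracket gets flagged.
  if (IU - IL > 1e-6) {
    warning(sprintf("channel capacity bracketed only to within %.3g bits",
                    (IU - IL) / log(2)))
  }
  (IL + IU) / (2 * log(2))
}

#' Percentage improvement of a value over a reference
#'
#' `100 * (value - reference) / reference`. `NA` (ND) inputs propagate.
#'
#' @param value Achieved metric value(s).
#' @param reference Baseline value(s); zero is an error.
#' @return Percentage(s).
#' @export
#' @examples
#' percentage_improvement(0.5789, mean(c(0.4619, 0.4837, 0.2358,
#'                                       0.2774, 0.5145, 0.4143)))
percentage_improvement <- function(value, reference) {
  if (any(!is.na(reference) & reference == 0)) {
    stop("reference must be nonzero", call. = FALSE)
  }
  100 * (value - reference) / reference
}

#' Evaluate decisions against true labels
#'
#' Convenience wrapper building the confusion table and the two headline
#' metrics from a decisions tibble (as returned by
#' [predict.fusion_model()]).
#'
#' @param decisions Tibble with `true_class` and `decision` columns.
#' @param classes Optional class label set.
#' @return A tibble with `p_correct`, `p_error`, `p_abstain`,
#'   `efficiency` (NA when ND) and `itr_bits`.
#' @export
evaluate_decisions <- function(decisions, classes = NULL) {
  tab <- confusion_with_abstention(decisions$true_class, decisions$decision,
                                   classes = classes)
  r <- confusion_rates(tab)
  tibble::tibble(
    p_correct = r$p_c, p_error = r$p_e, p_abstain = r$p_a,
    efficiency = efficiency(tab), itr_bits = nykopp_itr(tab)
  )
}
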