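# Capacity identification from training beliefs: least squares in the
# Moebius coefficients under monotonicity and normalization constraints,
# solved as a convex quadratic program.

#' Design row linearizing the Choquet integral
#'
#' In Moebius form the Choquet integral is linear in the coefficients:
#' `C(f) = sum over B of m(B) * min(f[B])`. The design row for a belief
#' vector therefore holds, for each coalition `B` of size at most `order`
#' (canonical coalition order), the minimum belief over `B`; its dot
#' product with a Moebius vector is the Choquet integral of that capacity.
#'
#' @param beliefs Numeric vector of `k` beliefs in `[0, 1]`.
#' @param order Additivity order in `[1, k]`.
#' @return Numeric vector of length `mobius_support_size(k, order)`, named
#'   by coalition key.
#' @export
#' @examples
#' build_design_row(c(0.2, 0.8), order = 2) # (0.2, 0.8, 0.2)
build_design_row <- function(beliefs, order) {
  beliefs <- as.numeric(beliefs)
  k <- length(beliefs)
  if (order < 1 || order > k) stop("order must be in [1, k]", call. = FALSE)
  if (any(beliefs < -1e-12) || any(beliefs > 1 + 1e-12)) {
    stop("beliefs must lie in [0, 1]", call. = FALSE)
  }
  coals <- enumerate_coalitions(k, order)
  stats::setNames(vapply(coals, function(b) min(beliefs[b + 1L]), 0),
                  vapply(coals, coalition_key, ""))
}

# T x p design matrix of min-features for a T x k belief matrix.
build_design_matrix <- function(beliefs, order) {
  t(apply(beliefs, 1, build_design_row, order = order))
}

#' Learn a capacity from training beliefs
#'
#' Finds the Moebius coefficients `m` minimizing
#' `sum_t (x_t' m - y_t)^2 + ridge * ||m||^2` over capacities of the given
#' additivity order, subject to all monotonicity inequalities and the
#' normalization equality `sum(m) = 1`. The problem is a convex quadratic
#' program (strictly convex for `ridge > 0`) solved with
#' [quadprog::solve.QP()]; the returned capacity is normalized and passes
#' [check_monotonicity()] at `1e-8`.
#'
#' @param beliefs A `T x k` numeric matrix of per-sample classifier
#'   beliefs (or a data frame of `k` numeric columns).
#' @param targets Numeric vector of `T` targets in `[0, 1]`; the training
#'   pipeline uses the one-vs-rest indicator (1 when the sample belongs to
#'   the class the capacity scores), but any likelihood-like target is
#'   accepted, e.g. for recovery studies with Choquet-generated targets.
#' @param order Additivity order in `[1, k]`. Default: `k` (unrestricted).
#' @param ridge Non-negative ridge weight; the small default keeps the
#'   program strictly convex when the design is rank-deficient.
#' @return A normalized `"capacity"` on `k` elements.
#' @export
learn_capacity <- function(beliefs, targets, order = NULL, ridge = 1e-6) {
  beliefs <- as.matrix(beliefs)
  if (nrow(beliefs) < 1) stop("need at least one training sample", call. = FALSE)
  if (length(targets) != nrow(beliefs)) {
    stop("targets must match the number of belief rows", call. = FALSE)
  }
  if (any(!is.finite(targets)) || any(targets < 0) || any(targets > 1)) {
    stop("targets must lie in [0, 1]", call. = FALSE)
  }
  if (ridge < 0) stop("ridge must be non-negative", call. = FALSE)
  k <- ncol(beliefs)
  if (is.null(order)) order <- k
  if (order < 1 || order > k) stop("order must be in [1, k]", call. = FALSE)

  X <- build_design_matrix(beliefs, order)
  p <- ncol(X)
  Dmat <- 2 * (crossprod(X) + ridge * diag(p))
  dvec <- 2 * as.numeric(crossprod(X, targets))
  mono <- monotonicity_matrix(k, order)
  Amat <- t(rbind(rep(1, p), mono$mat)) # columns are constraints
  bvec <- c(1, rep(0, nrow(mono$mat)))
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1),
    error = function(e) {
      stop(sprintf("capacity QP failed: %s", conditionMessage(e)), call. = FALSE)
    }
  )
  m <- sol$solution
  m <- m / sum(m)           # re-impose the normalization exactly
  m[abs(m) < 1e-14] <- 0    # deterministic serialization of numeric zeros
  capacity(stats::setNames(m, colnames(X)), n_elements = k, order = order,
           validate = TRUE, tol = 1e-8)
}

#' Train global one-vs-rest capacities, ensembles, and class capacities
#'
#' The full training sequence behind [fit_fusion()], exposed for
#' inspection. For every class: (1) an s-additive capacity over all `k`
#' classifiers is learned on one-vs-rest binary targets from that class's
#' belief column; (2) the class ensemble of at most `s` classifiers is
#' built greedily by the extended interaction index of that capacity;
#' (3) a full-order capacity on the ensemble members is learned on the
#' same targets.
#'
#' @param beliefs Long belief table (from [normalize_scores()]) with
#'   `true_class`.
#' @param s Ensemble size cap (and default global additivity order).
#' @param global_order Additivity order of the global capacities.
#' @param class_order Additivity order of the per-ensemble capacities;
#'   default `NULL` means full order (ensemble size).
#' @param ridge Ridge weight passed to [learn_capacity()].
#' @param early_stop Stop adding ensemble members when the best marginal
#'   interaction is negative. Off by default: ensembles are filled to `s`.
#' @return A list with `global_capacities`, `ensembles` (see
#'   [build_class_ensemble()]) and `class_capacities`, each named by class.
#' @export
learn_all <- function(beliefs, s = 4, global_order = s, class_order = NULL,
                      ridge = 1e-6, early_stop = FALSE) {
  beliefs <- validate_scores(beliefs, require_truth = TRUE)
  if (!"belief" %in% names(beliefs)) {
    stop("beliefs table must carry a belief column; run normalize_scores() first",
         call. = FALSE)
  }
  parts <- scores_to_matrices(beliefs, value_col = "belief")
  k <- length(parts$classifiers)
  n <- length(parts$classes)
  if (s > k) stop("ensemble size s cannot exceed the number of classifiers", call. = FALSE)
  global_order <- min(global_order, k)

  # belief array: sample x classifier x class
  arr <- simplify2array(parts$matrices)      # k x n x T
  global_capacities <- list()
  ensembles <- list()
  class_capacities <- list()
  for (ci in seq_len(n)) {
    cls <- parts$classes[ci]
    B <- t(arr[, ci, , drop = TRUE])         # T x k beliefs for this class
    if (k == 1) B <- matrix(B, ncol = 1)
    y <- as.numeric(parts$truth == cls)
    gcap <- learn_capacity(B, y, order = global_order, ridge = ridge)
    ens <- build_class_ensemble(gcap, s = s, early_stop = early_stop)
    members <- ens$members
    ccap <- learn_capacity(B[, members + 1L, drop = FALSE], y,
                           order = if (is.null(class_order)) length(members)
                                   else min(class_order, length(members)),
                           ridge = ridge)
    global_capacities[[cls]] <- gcap
    ensembles[[cls]] <- ens
    class_capacities[[cls]] <- ccap
  }
  list(global_capacities = global_capacities, ensembles = ensembles,
       class_capacities = class_capacities,
       classifiers = parts$classifiers, classes = parts$classes)
}
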