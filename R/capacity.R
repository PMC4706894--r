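# Capacities (fuzzy measures) in Moebius representation, and the three
# set-function operators built on them: Choquet integral, Shapley value,
# extended interaction index.

#' Coalition key
#'
#' Canonical string key for a coalition of 0-based element indices:
#' sorted, comma-joined (e.g. `"0,2"`). Used as names of Moebius
#' coefficient vectors and as JSON keys when capacities are serialized.
#'
#' @param members Integer vector of 0-based element indices.
#' @return A single string.
#' @export
#' @examples
#' coalition_key(c(2, 0))
coalition_key <- function(members) {
  members <- as.integer(members)
  if (anyDuplicated(members)) stop("coalition has duplicate members", call. = FALSE)
  paste(sort(members), collapse = ",")
}

#' @rdname coalition_key
#' @param key A coalition key string.
#' @return For `coalition_members()`, the integer vector of 0-based indices.
#' @export
coalition_members <- function(key) {
  if (identical(key, "")) return(integer(0))
  as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
}

# All nonempty coalitions of {0, ..., n-1} with size <= max_size, in
# canonical order: by size, then lexicographically. Returns a list of
# integer vectors.
enumerate_coalitions <- function(n, max_size = n) {
  stopifnot(n >= 1, max_size >= 1, max_size <= n)
  out <- list()
  for (sz in seq_len(max_size)) {
    combs <- utils::combn(n, sz) - 1L
    out <- c(out, lapply(seq_len(ncol(combs)), function(j) combs[, j]))
  }
  out
}

#' Number of Moebius coefficients of a k-additive capacity
#'
#' A k-additive capacity on a ground set of `n` elements is determined by
#' the Moebius coefficients of the coalitions of size at most `k`, i.e.
#' `sum(choose(n, 1:k))` numbers; with `k = n` this is the full `2^n - 1`.
#' Limiting `k` trades expressiveness (higher-order synergies) for
#' tractability.
#'
#' @param n Number of elements in the ground set.
#' @param k Additivity order, in `[1, n]`.
#' @return An integer count.
#' @export
#' @examples
#' mobius_support_size(6, 2) # 21
#' mobius_support_size(6, 6) # 2^6 - 1
mobius_support_size <- function(n, k) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (k < 1 || k > n) stop("k must be in [1, n]", call. = FALSE)
  as.integer(sum(choose(n, seq_len(k))))
}

#' Construct a capacity from Moebius coefficients
#'
#' A capacity (fuzzy measure) is a monotone set function with
#' `mu(empty) = 0`; it is stored here through its Moebius transform, the
#' coefficients `m(B)` such that `mu(A) = sum over B subset of A of m(B)`.
#' k-additivity is then a storage truncation: coefficients exist only for
#' coalitions of size at most `order`.
#'
#' @param mobius Named numeric vector of Moebius coefficients; names are
#'   [coalition_key()] strings over 0-based element indices.
#' @param n_elements Size of the ground set. Defaults to one more than the
#'   largest index referenced.
#' @param order Additivity order; defaults to the largest named coalition
#'   size. Coefficients for larger coalitions are an error.
#' @param validate If `TRUE` (default), monotonicity is checked at
#'   tolerance `tol` and violations raise an error.
#' @param tol Monotonicity tolerance used when `validate = TRUE`.
#' @return An object of class `"capacity"`.
#' @export
#' @examples
#' cap <- capacity(c("0" = 0.5, "1" = 0.3, "0,1" = 0.2))
#' measure_value(cap, c(0, 1))
capacity <- function(mobius, n_elements = NULL, order = NULL,
                     validate = TRUE, tol = 1e-8) {
  if (is.null(names(mobius)) || any(!nzchar(names(mobius)))) {
    stop("mobius must be a named vector keyed by coalition", call. = FALSE)
  }
  members <- lapply(names(mobius), coalition_members)
  if (any(vapply(members, length, 1L) == 0L)) {
    stop("the empty coalition carries no coefficient (mu(empty) = 0)", call. = FALSE)
  }
  max_idx <- max(vapply(members, max, 0L))
  if (is.null(n_elements)) n_elements <- max_idx + 1L
  n_elements <- as.integer(n_elements)
  if (max_idx >= n_elements) {
    stop("coalition references element index >= n_elements", call. = FALSE)
  }
  sizes <- vapply(members, length, 1L)
  if (is.null(order)) order <- max(sizes)
  order <- as.integer(order)
  if (order < 1L || order > n_elements) stop("order must be in [1, n]", call. = FALSE)
  if (any(sizes > order)) {
    stop("Moebius coefficient on a coalition larger than the additivity order",
         call. = FALSE)
  }
  # canonicalize: fill every coalition up to `order`, canonical ordering
  keys_all <- vapply(enumerate_coalitions(n_elements, order), coalition_key, "")
  # re-key input names canonically (sorting members) before matching
  names(mobius) <- vapply(members, coalition_key, "")
  if (anyDuplicated(names(mobius))) stop("duplicate coalition keys", call. = FALSE)
  m <- stats::setNames(numeric(length(keys_all)), keys_all)
  m[names(mobius)] <- as.numeric(mobius)
  cap <- structure(
    list(
      n_elements = n_elements,
      order = order,
      mobius = m,
      members = lapply(keys_all, coalition_members),
      normalized = isTRUE(all.equal(sum(m), 1, tolerance = 1e-9))
    ),
    class = "capacity"
  )
  if (validate) {
    bad <- check_monotonicity(cap, tolerance = tol)
    if (nrow(bad) > 0) {
      stop(sprintf("capacity violates monotonicity (%d constraints, worst margin %.3g)",
                   nrow(bad), min(bad$margin)), call. = FALSE)
    }
  }
  cap
}

#' @export
print.capacity <- function(x, ...) {
  cat(sprintf("<capacity> n = %d, order = %d, %snormalized\n",
              x$n_elements, x$order, if (x$normalized) "" else "not "))
  nz <- x$mobius[x$mobius != 0]
  cat(sprintf("  %d nonzero Moebius coefficients of %d\n", length(nz), length(x$mobius)))
  invisible(x)
}

#' Additive capacity from singleton weights
#'
#' @param weights Non-negative singleton weights, one per element.
#' @return A 1-additive `"capacity"`.
#' @export
capacity_additive <- function(weights) {
  capacity(stats::setNames(as.numeric(weights), as.character(seq_along(weights) - 1L)),
           n_elements = length(weights), order = 1L)
}

#' Capacity from tabulated measure values (Moebius inversion)
#'
#' Builds a capacity from the `2^n - 1` values `mu(A)` by Moebius
#' inversion `m(A) = sum over B subset of A of (-1)^(|A| - |B|) mu(B)`.
#'
#' @param mu Named numeric vector of measure values keyed by
#'   [coalition_key()], covering every nonempty coalition.
#' @param n_elements Ground set size.
#' @inheritParams capacity
#' @return A `"capacity"` of full order `n_elements`.
#' @export
capacity_from_measure <- function(mu, n_elements, validate = TRUE, tol = 1e-8) {
  coals <- enumerate_coalitions(n_elements)
  keys <- vapply(coals, coalition_key, "")
  if (!setequal(names(mu), keys)) {
    stop("mu must tabulate every nonempty coalition exactly once", call. = FALSE)
  }
  lookup <- function(members) {
    if (length(members) == 0) 0 else unname(mu[[coalition_key(members)]])
  }
  m <- vapply(coals, function(A) {
    subs <- subsets_of(A)
    sum(vapply(subs, function(B) (-1)^(length(A) - length(B)) * lookup(B), 0))
  }, 0)
  capacity(stats::setNames(m, keys), n_elements = n_elements,
           order = n_elements, validate = validate, tol = tol)
}

# all subsets (including empty) of an integer vector
subsets_of <- function(members) {
  n <- length(members)
  if (n == 0) return(list(integer(0)))
  out <- vector("list", 2^n)
  for (mask in 0:(2^n - 1)) {
    out[[mask + 1]] <- members[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
  }
  out
}

#' Measure value of a coalition
#'
#' `mu(A) = sum over B subset of A of m(B)`; the empty coalition has
#' measure 0 by construction.
#'
#' @param cap A [capacity()].
#' @param subset Integer vector of 0-based element indices (may be empty).
#' @return `mu(subset)`.
#' @export
measure_value <- function(cap, subset) {
  stopifnot(inherits(cap, "capacity"))
  subset <- as.integer(subset)
  if (length(subset) == 0) return(0)
  if (any(subset < 0L) || any(subset >= cap$n_elements)) {
    stop("subset references element outside the ground set", call. = FALSE)
  }
  inside <- vapply(cap$members, function(b) all(b %in% subset), TRUE)
  sum(cap$mobius[inside])
}

#' Choquet integral of a non-negative integrand
#'
#' Integrates `f >= 0` against the capacity. In Moebius form the integral
#' is `sum over B of m(B) * min(f[B])`, equivalent to the sorted
#' level-set expression `sum_i (f(x_(i)) - f(x_(i-1))) * mu(A_i)`; for an
#' additive capacity it reduces to the weighted arithmetic mean.
#'
#' @param cap A [capacity()].
#' @param f Numeric vector of `n_elements` non-negative values.
#' @return A single number.
#' @export
#' @examples
#' cap <- capacity_additive(c(0.5, 0.5))
#' choquet_integral(cap, c(0.2, 0.8)) # 0.5
choquet_integral <- function(cap, f) {
  stopifnot(inherits(cap, "capacity"))
  f <- as.numeric(f)
  if (length(f) != cap$n_elements) {
    stop(sprintf("integrand has length %d, capacity has %d elements",
                 length(f), cap$n_elements), call. = FALSE)
  }
  if (any(!is.finite(f))) stop("integrand must be finite", call. = FALSE)
  if (any(f < 0)) stop("integrand must be non-negative", call. = FALSE)
  mins <- vapply(cap$members, function(b) min(f[b + 1L]), 0)
  sum(cap$mobius * mins)
}

#' Shapley values (importance indices)
#'
#' The Shapley value of element `x` is its marginal contribution
#' `mu(A + x) - mu(A)` averaged over coalitions `A` with the usual
#' permutation weights; in Moebius form `v[x] = sum over B containing x of
#' m(B) / |B|`. Shapley values always sum to `mu(X)` (efficiency).
#'
#' @param cap A [capacity()].
#' @return Numeric vector of length `n_elements`.
#' @export
shapley_values <- function(cap) {
  stopifnot(inherits(cap, "capacity"))
  v <- numeric(cap$n_elements)
  for (j in seq_along(cap$mobius)) {
    b <- cap$members[[j]]
    v[b + 1L] <- v[b + 1L] + cap$mobius[[j]] / length(b)
  }
  v
}

#' Extended (generalized) interaction index of a coalition
#'
#' Signed synergy of a coalition `S`: positive when its members are
#' complementary, negative when redundant, zero beyond singletons for
#' additive capacities. In Moebius form
#' `I(S) = sum over B containing S of m(B) / (|B| - |S| + 1)`. For a
#' singleton it equals that element's Shapley value, of which the index is
#' a proper generalization; for `|S| = 2` it is the Murofushi-Soneda
#' pairwise interaction index.
#'
#' @param cap A [capacity()].
#' @param s_coalition Nonempty integer vector of 0-based element indices.
#' @return A single number.
#' @export
extended_interaction_index <- function(cap, s_coalition) {
  stopifnot(inherits(cap, "capacity"))
  s <- as.integer(s_coalition)
  if (length(s) == 0) stop("coalition must be nonempty", call. = FALSE)
  if (any(s < 0L) || any(s >= cap$n_elements)) {
    stop("coalition references element outside the ground set", call. = FALSE)
  }
  tot <- 0
  for (j in seq_along(cap$mobius)) {
    b <- cap$members[[j]]
    if (all(s %in% b)) tot <- tot + cap$mobius[[j]] / (length(b) - length(s) + 1)
  }
  tot
}

#' Check capacity monotonicity
#'
#' A capacity must satisfy `mu(A) <= mu(B)` whenever `A` is a subset of
#' `B`; equivalently, for every element `x` and every coalition `A` not
#' containing `x`, the Moebius sum `sum over B subset of A of m(B + x)`
#' must be non-negative. Returns the violated constraints.
#'
#' @param cap A [capacity()] (or a capacity built with `validate = FALSE`).
#' @param tolerance Margins below `-tolerance` count as violations.
#' @return A tibble with columns `element` (0-based index), `subset`
#'   (coalition key of `A`) and `margin` (the constraint value; negative
#'   means violated). Zero rows means the capacity is monotone.
#' @export
check_monotonicity <- function(cap, tolerance = 1e-8) {
  stopifnot(inherits(cap, "capacity"))
  n <- cap$n_elements
  rows <- monotonicity_matrix(n, cap$order)
  margins <- as.numeric(rows$mat %*% cap$mobius)
  bad <- margins < -tolerance
  tibble::tibble(
    element = rows$element[bad],
    subset = rows$subset[bad],
    margin = margins[bad]
  )
}

# Monotonicity constraint rows over the canonical coalition basis of
# (n, order): one row per (element x, A subset of X \ {x}); row %*% m >= 0.
# Shared by check_monotonicity and the learning QP.
monotonicity_matrix <- function(n, order) {
  coals <- enumerate_coalitions(n, order)
  keys <- vapply(coals, coalition_key, "")
  p <- length(coals)
  n_rows <- n * 2^(n - 1)
  mat <- matrix(0, nrow = n_rows, ncol = p, dimnames = list(NULL, keys))
  element <- integer(n_rows)
  subset <- character(n_rows)
  r <- 0L
  for (x in 0:(n - 1L)) {
    others <- setdiff(0:(n - 1L), x)
    for (A in subsets_of(others)) {
      r <- r + 1L
      element[r] <- x
      subset[r] <- coalition_key(A)
      for (j in seq_len(p)) {
        b <- coals[[j]]
        if (x %in% b && all(setdiff(b, x) %in% A)) mat[r, j] <- 1
      }
    }
  }
  list(mat = mat, element = element, subset = subset)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a capacity into one row per coalition
#'
#' @param x A [capacity()].
#' @param ... Unused.
#' @return A tibble with `coalition`, `size`, `mobius`, `measure` and
#'   `interaction` (the extended interaction index of the coalition).
#' @export
tidy.capacity <- function(x, ...) {
  tibble::tibble(
    coalition = names(x$mobius),
    size = vapply(x$members, length, 1L),
    mobius = unname(x$mobius),
    measure = vapply(x$members, function(b) measure_value(x, b), 0),
    interaction = vapply(x$members, function(b) extended_interaction_index(x, b), 0)
  )
}

#' One-row summary of a capacity
#'
#' @param x A [capacity()].
#' @param ... Unused.
#' @return A tibble with ground-set size, order, total mass `mu(X)`,
#'   normalization flag and the worst monotonicity margin.
#' @export
glance.capacity <- function(x, ...) {
  rows <- monotonicity_matrix(x$n_elements, x$order)
  tibble::tibble(
    n_elements = x$n_elements,
    order = x$order,
    mass = sum(x$mobius),
    normalized = x$normalized,
    min_monotonicity_margin = min(as.numeric(rows$mat %*% x$mobius))
  )
}
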