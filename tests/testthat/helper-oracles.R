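# Literal brute-force evaluations of the three set-function operators,
# working directly on a named Moebius vector (keys "0,2", ...), kept
# independent of the package's internal representation.

oracle_members <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1]])

# mu(A) by direct subset-sum over Moebius terms
oracle_mu <- function(mobius, subset) {
  if (length(subset) == 0) return(0)
  tot <- 0
  for (key in names(mobius)) {
    if (all(oracle_members(key) %in% subset)) tot <- tot + mobius[[key]]
  }
  tot
}

# all subsets of an index vector, via binary masks
oracle_subsets <- function(members) {
  n <- length(members)
  lapply(0:(2^n - 1), function(mask) {
    members[bitwAnd(mask, bitwShiftL(1L, seq_len(max(n, 1)) - 1L)) != 0L]
  })
}

# Choquet integral: permute so f ascending (ties by element index),
# sum (f(x_i) - f(x_(i-1))) * mu(A_i) with A_i the upper-level set.
oracle_choquet <- function(mobius, n, f) {
  ord <- order(f, seq_len(n)) # ascending, index tie-break
  fs <- f[ord]
  prev <- 0
  tot <- 0
  for (i in seq_len(n)) {
    upper <- ord[i:n] - 1L
    tot <- tot + (fs[i] - prev) * oracle_mu(mobius, upper)
    prev <- fs[i]
  }
  tot
}

# Shapley value: weighted marginal contributions over all A excluding x.
oracle_shapley <- function(mobius, n) {
  vapply(0:(n - 1L), function(x) {
    others <- setdiff(0:(n - 1L), x)
    tot <- 0
    for (A in oracle_subsets(others)) {
      w <- factorial(n - length(A) - 1) * factorial(length(A)) / factorial(n)
      tot <- tot + w * (oracle_mu(mobius, c(A, x)) - oracle_mu(mobius, A))
    }
    tot
  }, 0)
}

# Extended interaction index: double sum over A excluding S and B within S,
# with sign (-1)^(|S| - |B|).
oracle_interaction <- function(mobius, n, S) {
  others <- setdiff(0:(n - 1L), S)
  tot <- 0
  for (A in oracle_subsets(others)) {
    w <- factorial(n - length(A) - length(S)) * factorial(length(A)) /
      factorial(n - length(S) + 1)
    inner <- 0
    for (B in oracle_subsets(S)) {
      inner <- inner + (-1)^(length(S) - length(B)) * oracle_mu(mobius, c(A, B))
    }
    tot <- tot + w * inner
  }
  tot
}

# Murofushi-Soneda pairwise interaction of {x, y}, computed from its own
# definition: weighted second differences over A excluding both.
oracle_pairwise_ms <- function(mobius, n, x, y) {
  others <- setdiff(0:(n - 1L), c(x, y))
  tot <- 0
  for (A in oracle_subsets(others)) {
    w <- factorial(n - length(A) - 2) * factorial(length(A)) / factorial(n - 1)
    tot <- tot + w * (oracle_mu(mobius, c(A, x, y)) - oracle_mu(mobius, c(A, x)) -
                        oracle_mu(mobius, c(A, y)) + oracle_mu(mobius, A))
  }
  tot
}

# --- random valid capacities for property tests ---

# totally monotone (belief-function) capacity: positive random Moebius mass
# on coalitions up to `order`, normalized
rand_capacity_positive <- function(n, order = n) {
  coals <- choqfuse:::enumerate_coalitions(n, order)
  w <- stats::rexp(length(coals))
  w <- w / sum(w)
  capacity(stats::setNames(w, vapply(coals, coalition_key, "")),
           n_elements = n, order = order)
}

# monotone capacity with (generally) signed Moebius terms: mu(A) is the
# running max of uniform draws over subsets, normalized, then inverted
rand_capacity_signed <- function(n) {
  coals <- choqfuse:::enumerate_coalitions(n)
  keys <- vapply(coals, coalition_key, "")
  u <- stats::setNames(stats::runif(length(coals)), keys)
  mu <- stats::setNames(vapply(coals, function(A) {
    max(vapply(keys, function(k2) {
      b <- oracle_members(k2)
      if (all(b %in% A)) u[[k2]] else 0
    }, 0))
  }, 0), keys)
  mu <- mu / mu[[coalition_key(0:(n - 1L))]]
  capacity_from_measure(mu, n_elements = n)
}

rand_capacity <- function(n, order = n) {
  if (order < n && stats::runif(1) < 0.5) return(rand_capacity_positive(n, order))
  if (stats::runif(1) < 0.5) rand_capacity_positive(n, order) else rand_capacity_signed(n)
}
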