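test_that("confusion tables tally truth against decisions and abstentions", {
  classes <- paste0("C", 1:6)
  tab <- confusion_with_abstention(classes, classes, classes)
  expect_equal(unname(diag(tab[, 1:6])), rep(1L, 6))
  expect_equal(sum(tab[, 7]), 0L)

  all_abs <- confusion_with_abstention(classes, rep(abstain_label(), 6), classes)
  expect_equal(sum(all_abs[, 1:6]), 0L)
  expect_equal(unname(all_abs[, 7]), rep(1L, 6))

  set.seed(61)
  truth <- sample(classes, 200, replace = TRUE)
  dec <- sample(c(classes, abstain_label()), 200, replace = TRUE)
  tab <- confusion_with_abstention(truth, dec, classes)
  expect_equal(sum(tab), 200L)
  for (rep in 1:20) {
    i <- sample(classes, 1); j <- sample(c(classes, abstain_label()), 1)
    expect_equal(tab[i, j], sum(truth == i & dec == j))
  }
  expect_error(confusion_with_abstention("C1", "C9", classes), "unknown decision")
})

test_that("Nykopp ITR reproduces closed-form channel capacities", {
  # noiseless 6-symbol channel
  ident <- cbind(diag(6), 0)
  expect_equal(nykopp_itr(ident), log2(6), tolerance = 1e-9)
  # useless channel: identical rows
  useless <- matrix(rep(c(0.2, 0.3, 0.5), 3), 3, byrow = TRUE)
  expect_equal(nykopp_itr(useless), 0, tolerance = 1e-9)
  # binary symmetric channel with flip 0.1: capacity 1 - H(0.1)
  bsc <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  H <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(nykopp_itr(bsc), 1 - H(0.1), tolerance = 1e-6)
  expect_error(nykopp_itr(matrix(0, 2, 2)), "empty")
})

test_that("alternating maximization agrees with a grid over 2-input channels", {
  set.seed(62)
  for (rep in 1:10) {
    Q <- matrix(rexp(2 * 3), 2, 3)
    Q <- Q / rowSums(Q)
    mi <- function(p1) {
      p <- c(p1, 1 - p1)
      q <- as.numeric(p %*% Q)
      sum(vapply(1:2, function(x) {
        nz <- Q[x, ] > 0
        p[x] * sum(Q[x, nz] * log2(Q[x, nz] / q[nz]))
      }, 0))
    }
    grid_best <- max(vapply(seq(0, 1, by = 1e-4), mi, 0))
    expect_equal(nykopp_itr(Q), grid_best, tolerance = 1e-4)
  }
})

test_that("ITR is bounded by log2(n) and maximal only for permutation channels", {
  set.seed(63)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    Q <- matrix(rexp(n * (n + 1)), n)
    expect_lte(nykopp_itr(Q), log2(n) + 1e-9)
  }
  perm <- cbind(diag(4)[, c(3, 1, 4, 2)], 0)
  expect_equal(nykopp_itr(perm), 2, tolerance = 1e-9)
  noisy <- cbind(diag(4) * 0.9 + 0.025, 0)
  expect_lt(nykopp_itr(noisy), 2)
})

test_that("efficiency is net progress with the ND convention", {
  classes <- paste0("C", 1:4)
  perfect <- confusion_with_abstention(classes, classes, classes)
  expect_equal(efficiency(perfect), 1.0)

  # p_c = 0.3, p_e = 0.5, p_a = 0.2 -> ND
  tab <- matrix(0, 2, 3, dimnames = list(c("a", "b"), c("a", "b", "ABSTAIN")))
  tab["a", "a"] <- 3; tab["a", "b"] <- 5; tab["a", "ABSTAIN"] <- 2
  expect_true(is.na(efficiency(tab)))

  # p_c = 0.8, p_e = 0.1, p_a = 0.1 -> 0.7
  tab2 <- matrix(0, 2, 3, dimnames = list(c("a", "b"), c("a", "b", "ABSTAIN")))
  tab2["a", "a"] <- 8; tab2["a", "b"] <- 1; tab2["a", "ABSTAIN"] <- 1
  expect_equal(efficiency(tab2), 0.7, tolerance = 1e-12)

  # boundary: p_c == p_e is ND; just above is defined
  tab3 <- tab2; tab3["a", "b"] <- 8
  expect_true(is.na(efficiency(tab3)))
})

test_that("efficiency is ND exactly when p_c <= p_e across random tables", {
  set.seed(64)
  for (rep in 1:50) {
    counts <- matrix(rpois(6, 3), 2, 3,
                     dimnames = list(c("a", "b"), c("a", "b", "ABSTAIN")))
    if (sum(counts) == 0) next
    p_c <- sum(diag(counts[, 1:2])) / sum(counts)
    p_e <- (sum(counts[, 1:2]) - sum(diag(counts[, 1:2]))) / sum(counts)
    expect_identical(is.na(efficiency(counts)), p_c <= p_e)
  }
})

test_that("percentage improvement matches hand arithmetic on the benchmark", {
  base_d <- c(0.4619, 0.4837, 0.2358, 0.2774, 0.5145, 0.4143)
  expect_equal(percentage_improvement(0.5789, mean(base_d)), 45.5, tolerance = 0.01)
  expect_equal(percentage_improvement(0.42, 0.42), 0)
  expect_equal(percentage_improvement(0.3798, 0.4559), -16.7, tolerance = 0.01)
  expect_error(percentage_improvement(1, 0), "nonzero")
})

test_that("benchmark table reproduces its published improvement ranges", {
  bench <- speller_benchmark()
  # ND entries are skipped in the averages (subject B efficiency)
  imp <- fusion_improvement(bench)
  b_eff <- imp$vs_average[imp$subject == "B" & imp$metric == "efficiency"]
  expect_equal(b_eff, percentage_improvement(0.5121, mean(c(0.5320, 0.3283, 0.2019, 0.3874))),
               tolerance = 1e-9)
  ranges <- improvement_ranges(bench)
  get <- function(m, r, what) ranges[[what]][ranges$metric == m & ranges$reference == r]
  expect_gte(get("efficiency", "average", "min"), 14)
  expect_gte(get("efficiency", "average", "max"), 45)
  expect_gte(get("itr", "average", "min"), 6)
  expect_gte(get("itr", "average", "max"), 22)
  expect_lte(get("efficiency", "best", "min"), -16)
  expect_gte(get("efficiency", "best", "max"), 12)
})
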