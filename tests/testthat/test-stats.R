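test_that("Fisher exact matches hand-derived and enumerated values", {
  expect_equal(fisher_exact_2x2(5, 95, 5, 95)$p_value, 1.0)
  # Hypergeom(N=6, K=3, n=3): P(0) + P(3) = 2/20
  expect_equal(fisher_exact_2x2(3, 0, 0, 3)$p_value, 0.1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), class = "cogdepth_validation_error")

  set.seed(101)
  for (i in 1:300) {
    a <- rpois(1, 8); b <- rpois(1, 40); c <- rpois(1, 8); d <- rpois(1, 40)
    if (a + b + c + d == 0) next
    p <- fisher_exact_2x2(a, b, c, d)$p_value
    expect_equal(p, oracle_fisher_p(a, b, c, d), tolerance = 1e-7)
  }
})

test_that("Fisher exact agrees with stats::fisher.test two-sided p", {
  set.seed(7)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 12), 2)
    if (any(rowSums(tab) + colSums(tab) == 0)) next
    ours <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$p_value
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("conditional binomial test matches closed forms and enumeration", {
  # symmetric q = 1/2: two-sided p of a 0/10 split is 2 * (1/2)^10
  expect_equal(binomial_exact_counts(0, 10, 100, 100)$p_value, 0.001953125)
  expect_equal(binomial_exact_counts(5, 5, 100, 100)$p_value, 1.0)
  expect_match(binomial_exact_counts(0, 0, 10, 10)$method, "no information")
  expect_equal(binomial_exact_counts(0, 0, 10, 10)$p_value, 1.0)

  set.seed(11)
  for (i in 1:300) {
    n1 <- sample(50:200, 1); n2 <- sample(50:200, 1)
    x1 <- sample(0:30, 1); x2 <- sample(0:30, 1)
    p <- binomial_exact_counts(x1, x2, n1, n2)$p_value
    expect_equal(p, oracle_binom_p(x1, x1 + x2, n1 / (n1 + n2)),
                 tolerance = 1e-7)
  }
})

test_that("Welch t reproduces hand evaluation and antisymmetry", {
  r <- welch_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(r$statistic, -2.19089023, tolerance = 1e-6)
  expect_equal(r$df, 6.0)
  expect_equal(r$p_value, 0.07098765, tolerance = 1e-6)

  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(welch_t(c(2, 2), c(5, 5)), class = "cogdepth_degenerate_error")

  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), 0.5)
    ours <- welch_t(x, y)
    swapped <- welch_t(y, x)
    expect_equal(ours$statistic, -swapped$statistic)
    expect_equal(ours$p_value, swapped$p_value)
    ref <- stats::t.test(x, y)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact rank-sum enumeration handles small samples and ties", {
  expect_equal(ranksum_exact(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(ranksum_exact(c(1, 2), c(1, 2))$p_value, 1.0)
  expect_error(ranksum_exact(numeric(), 1), class = "cogdepth_validation_error")

  # tie-free cases agree with the exact Wilcoxon distribution
  set.seed(5)
  for (i in 1:30) {
    x <- rnorm(4); y <- rnorm(5)
    ours <- ranksum_exact(x, y)$p_value
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }

  # with ties: independent subset enumeration with positional midranks
  set.seed(6)
  for (i in 1:20) {
    x <- sample(1:4, 3, TRUE); y <- sample(1:4, 6, TRUE)
    expect_equal(ranksum_exact(x, y)$p_value, oracle_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum falls back to a flagged normal approximation", {
  set.seed(8)
  x <- rnorm(30); y <- rnorm(40)
  r <- ranksum_exact(x, y, exact_limit = 1e4)
  expect_match(r$method, "normal approximation")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(r$p_value, ref, tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up rule and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.1, 1.2)), class = "cogdepth_validation_error")

  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, stats::p.adjust(p, "BH"))
    # step-up output is monotone in the input order
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  # NA pass-through keeps order and excludes NAs from m
  p <- c(0.02, NA, 0.04)
  expect_equal(bh_fdr(p), c(0.04, NA, 0.04))
})

test_that("the exact count tests are conservative under the null", {
  set.seed(12)
  n <- 500
  reject <- logical(2000)
  for (i in seq_len(2000)) {
    x <- rbinom(2, n, 0.03)
    reject[i] <- fisher_exact_2x2(x[1], n - x[1], x[2], n - x[2])$p_value <= 0.05
  }
  expect_lte(mean(reject), 0.06)
})
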