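test_that("Fisher's exact test agrees with direct hypergeometric enumeration", {
  tabs <- list(matrix(c(5, 0, 0, 5), 2), matrix(c(1, 1, 1, 1), 2),
               matrix(c(89, 5, 148, 26), 2), matrix(c(3, 45, 3, 47), 2))
  for (tab in tabs) {
    expect_equal(fisher_exact_two_sided(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-7)
  }
  # frozen enumeration values
  expect_equal(fisher_exact_two_sided(matrix(c(5, 0, 0, 5), 2))$p_value,
               2 / choose(10, 5), tolerance = 1e-9)   # 0.00793...
  expect_equal(fisher_exact_two_sided(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
})

test_that("Fisher p is invariant under row/column swaps and transposition", {
  set.seed(41)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_two_sided(tab)$p_value
    expect_equal(fisher_exact_two_sided(tab[2:1, ])$p_value, p)
    expect_equal(fisher_exact_two_sided(tab[, 2:1])$p_value, p)
    expect_equal(fisher_exact_two_sided(t(tab))$p_value, p)
  }
})

test_that("a zero margin returns p = 1 with a warning", {
  expect_warning(r <- fisher_exact_two_sided(matrix(c(0, 0, 5, 5), 2)),
                 "zero margin")
  expect_equal(r$p_value, 1)
  expect_error(fisher_exact_two_sided(matrix(0, 2, 2)), "empty")
})

test_that("Mann-Whitney U is exact for small tie-free samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)          # 2/20 rank splits as extreme
  expect_equal(oracle_mwu_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical samples: no separation
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1,
               tolerance = 0.05)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("Mann-Whitney exact path matches the enumeration oracle", {
  set.seed(42)
  for (i in 1:15) {
    x <- stats::rnorm(sample(3:6, 1))
    y <- stats::rnorm(sample(3:6, 1), mean = stats::runif(1, -1, 1))
    expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
                 oracle_mwu_p(x, y), tolerance = 1e-9)
  }
})

test_that("normal approximation tracks the exact p within 0.02", {
  # at n = 4 per group the continuity-corrected approximation can deviate by
  # up to ~0.031 from the enumerated p, so the guard runs at 5-8 per group
  set.seed(43)
  for (i in 1:30) {
    x <- stats::rnorm(sample(5:8, 1))
    y <- stats::rnorm(sample(5:8, 1), mean = stats::runif(1, -1.5, 1.5))
    p_ex <- mann_whitney_u(x, y, mode = "exact")$p_value
    p_no <- mann_whitney_u(x, y, mode = "normal")$p_value
    expect_lt(abs(p_ex - p_no), 0.02)
  }
})

test_that("a 1-SD shift at n=500 per group is decisively detected", {
  set.seed(44)
  x <- stats::rnorm(500)
  y <- stats::rnorm(500, mean = 1)
  expect_lt(mann_whitney_u(x, y)$p_value, 1e-4)
  # cross-check with a permutation oracle: no permutation as extreme
  pooled <- c(x, y)
  u_obs <- mann_whitney_u(x, y)$statistic
  mu <- 500 * 500 / 2
  extreme <- replicate(500, {
    idx <- sample(1000, 500)
    u <- sum(rank(pooled)[idx]) - 500 * 501 / 2
    abs(u - mu) >= abs(u_obs - mu)
  })
  expect_equal(sum(extreme), 0)
})

test_that("Wilcoxon signed-rank is exact for small tie-free pairs", {
  r <- wilcoxon_signed_rank(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$p_value, 0.25)         # 2/8 sign assignments as extreme
  expect_equal(oracle_signed_rank_p(c(1, 2, 3)), 0.25)
  # perfectly balanced differences
  expect_equal(wilcoxon_signed_rank(c(0, 0), c(1, -1))$p_value, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("Wilcoxon drops zero differences and detects a paired shift", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4), c(1, 4, 6, 8))
  expect_equal(r$n1, 3)   # one zero difference dropped
  expect_equal(r$n2, 1)
  set.seed(45)
  normal <- stats::rlnorm(83, log(40), 0.6)
  tumor <- normal * stats::rlnorm(83, log(5), 0.4)
  expect_lt(wilcoxon_signed_rank(normal, tumor)$p_value, 1e-4)
})

test_that("t-test defaults to Welch and handles degenerate input", {
  expect_equal(unpaired_t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(unpaired_t_test(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  r <- unpaired_t_test(c(10, 11, 12), c(20, 21, 22))
  expect_lt(r$p_value, 0.01)
  # Welch closed form: t = (mean diff) / sqrt(s1^2/n1 + s2^2/n2)
  expect_equal(r$statistic, -10 / sqrt(2 / 3), tolerance = 1e-9)
  # constant equal groups: convention t = 0, p = 1
  d <- unpaired_t_test(c(5, 5), c(5, 5))
  expect_equal(d$p_value, 1)
  expect_error(unpaired_t_test(c(5, 5), c(7, 7)), "degenerate")
})

test_that("amplified fraction uses a strict more-than-four rule", {
  expect_equal(amplified_fraction(c(2, 2, 4, 5, 6)), 40)
  expect_equal(amplified_fraction(c(4, 4, 4)), 0)
  expect_equal(amplified_fraction(5), 100)
  expect_error(amplified_fraction(integer(0)), "no cells")
})

test_that("chromosome-count summaries and pairwise comparisons", {
  s <- list(a = c(98L, 100L, 102L), b = c(98L, 100L, 102L),
            c = c(120L, 125L, 130L))
  out <- summarize_chromosome_counts(s, comparisons = list(c("a", "b"),
                                                           c("a", "c")))
  expect_equal(out$summary$median[out$summary$condition == "a"], 100)
  p_ab <- out$comparisons$p_value[out$comparisons$a == "a" &
                                    out$comparisons$b == "b"]
  expect_gt(p_ab, 0.9)   # identical conditions: NS
  expect_error(summarize_chromosome_counts(s, comparisons = list(c("a", "zz"))),
               "zz")
})
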