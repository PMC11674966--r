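test_that("two-thirds rule boundary is inclusive and pools deep/shallow calls", {
  # exactly 8/12 deleted genes: on the boundary, called deletion
  expect_identical(call_arm_status(c(rep(-1L, 8), rep(0L, 4))), "deletion")
  # 6/10 gained: below two-thirds, diploid
  expect_identical(call_arm_status(c(rep(1L, 6), rep(0L, 4))), "diploid")
  # -2 and -1 pool into the deletion numerator
  expect_identical(call_arm_status(c(rep(-2L, 5), rep(-1L, 3), rep(0L, 4))),
                   "deletion")
  # just under the boundary (7/12): diploid
  expect_identical(call_arm_status(c(rep(-1L, 7), rep(0L, 5))), "diploid")
  # zero informative genes
  expect_identical(call_arm_status(c(NA_integer_, NA_integer_)), "no_call")
  expect_identical(call_arm_status(integer(0)), "no_call")
})

test_that("invalid call values are rejected by name", {
  expect_error(call_arm_status(c(0L, 3L)), "3")
  expect_error(call_arm_status(c(-5L, 0L)), "-5")
})

test_that("deletion and gain are mutually exclusive at majority thresholds", {
  set.seed(11)
  for (i in 1:200) {
    calls <- sample(c(-2L, -1L, 0L, 1L, 2L), sample(1:20, 1), replace = TRUE)
    n <- length(calls)
    k_del <- sum(calls < 0); k_amp <- sum(calls > 0)
    both <- (3 * k_del >= 2 * n) && (3 * k_amp >= 2 * n)
    expect_false(both)
    expect_no_warning(call_arm_status(calls))
  }
  # at threshold <= 1/2 a tie is diploid with a warning
  expect_warning(s <- call_arm_status(c(-1L, 1L), threshold = c(1L, 2L)),
                 "diploid")
  expect_identical(s, "diploid")
})

test_that("raising the threshold never creates an alteration call", {
  set.seed(12)
  rank_alt <- function(s) s %in% c("deletion", "amp_gain")
  for (i in 1:100) {
    calls <- sample(c(-2L, -1L, 0L, 1L, 2L), sample(1:15, 1), replace = TRUE)
    lo <- call_arm_status(calls, threshold = c(2L, 3L))
    hi <- call_arm_status(calls, threshold = c(3L, 4L))
    expect_false(!rank_alt(lo) && rank_alt(hi))
  }
})

toy_table <- function() {
  calls <- rbind(a1 = c(-1L, 0L), a2 = c(-1L, 0L), a3 = c(-1L, NA),
                 b1 = c(0L, 1L), b2 = c(0L, 1L), b3 = c(0L, 1L))
  colnames(calls) <- c("case1", "case2")
  map <- build_arm_map(data.frame(gene_id = rownames(calls),
                                  arm = rep(c("1p", "1q"), each = 3)),
                       universe = c("1p", "1q"))
  list(calls = calls, map = map)
}

test_that("call_all_arms aggregates per arm and case", {
  t <- toy_table()
  st <- call_all_arms(t$calls, t$map)
  expect_identical(st$status["1p", "case1"], "deletion")
  expect_identical(st$status["1q", "case1"], "diploid")
  expect_identical(st$status["1p", "case2"], "diploid")
  expect_identical(st$status["1q", "case2"], "amp_gain")
  expect_identical(st$informative["1p", "case2"], 2L)
})

test_that("gene row order does not affect the status table", {
  t <- toy_table()
  st1 <- call_all_arms(t$calls, t$map)
  st2 <- call_all_arms(t$calls[sample(nrow(t$calls)), ], t$map)
  expect_identical(st1$status, st2$status)
  expect_identical(st1$informative, st2$informative)
})

test_that("an all-missing case is no_call on every arm and excluded", {
  t <- toy_table()
  calls <- cbind(t$calls, case3 = NA_integer_)
  st <- call_all_arms(calls, t$map)
  expect_true(all(st$status[, "case3"] == "no_call"))
  b <- burden_per_case(st)
  expect_true(b$excluded[b$case_id == "case3"])
  expect_false(any(b$excluded[b$case_id != "case3"]))
})

test_that("burden counts altered and evaluable arms; no_call joins neither", {
  st <- structure(list(
    status = matrix(c("deletion", "diploid", "amp_gain", "diploid",
                      "no_call", "diploid", "diploid", "diploid"),
                    4, 2, dimnames = list(c("1p", "1q", "2p", "2q"),
                                          c("c1", "c2"))),
    informative = matrix(1L, 4, 2), universe = c("1p", "1q", "2p", "2q"),
    threshold = c(2L, 3L)), class = "arm_status_table")
  b <- burden_per_case(st)
  expect_equal(b$altered_arms, c(2L, 0L))
  expect_equal(b$evaluable_arms, c(4L, 3L))
})

test_that("median split is inclusive at the median", {
  b <- data.frame(case_id = letters[1:4], altered_arms = c(0L, 2L, 5L, 7L),
                  evaluable_arms = 10L, excluded = FALSE,
                  label = NA_character_)
  cls <- classify_cna(b)
  expect_equal(cls$median_cutoff, 3.5)
  expect_identical(cls$burdens$label,
                   c("CNA_low", "CNA_low", "CNA_high", "CNA_high"))
  # all counts equal: "equal to or above" puts everyone in CNA-high
  b2 <- data.frame(case_id = letters[1:3], altered_arms = 3L,
                   evaluable_arms = 10L, excluded = FALSE,
                   label = NA_character_)
  expect_true(all(classify_cna(b2)$burdens$label == "CNA_high"))
})

test_that("excluded cases keep their label and all-excluded errors", {
  b <- data.frame(case_id = letters[1:3], altered_arms = c(1L, 4L, 9L),
                  evaluable_arms = 10L, excluded = c(FALSE, TRUE, FALSE),
                  label = NA_character_)
  cls <- classify_cna(b)
  expect_identical(cls$burdens$label, c("CNA_low", "excluded", "CNA_high"))
  expect_equal(cls$median_cutoff, 5)  # median of 1 and 9
  b$excluded <- TRUE
  expect_error(classify_cna(b), "non-excluded")
})

test_that("burden recount matches the brute-force oracle on random cohorts", {
  set.seed(21)
  for (i in 1:40) {
    rc <- random_small_cohort()
    st <- call_all_arms(rc$calls, rc$map)
    b <- burden_per_case(st, completeness_rule(max_nocall_frac = 1))
    expected <- oracle_burden(rc$calls, rc$gene_arm, rc$universe)
    expect_equal(b$altered_arms, unname(expected[, "altered"]))
    expect_equal(b$evaluable_arms, unname(expected[, "evaluable"]))
  }
})
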