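#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p by hypergeometric enumeration with the point-probability
#' rule (the sum of probabilities, at fixed margins, of all tables no more
#' probable than the observed one) — the convention of mainstream statistical
#' software. A table with a zero margin carries no information; by convention
#' it returns p = 1 with a warning.
#'
#' @param tab 2x2 matrix (or object coercible to one) of non-negative counts;
#'   rows = factor levels, columns = low/high groups.
#' @return a `test_result` list: `method`, `statistic` (odds-ratio estimate),
#'   `p_value`, `n1`, `n2` (column totals).
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  if (sum(tab) == 0) stop("empty table")
  res <- list(method = "Fisher's exact test (two-sided)",
              n1 = sum(tab[, 1]), n2 = sum(tab[, 2]))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in 2x2 table; p = 1 by convention")
    res$statistic <- NA_real_
    res$p_value <- 1
  } else {
    ft <- stats::fisher.test(tab)
    res$statistic <- unname(ft$estimate)
    res$p_value <- ft$p.value
  }
  class(res) <- "test_result"
  res
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic) && !is.na(x$statistic)) {
    cat("  statistic:", format(x$statistic), "\n")
  }
  cat("  p-value:", format_p(x$p_value), "\n")
  invisible(x)
}

# table-style p formatting: 4 decimals, trailing zeros kept
format_p <- function(p) formatC(p, format = "f", digits = 4)

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration when both samples are small (min(n1, n2) <= 8) and
#' tie-free, otherwise the normal approximation with tie and continuity
#' correction. `mode` forces either path.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"` (default), `"exact"`, or `"normal"`.
#' @return `test_result` with the U statistic (for `x`), `p_value`, group
#'   sizes.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = min(length(x), length(y)) <= 8 && !ties,
                  exact = TRUE,
                  normal = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  structure(list(method = paste0("Mann-Whitney U (",
                                 if (exact) "exact" else "normal approx", ")"),
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 n1 = length(x), n2 = length(y)),
            class = "test_result")
}

#' Wilcoxon signed-rank test on paired values (two-sided)
#'
#' Zero differences are dropped (the standard signed-rank convention);
#' exact enumeration when at most 12 informative pairs remain and the
#' absolute differences are tie-free, otherwise the normal approximation
#' with tie and continuity correction.
#'
#' @param before,after paired numeric vectors of equal length.
#' @return `test_result` with the V statistic, `p_value`, `n1` = informative
#'   pairs, `n2` = dropped zero-difference pairs.
#' @export
wilcoxon_signed_rank <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 1)
  d <- after - before
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) stop("all paired differences are zero")
  exact <- length(nz) <= 12 && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    stats::wilcox.test(nz, exact = exact, correct = TRUE)
  )
  structure(list(method = paste0("Wilcoxon signed-rank (",
                                 if (exact) "exact" else "normal approx", ")"),
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 n1 = length(nz), n2 = length(d) - length(nz)),
            class = "test_result")
}

#' Unpaired two-sample t-test (two-sided)
#'
#' Welch's unequal-variance t-test by default; set `pooled = TRUE` for the
#' classical equal-variance variant. Degenerate input (zero variance in both
#' groups with equal means) returns t = 0, p = 1 by convention.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @return `test_result` with t statistic, `p_value`, group sizes.
#' @export
unpaired_t_test <- function(x, y, pooled = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  method <- if (pooled) "t-test (pooled variance)" else "t-test (Welch)"
  res <- tryCatch(stats::t.test(x, y, var.equal = pooled),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(structure(list(method = method, statistic = 0, p_value = 1,
                            n1 = length(x), n2 = length(y)),
                       class = "test_result"))
    }
    stop("degenerate t-test input: zero variance with unequal means")
  }
  structure(list(method = method, statistic = unname(res$statistic),
                 p_value = res$p.value, n1 = length(x), n2 = length(y)),
            class = "test_result")
}

#' Fraction of cells with centrosome amplification
#'
#' The percentage of cells with strictly more than four centrioles (centrin
#' foci); a cell with exactly four is normal.
#'
#' @param counts non-negative integer vector of per-cell focus counts.
#' @return percentage in \[0, 100\].
#' @export
amplified_fraction <- function(counts) {
  if (length(counts) == 0) stop("no cells")
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  100 * sum(counts > 4) / length(counts)
}

#' Summaries and pairwise comparisons of per-metaphase chromosome counts
#'
#' @param samples named list of positive integer vectors, one per condition
#'   (e.g. clone x cumate treatment).
#' @param comparisons optional 2-column character matrix (or list of length-2
#'   vectors) of condition pairs to compare by Mann-Whitney U.
#' @return list with `summary` (data.frame: condition, n, median, q1, q3)
#'   and `comparisons` (data.frame: a, b, U, p_value), or NULL when no pairs
#'   requested.
#' @export
summarize_chromosome_counts <- function(samples, comparisons = NULL) {
  stopifnot(is.list(samples), length(samples) >= 2,
            !is.null(names(samples)))
  for (s in samples) stopifnot(all(s >= 1), all(s == round(s)))
  qs <- t(vapply(samples,
                 function(s) stats::quantile(s, c(0.25, 0.5, 0.75),
                                             names = FALSE),
                 numeric(3)))
  summary <- data.frame(condition = names(samples),
                        n = vapply(samples, length, integer(1)),
                        median = qs[, 2], q1 = qs[, 1], q3 = qs[, 3],
                        row.names = NULL, stringsAsFactors = FALSE)
  comp_df <- NULL
  if (!is.null(comparisons)) {
    if (is.matrix(comparisons)) {
      comparisons <- lapply(seq_len(nrow(comparisons)),
                            function(i) comparisons[i, ])
    }
    comp_df <- do.call(rbind, lapply(comparisons, function(pr) {
      if (!all(pr %in% names(samples))) {
        stop("unknown condition(s) in comparison: ",
             paste(setdiff(pr, names(samples)), collapse = ", "))
      }
      r <- mann_whitney_u(samples[[pr[1]]], samples[[pr[2]]])
      data.frame(a = pr[1], b = pr[2], U = r$statistic, p_value = r$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = summary, comparisons = comp_df)
}
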