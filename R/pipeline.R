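#' Run the arm-level CNA burden / expression association analysis
#'
#' End-to-end: aggregate gene-level calls to arm status, count each case's
#' altered arms, exclude incomplete cases, median-split the cohort into
#' CNA-high and CNA-low, then compare the designated gene's expression
#' between the two groups by a two-sided Mann-Whitney U test.
#'
#' @param copy_matrix integer gene x case matrix of GISTIC-style calls
#'   (or a path readable by [load_copy_matrix()]).
#' @param expression numeric gene x case matrix (or a path for
#'   [load_expression()]); must contain `gene` in its rows and every
#'   copy-number case in its columns.
#' @param map an [build_arm_map()] result.
#' @param gene designated gene symbol whose expression is compared
#'   (default `"STIL"`).
#' @param threshold arm-status majority threshold, default `c(2L, 3L)`.
#' @param completeness a [completeness_rule()].
#' @return `cna_report` list: `burdens` (labeled per-case table),
#'   `median_cutoff`, `n_high`, `n_low`, `n_excluded`, `test`
#'   (Mann-Whitney `test_result`), `group_medians` (named: expression
#'   medians in CNA_high / CNA_low), `config` echo.
#' @export
run_cna_association <- function(copy_matrix, expression, map,
                                gene = "STIL", threshold = c(2L, 3L),
                                completeness = completeness_rule()) {
  if (is.character(copy_matrix)) copy_matrix <- load_copy_matrix(copy_matrix)
  if (is.character(expression)) expression <- load_expression(expression)
  if (!gene %in% rownames(expression)) {
    stop("designated gene '", gene, "' not found in the expression matrix")
  }
  orphans <- setdiff(colnames(copy_matrix), colnames(expression))
  if (length(orphans) > 0 && !completeness$require_expression) {
    stop("case id(s) in copy-number but not expression data: ",
         paste(utils::head(orphans, 5), collapse = ", "),
         if (length(orphans) > 5) ", ...")
  }

  table <- call_all_arms(copy_matrix, map, threshold = threshold)
  has_expr <- stats::setNames(colnames(copy_matrix) %in% colnames(expression),
                              colnames(copy_matrix))
  burdens <- burden_per_case(table, completeness = completeness,
                             has_expression = if (completeness$require_expression)
                               has_expr else NULL)
  cls <- classify_cna(burdens)
  burdens <- cls$burdens

  expr <- expression[gene, ]
  hi <- expr[burdens$case_id[burdens$label == "CNA_high"]]
  lo <- expr[burdens$case_id[burdens$label == "CNA_low"]]
  hi <- hi[!is.na(hi)]; lo <- lo[!is.na(lo)]
  test <- if (length(hi) > 0 && length(lo) > 0) {
    mann_whitney_u(hi, lo)
  } else NULL

  structure(list(
    burdens = burdens,
    median_cutoff = cls$median_cutoff,
    n_high = sum(burdens$label == "CNA_high"),
    n_low = sum(burdens$label == "CNA_low"),
    n_excluded = sum(burdens$label == "excluded"),
    test = test,
    group_medians = c(CNA_high = stats::median(hi),
                      CNA_low = stats::median(lo)),
    config = list(gene = gene, threshold = as.integer(threshold),
                  completeness = unclass(completeness),
                  arm_universe = map$universe)),
    class = "cna_report")
}

#' @export
print.cna_report <- function(x, ...) {
  cat(sprintf("CNA burden report: %d CNA-high, %d CNA-low, %d excluded\n",
              x$n_high, x$n_low, x$n_excluded))
  cat(sprintf("  median altered-arm cutoff: %g\n", x$median_cutoff))
  if (!is.null(x$test)) {
    cat(sprintf("  %s expression, CNA-high vs CNA-low median: %.1f vs %.1f, p = %s\n",
                x$config$gene, x$group_medians["CNA_high"],
                x$group_medians["CNA_low"], format_p(x$test$p_value)))
  }
  invisible(x)
}

#' Per-factor Fisher's exact tests on a clinicopathological table
#'
#' Takes a long-format table (one row per factor level, counts in the low
#' and high expression groups) and runs a two-sided Fisher's exact test per
#' two-level factor, emitting counts, row percentages, and the p-value.
#' Factors with fewer or more than two observed levels are skipped with a
#' warning.
#'
#' @param clin data.frame with columns `factor`, `level`, `n_low`, `n_high`
#'   (see [load_clinical_tables()]).
#' @return data.frame: one row per factor level, with `n_cases`, `pct_low`,
#'   `pct_high` and the factor's `p_value` (repeated over its levels).
#' @export
run_clinicopath <- function(clin) {
  stopifnot(is.data.frame(clin),
            all(c("factor", "level", "n_low", "n_high") %in% names(clin)))
  if (nrow(clin) == 0) stop("empty clinical table")
  out <- lapply(unique(clin$factor), function(f) {
    rows <- clin[clin$factor == f, , drop = FALSE]
    rows$n_cases <- rows$n_low + rows$n_high
    rows$pct_low <- 100 * rows$n_low / rows$n_cases
    rows$pct_high <- 100 * rows$n_high / rows$n_cases
    if (nrow(rows) != 2) {
      warning("factor '", f, "' has ", nrow(rows),
              " level(s); Fisher test skipped")
      rows$p_value <- NA_real_
      return(rows)
    }
    rows$p_value <- fisher_exact_two_sided(
      as.matrix(rows[, c("n_low", "n_high")]))$p_value
    rows
  })
  do.call(rbind, out)
}

#' Cross-tabulate per-case clinical factors against a low/high label
#'
#' Convenience bridge from a per-case clinical table (as produced by
#' [generate_clinical()]) to the long count format [run_clinicopath()]
#' consumes.
#'
#' @param clinical per-case data.frame with a `label` column
#'   (`"low"`/`"high"`) and factor columns.
#' @param factors which columns to tabulate.
#' @return long data.frame: factor, level, n_low, n_high.
#' @export
tabulate_clinical <- function(clinical,
                              factors = c("age", "sex", "smoking",
                                          "pT", "pN", "stage")) {
  stopifnot("label" %in% names(clinical))
  do.call(rbind, lapply(factors, function(f) {
    tab <- table(clinical[[f]], factor(clinical$label, c("low", "high")))
    data.frame(factor = f, level = rownames(tab),
               n_low = as.integer(tab[, "low"]),
               n_high = as.integer(tab[, "high"]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
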