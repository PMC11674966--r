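#' Call the copy-number status of one arm in one case
#'
#' Applies the inclusive two-thirds majority rule to the gene-level GISTIC
#' calls on an arm. With n informative (non-missing) genes, the arm is a
#' `"deletion"` when the genes called -2 or -1 make up two-thirds or more of
#' n, otherwise `"amp_gain"` when the genes called +1 or +2 do, otherwise
#' `"diploid"`. An arm with no informative gene is `"no_call"`.
#'
#' The boundary is inclusive and evaluated in exact integer arithmetic
#' (`den * k >= num * n`), so an arm with exactly 8 of 12 genes deleted is a
#' deletion. Deletion is evaluated before amplification/gain; for any
#' majority threshold (> 1/2) the two criteria are mutually exclusive, and
#' for permissive thresholds <= 1/2 a tie yields `"diploid"` with a warning.
#'
#' @param calls integer vector of gene-level calls in \{-2,-1,0,1,2\};
#'   `NA` cells are dropped before evaluation.
#' @param threshold length-2 integer vector `c(numerator, denominator)` of
#'   the majority fraction; default `c(2L, 3L)`.
#' @return single string: `"deletion"`, `"amp_gain"`, `"diploid"` or
#'   `"no_call"`.
#' @export
call_arm_status <- function(calls, threshold = c(2L, 3L)) {
  stopifnot(length(threshold) == 2, threshold[1] > 0,
            threshold[1] <= threshold[2])
  calls <- calls[!is.na(calls)]
  bad <- setdiff(unique(calls), c(-2L, -1L, 0L, 1L, 2L))
  if (length(bad) > 0) {
    stop("invalid copy-number call value(s): ", paste(bad, collapse = ", "))
  }
  n <- length(calls)
  if (n == 0) return("no_call")
  num <- as.numeric(threshold[1]); den <- as.numeric(threshold[2])
  k_del <- sum(calls <= -1L)
  k_amp <- sum(calls >= 1L)
  del <- den * k_del >= num * n
  amp <- den * k_amp >= num * n
  if (del && amp) {
    warning("deletion and amplification criteria both met at threshold <= 1/2; ",
            "returning diploid")
    return("diploid")
  }
  if (del) "deletion" else if (amp) "amp_gain" else "diploid"
}

#' Arm-level status for every (arm, case) pair
#'
#' Aggregates a gene-by-sample call matrix to an arm-by-sample status table
#' using [call_arm_status()] per cell. Genes of the matrix not present in the
#' arm map are ignored; arms of the universe with no gene in the matrix are
#' `"no_call"` everywhere.
#'
#' @param matrix_calls integer matrix, genes in rows (rownames = gene ids),
#'   cases in columns (colnames = case ids), cells in \{-2..2\} or `NA`.
#' @param map an [build_arm_map()] result.
#' @param threshold majority threshold passed to [call_arm_status()].
#' @return object of class `arm_status_table`: list with `status`
#'   (character arm x case matrix), `informative` (integer matrix of
#'   informative gene counts), `universe`, `threshold`.
#' @export
call_all_arms <- function(matrix_calls, map, threshold = c(2L, 3L)) {
  stopifnot(is.matrix(matrix_calls), inherits(map, "arm_map"))
  if (is.null(rownames(matrix_calls)) || is.null(colnames(matrix_calls))) {
    stop("call matrix needs gene rownames and case colnames")
  }
  if (anyDuplicated(rownames(matrix_calls))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(matrix_calls))) stop("duplicate case ids")
  bad <- setdiff(unique(as.vector(matrix_calls)), c(-2L, -1L, 0L, 1L, 2L, NA))
  if (length(bad) > 0) {
    stop("invalid copy-number call value(s): ", paste(bad, collapse = ", "))
  }
  mapped <- intersect(map$genes$gene_id, rownames(matrix_calls))
  if (length(mapped) == 0) stop("no gene of the call matrix is mapped to an arm")

  arms <- map$universe
  cases <- colnames(matrix_calls)
  num <- as.numeric(threshold[1]); den <- as.numeric(threshold[2])

  status <- matrix("no_call", length(arms), length(cases),
                   dimnames = list(arms, cases))
  informative <- matrix(0L, length(arms), length(cases),
                        dimnames = list(arms, cases))
  for (a in arms) {
    g <- intersect(genes_on_arm(map, a), mapped)
    if (length(g) == 0) next
    sub <- matrix_calls[g, , drop = FALSE]
    n <- colSums(!is.na(sub))
    k_del <- colSums(sub <= -1L, na.rm = TRUE)
    k_amp <- colSums(sub >= 1L, na.rm = TRUE)
    del <- den * k_del >= num * n
    amp <- den * k_amp >= num * n
    if (any(del & amp & n > 0)) {  # only reachable at threshold <= 1/2
      warning("deletion and amplification criteria both met at threshold <= 1/2; ",
              "returning diploid")
      keep <- !(del & amp)
      del <- del & keep; amp <- amp & keep
    }
    s <- rep("diploid", length(cases))
    s[amp] <- "amp_gain"
    s[del] <- "deletion"
    s[n == 0] <- "no_call"
    status[a, ] <- s
    informative[a, ] <- as.integer(n)
  }
  structure(list(status = status, informative = informative,
                 universe = arms, threshold = as.integer(threshold)),
            class = "arm_status_table")
}

#' @export
print.arm_status_table <- function(x, ...) {
  cat(sprintf("arm_status_table: %d arms x %d cases\n",
              nrow(x$status), ncol(x$status)))
  print(table(factor(x$status,
                     c("deletion", "amp_gain", "diploid", "no_call"))))
  invisible(x)
}

#' Completeness rule for case inclusion
#'
#' A case is excluded from burden classification when more than
#' `max_nocall_frac` of the universe arms are `no_call`, or when
#' `require_expression` is TRUE and the case has no matched expression value.
#'
#' @param max_nocall_frac maximum tolerated fraction of no_call arms
#'   (default 0.5).
#' @param require_expression whether a matched expression value is required.
#' @return a `completeness_rule` list.
#' @export
completeness_rule <- function(max_nocall_frac = 0.5,
                              require_expression = FALSE) {
  stopifnot(max_nocall_frac >= 0, max_nocall_frac <= 1)
  structure(list(max_nocall_frac = max_nocall_frac,
                 require_expression = require_expression),
            class = "completeness_rule")
}

#' Per-case altered-arm burden
#'
#' Counts, per case, the arms called deletion or amplification/gain
#' (`altered_arms`) and the arms with any call (`evaluable_arms`); no_call
#' arms contribute to neither. Cases failing the completeness rule are marked
#' excluded and take no part in the later median split.
#'
#' @param table an [call_all_arms()] result.
#' @param completeness a [completeness_rule()].
#' @param has_expression optional named logical vector (names = case ids);
#'   used only when the rule requires matched expression.
#' @return data.frame with `case_id`, `altered_arms`, `evaluable_arms`,
#'   `excluded` (logical), `label` (all `NA` until [classify_cna()]).
#' @export
burden_per_case <- function(table, completeness = completeness_rule(),
                            has_expression = NULL) {
  stopifnot(inherits(table, "arm_status_table"),
            inherits(completeness, "completeness_rule"))
  st <- table$status
  altered <- colSums(st == "deletion" | st == "amp_gain")
  evaluable <- colSums(st != "no_call")
  n_arms <- nrow(st)
  excluded <- (n_arms - evaluable) / n_arms > completeness$max_nocall_frac
  if (completeness$require_expression) {
    if (is.null(has_expression)) {
      stop("completeness rule requires expression but has_expression is NULL")
    }
    he <- has_expression[colnames(st)]
    he[is.na(he)] <- FALSE
    excluded <- excluded | !he
  }
  data.frame(case_id = colnames(st),
             altered_arms = as.integer(altered),
             evaluable_arms = as.integer(evaluable),
             excluded = unname(excluded),
             label = NA_character_,
             stringsAsFactors = FALSE)
}

#' Median-split CNA-high / CNA-low classification
#'
#' The median altered-arm count is computed over non-excluded cases (even n:
#' mean of the two central values). A case is `CNA_high` when its altered-arm
#' count is greater than or equal to the median, `CNA_low` when below;
#' excluded cases keep the label `excluded`.
#'
#' @param burdens data.frame from [burden_per_case()].
#' @return list with `burdens` (labels filled in) and `median_cutoff`.
#' @export
classify_cna <- function(burdens) {
  stopifnot(is.data.frame(burdens),
            all(c("altered_arms", "excluded") %in% names(burdens)))
  keep <- !burdens$excluded
  if (sum(keep) < 2) stop("fewer than 2 non-excluded cases; cannot median-split")
  med <- stats::median(burdens$altered_arms[keep])
  burdens$label <- ifelse(burdens$excluded, "excluded",
                          ifelse(burdens$altered_arms >= med,
                                 "CNA_high", "CNA_low"))
  list(burdens = burdens, median_cutoff = med)
}
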