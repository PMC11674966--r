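#' Read a cBioPortal-style discrete copy-number matrix
#'
#' TSV with genes in rows: the first column holds gene identifiers and the
#' remaining columns one case each, cells in \{-2,-1,0,1,2\}. Blank cells,
#' `NA` and `NaN` are normalized to missing on read.
#'
#' @param path TSV file path.
#' @return integer matrix, gene rownames, case colnames.
#' @export
load_copy_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA", "NaN"),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("copy-number file ", path, ": needs gene + case columns")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("copy-number file ", path, ": duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("copy-number file ", path, ": duplicate case column(s): ",
         paste(unique(names(df)[-1][duplicated(names(df)[-1])]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))
    stop("copy-number file ", path, ": non-numeric cell(s), e.g. '",
         m[bad[1]], "'")
  }
  bad <- setdiff(unique(as.vector(m)), c(-2, -1, 0, 1, 2, NA))
  if (length(bad) > 0) {
    stop("copy-number file ", path, ": invalid call value(s): ",
         paste(bad, collapse = ", "))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  n_missing <- sum(is.na(m))
  if (n_missing > 0) {
    message(n_missing, " missing call(s) in ", basename(path))
  }
  m
}

#' Write a copy-number matrix as the TSV dialect [load_copy_matrix()] reads
#' @param m integer matrix with dimnames.
#' @param path output path.
#' @export
write_copy_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample expression matrix (RSEM-style TSV)
#' @param path TSV file path; first column gene ids, remaining columns cases.
#' @return numeric matrix.
#' @export
load_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA", "NaN"),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file ", path, ": needs gene + case columns")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("expression file ", path, ": duplicate gene ids")
  if (anyDuplicated(names(df)[-1])) {
    stop("expression file ", path, ": duplicate case columns")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("expression file ", path, ": non-numeric cell(s)")
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-location table
#'
#' Accepts either a TSV with columns `gene_id`, `chromosome`, `cytoband`
#' (arm parsed from the band label) or a BED file (`chrom`, `chromStart`,
#' `chromEnd`, `name`; 0-based half-open converted to 1-based inclusive).
#' BED input carries no centromere information, so the arm must be encoded
#' in the name as `gene|arm` (e.g. `STIL|1p`), or supplied via `cytoband`.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return data.frame with `gene_id`, `arm` (NA when unknown), and
#'   `start`/`end` when positions are available.
#' @export
load_gene_locations <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED file ", path, ": needs chrom/start/end/name")
    name <- strsplit(as.character(df[[4]]), "|", fixed = TRUE)
    data.frame(gene_id = vapply(name, `[`, "", 1),
               arm = vapply(name, function(x) {
                 if (length(x) >= 2) x[2] else NA_character_
               }, ""),
               start = df[[2]] + 1L,  # 0-based half-open -> 1-based inclusive
               end = df[[3]],
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
    if (!"gene_id" %in% names(df)) {
      stop("gene-location file ", path, ": no gene_id column")
    }
    if (!"arm" %in% names(df) && "cytoband" %in% names(df)) {
      df$arm <- parse_cytoband_arm(as.character(df$cytoband))
    }
    df
  }
}

#' Read per-case IHC intensity distributions
#'
#' TSV columns: `case_id`, `tissue` (tumor/normal), `pct0`..`pct3`.
#' Scores are computed on read via [compute_ihc_score()].
#'
#' @param path TSV file path.
#' @param renormalize passed to [compute_ihc_score()].
#' @return data.frame with the input columns plus `score`.
#' @export
load_ihc <- function(path, renormalize = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("case_id", "tissue", "pct0", "pct1", "pct2", "pct3")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("IHC file ", path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$score <- apply(as.matrix(df[, c("pct0", "pct1", "pct2", "pct3")]), 1,
                    compute_ihc_score, renormalize = renormalize)
  df
}

#' Read a clinicopathological contingency table
#'
#' Long TSV: one row per factor level with columns `factor`, `level`,
#' `n_low`, `n_high` (counts in the low/high expression groups). An optional
#' `cohort` column keeps several cohorts in one file.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
load_clinical_tables <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("factor", "level", "n_low", "n_high")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("clinical table ", path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$n_low < 0) || any(df$n_high < 0)) {
    stop("clinical table ", path, ": negative counts")
  }
  df
}

#' Write a per-case burden table as TSV
#' @param burdens data.frame from [classify_cna()]'s `burdens`.
#' @param path output path.
#' @export
write_burden <- function(burdens, path) {
  utils::write.table(burdens, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
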