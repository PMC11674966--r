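#' Chromosome-arm universe
#'
#' Returns the ordered set of chromosome arms over which arm-level burden is
#' counted. The default universe holds the 39 autosomal arms with appreciable
#' gene content (1p..22q, excluding the gene-poor acrocentric short arms 13p,
#' 14p, 15p, 21p and 22p) plus Xp and Xq; chromosome Y is excluded. The full
#' 48-arm set can be requested for sensitivity analyses.
#'
#' @param include_acrocentric_p include 13p, 14p, 15p, 21p, 22p.
#' @param include_x include Xp and Xq (default TRUE).
#' @param include_y include Yp and Yq (default FALSE).
#' @return character vector of arm identifiers (e.g. `"17p"`) in genomic
#'   order: 1p, 1q, 2p, ..., Xq, Yq.
#' @export
arm_universe <- function(include_acrocentric_p = FALSE, include_x = TRUE,
                         include_y = FALSE) {
  chroms <- as.character(1:22)
  if (include_x) chroms <- c(chroms, "X")
  if (include_y) chroms <- c(chroms, "Y")
  arms <- as.vector(t(outer(chroms, c("p", "q"), paste0)))
  if (!include_acrocentric_p) {
    arms <- setdiff(arms, c("13p", "14p", "15p", "21p", "22p"))
  }
  arms
}

# genomic sort order for arbitrary arm labels (1p < 1q < 2p < ... < Xq < Yq)
arm_order <- function(arms) {
  chrom <- sub("[pq]$", "", arms)
  arm <- substring(arms, nchar(arms))
  chrom_rank <- match(chrom, c(as.character(1:22), "X", "Y"))
  order(chrom_rank, arm)
}

#' Parse the arm from a cytoband label
#'
#' `"17p13.1"` maps to `"17p"`; whole-arm labels (`"17p"`) pass through.
#' Labels without a p/q component (unplaced contigs, blanks) return `NA`.
#'
#' @param cytoband character vector of cytoband strings.
#' @return character vector of arm ids or `NA`.
#' @export
parse_cytoband_arm <- function(cytoband) {
  out <- rep(NA_character_, length(cytoband))
  rx <- regexpr("^([1-9]|1[0-9]|2[0-2]|X|Y)[pq]", cytoband)
  ok <- !is.na(cytoband) & rx > 0
  out[ok] <- substr(cytoband[ok], 1, attr(rx, "match.length")[ok])
  out
}

#' Build a gene-to-arm map
#'
#' Maps each gene to exactly one chromosome arm. Duplicated rows agreeing on
#' the arm are deduplicated; a gene listed on two different arms is an error.
#' Genes whose arm is unknown (`NA`) or outside the configured universe are
#' recorded as unmapped rather than dropped silently.
#'
#' @param locations data.frame with columns `gene_id` and either `arm`
#'   (e.g. `"17p"`) or `cytoband` (parsed via [parse_cytoband_arm()]).
#'   Optional `start`/`end` columns (1-based inclusive) give within-arm
#'   ordering.
#' @param universe ordered character vector of arm ids to count over;
#'   default [arm_universe()].
#' @return an object of class `arm_map`: list with `genes` (data.frame
#'   `gene_id`, `arm`, plus position if supplied), `universe`, and
#'   `unmapped` (character vector of gene ids without a usable arm).
#' @export
build_arm_map <- function(locations, universe = arm_universe()) {
  stopifnot(is.data.frame(locations), nrow(locations) > 0,
            "gene_id" %in% names(locations))
  if (length(universe) == 0) stop("empty arm universe")
  if (anyDuplicated(universe)) stop("duplicated arms in universe")

  if (!"arm" %in% names(locations)) {
    if (!"cytoband" %in% names(locations)) {
      stop("locations needs an 'arm' or 'cytoband' column")
    }
    locations$arm <- parse_cytoband_arm(as.character(locations$cytoband))
  }
  locations$gene_id <- as.character(locations$gene_id)
  locations$arm <- as.character(locations$arm)

  # deduplicate identical (gene, arm) rows; conflicting arms are an error
  key <- paste(locations$gene_id, locations$arm, sep = "\r")
  locations <- locations[!duplicated(key), , drop = FALSE]
  dup <- unique(locations$gene_id[duplicated(locations$gene_id)])
  if (length(dup) > 0) {
    conflicting <- dup[vapply(dup, function(g) {
      length(unique(stats::na.omit(locations$arm[locations$gene_id == g]))) > 1
    }, logical(1))]
    if (length(conflicting) > 0) {
      stop("gene(s) mapped to more than one arm: ",
           paste(conflicting, collapse = ", "))
    }
    locations <- locations[!duplicated(locations$gene_id), , drop = FALSE]
  }

  usable <- !is.na(locations$arm) & locations$arm %in% universe
  genes <- locations[usable, , drop = FALSE]

  # deterministic order: genomic position when available, else lexicographic,
  # independent of input row order
  if ("start" %in% names(genes)) {
    o <- order(match(genes$arm, universe), genes$start, genes$gene_id)
  } else {
    o <- order(match(genes$arm, universe), genes$gene_id)
  }
  genes <- genes[o, , drop = FALSE]
  rownames(genes) <- NULL

  structure(list(genes = genes[, intersect(c("gene_id", "arm", "start", "end"),
                                           names(genes)), drop = FALSE],
                 universe = universe,
                 unmapped = sort(locations$gene_id[!usable])),
            class = "arm_map")
}

#' @export
print.arm_map <- function(x, ...) {
  cat(sprintf("arm_map: %d genes on %d arms (%d unmapped)\n",
              nrow(x$genes), length(x$universe), length(x$unmapped)))
  invisible(x)
}

#' Genes on one arm
#'
#' @param map an `arm_map`.
#' @param arm single arm id, must belong to the map's universe.
#' @return character vector of gene ids in the map's stable order.
#' @export
genes_on_arm <- function(map, arm) {
  stopifnot(inherits(map, "arm_map"), length(arm) == 1)
  if (!arm %in% map$universe) {
    stop("arm '", arm, "' is not in the configured arm universe")
  }
  map$genes$gene_id[map$genes$arm == arm]
}
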