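#' Specification for a synthetic tumor cohort
#'
#' Captures, in one validated object, the generating process for a
#' TCGA-shaped cohort: arm-coherent discrete copy-number calls, log-normal
#' expression whose designated gene is coupled to the altered-arm burden,
#' H-score-style IHC distributions, and a clinical table whose advanced-stage
#' factors are linked to high expression by an odds ratio.
#'
#' Defaults mirror the lung adenocarcinoma cohort shape: 515 tumors and 59
#' normals, 3 cases with incomplete copy-number data, a designated gene whose
#' tumor/normal expression medians sit near 221 and 40, IHC medians near 200
#' (tumor) and 50 (normal).
#'
#' @param n_tumor,n_normal cohort sizes.
#' @param universe chromosome-arm universe, default [arm_universe()].
#' @param genes_per_arm genes simulated per arm (scalar).
#' @param p_arm_alter per-arm probability that an arm is altered in a case.
#' @param del_vs_amp probability an altered arm is a deletion (vs gain).
#' @param within_arm_coherence probability a gene on an altered arm carries
#'   the arm's call (others stay 0).
#' @param deep_call_prob probability a carried call is the deep state
#'   (-2 or +2) rather than the shallow one (-1 or +1).
#' @param missing_rate cell-level missing probability in the call matrix.
#' @param n_incomplete_cases tumor cases whose entire call profile is
#'   blanked, so they fail the completeness rule.
#' @param expression_model list: `baseline_log_mean`, `baseline_log_sd`,
#'   `tumor_log_fold`, `burden_coupling_beta` (designated-gene log-expression
#'   increment per altered arm).
#' @param ihc_model list: `normal_median`, `tumor_median`, `log_sd` of the
#'   log-normal score distributions (scores capped at 300).
#' @param clinical_association_or odds ratio linking advanced pT/pN/stage to
#'   the high-expression label.
#' @param designated_gene symbol of the burden-coupled gene (placed on 1p).
#' @param seed integer seed fixing the whole bundle.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_tumor = 515L, n_normal = 59L,
                        universe = arm_universe(),
                        genes_per_arm = 30L,
                        p_arm_alter = 0.35,
                        del_vs_amp = 0.5,
                        within_arm_coherence = 0.95,
                        deep_call_prob = 0.3,
                        missing_rate = 0.02,
                        n_incomplete_cases = 3L,
                        expression_model = list(
                          baseline_log_mean = log(40),
                          baseline_log_sd = 0.8,
                          tumor_log_fold = log(221 / 40),
                          burden_coupling_beta = 0.05),
                        ihc_model = list(normal_median = 50,
                                         tumor_median = 200,
                                         log_sd = 0.5),
                        clinical_association_or = 3,
                        designated_gene = "STIL",
                        seed = 1L) {
  spec <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
               universe = universe, genes_per_arm = as.integer(genes_per_arm),
               p_arm_alter = p_arm_alter, del_vs_amp = del_vs_amp,
               within_arm_coherence = within_arm_coherence,
               deep_call_prob = deep_call_prob, missing_rate = missing_rate,
               n_incomplete_cases = as.integer(n_incomplete_cases),
               expression_model = expression_model, ihc_model = ihc_model,
               clinical_association_or = clinical_association_or,
               designated_gene = designated_gene, seed = as.integer(seed))
  probs <- c(spec$p_arm_alter, spec$del_vs_amp, spec$within_arm_coherence,
             spec$deep_call_prob, spec$missing_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (spec$n_tumor < 2) stop("n_tumor must be >= 2")
  if (spec$n_normal < 0) stop("n_normal must be >= 0")
  if (spec$genes_per_arm < 1) stop("genes_per_arm must be >= 1")
  if (spec$n_incomplete_cases > spec$n_tumor) {
    stop("n_incomplete_cases exceeds n_tumor")
  }
  if (spec$clinical_association_or <= 0) stop("odds ratio must be positive")
  if (length(spec$universe) == 0) stop("empty arm universe")
  structure(spec, class = "cohort_spec")
}

# realize an H-score as a two-level intensity distribution: mass split
# between floor(score/100) and the next level reproduces the score exactly
score_to_distribution <- function(score) {
  score <- min(max(score, 0), 300)
  i <- min(floor(score / 100), 2)
  f <- score / 100 - i
  pct <- numeric(4)
  pct[i + 1] <- 100 * (1 - f)
  pct[i + 2] <- 100 * f
  pct
}

#' Generate a synthetic cohort bundle
#'
#' Draws, from the generating process in a [cohort_spec()]: a gene-by-case
#' GISTIC-style call matrix with arm-coherent alterations; an expression
#' matrix (tumors and normals) whose designated gene is log-normally
#' distributed with a per-altered-arm log increment; per-case IHC intensity
#' distributions; a clinical table; and the ground truth (true altered-arm
#' count and the CNA label implied by a median split on the truth).
#'
#' Fully reproducible: the spec's seed is set at entry.
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort_bundle` list: `copy_matrix` (genes x tumors, integer,
#'   NA = missing), `expression` (genes x all cases), `ihc` (data.frame),
#'   `clinical` (data.frame), `truth` (data.frame: case_id,
#'   true_altered_arms, incomplete, true_label), `arm_map`, `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)

  arms <- spec$universe
  n_arms <- length(arms)
  g <- spec$genes_per_arm
  gene_arm <- rep(arms, each = g)
  gene_ids <- paste0("GENE_", gene_arm, "_", sprintf("%03d", seq_len(g)))
  # the designated, burden-coupled gene sits on 1p
  slot <- which(gene_arm == "1p")[1]
  gene_ids[slot] <- spec$designated_gene
  n_genes <- length(gene_ids)

  tumors <- sprintf("TUMOR_%04d", seq_len(spec$n_tumor))
  normals <- if (spec$n_normal > 0) {
    sprintf("NORMAL_%04d", seq_len(spec$n_normal))
  } else character(0)

  # per-case arm alterations: 0 = none, -1 = arm deletion, +1 = arm gain
  altered <- matrix(stats::rbinom(n_arms * spec$n_tumor, 1,
                                  spec$p_arm_alter),
                    n_arms, spec$n_tumor, dimnames = list(arms, tumors))
  direction <- matrix(ifelse(stats::rbinom(n_arms * spec$n_tumor, 1,
                                           spec$del_vs_amp) == 1, -1L, 1L),
                      n_arms, spec$n_tumor)
  arm_call <- altered * direction

  # gene-level calls: genes on altered arms carry the arm's call with the
  # coherence probability (deep state with deep_call_prob), else 0
  gene_arm_call <- arm_call[gene_arm, , drop = FALSE]
  carries <- matrix(stats::rbinom(n_genes * spec$n_tumor, 1,
                                  spec$within_arm_coherence),
                    n_genes, spec$n_tumor)
  deep <- matrix(stats::rbinom(n_genes * spec$n_tumor, 1,
                               spec$deep_call_prob),
                 n_genes, spec$n_tumor)
  calls <- gene_arm_call * carries * (1L + deep)
  if (spec$missing_rate > 0) {
    calls[matrix(stats::runif(n_genes * spec$n_tumor), n_genes,
                 spec$n_tumor) < spec$missing_rate] <- NA_integer_
  }
  dimnames(calls) <- list(gene_ids, tumors)
  storage.mode(calls) <- "integer"

  incomplete <- rep(FALSE, spec$n_tumor)
  if (spec$n_incomplete_cases > 0) {
    incomplete[sample.int(spec$n_tumor, spec$n_incomplete_cases)] <- TRUE
    calls[, incomplete] <- NA_integer_
  }

  true_burden <- colSums(altered)
  # ground-truth labels: median split over the cases that remain classifiable
  med <- stats::median(true_burden[!incomplete])
  true_label <- ifelse(incomplete, "excluded",
                       ifelse(true_burden >= med, "CNA_high", "CNA_low"))

  # expression: log-normal; every gene gets the tumor fold, the designated
  # gene additionally couples to the true altered-arm burden
  em <- spec$expression_model
  cases <- c(tumors, normals)
  is_tumor <- c(rep(1, spec$n_tumor), rep(0, spec$n_normal))
  log_mean <- matrix(em$baseline_log_mean + em$tumor_log_fold *
                       rep(is_tumor, each = n_genes),
                     n_genes, length(cases))
  log_mean[slot, seq_len(spec$n_tumor)] <-
    log_mean[slot, seq_len(spec$n_tumor)] +
    em$burden_coupling_beta * true_burden
  expression <- matrix(stats::rlnorm(n_genes * length(cases),
                                     meanlog = log_mean,
                                     sdlog = em$baseline_log_sd),
                       n_genes, length(cases),
                       dimnames = list(gene_ids, cases))

  # IHC scores: log-normal around the tissue median, capped at the 300 scale
  # maximum, then realized as a two-level intensity distribution
  im <- spec$ihc_model
  scores <- pmin(300, c(
    stats::rlnorm(spec$n_tumor, log(im$tumor_median), im$log_sd),
    stats::rlnorm(spec$n_normal, log(im$normal_median), im$log_sd)))
  pct <- t(vapply(scores, score_to_distribution, numeric(4)))
  ihc <- data.frame(case_id = cases,
                    tissue = c(rep("tumor", spec$n_tumor),
                               rep("normal", spec$n_normal)),
                    pct0 = pct[, 1], pct1 = pct[, 2],
                    pct2 = pct[, 3], pct3 = pct[, 4],
                    score = scores, stringsAsFactors = FALSE)

  cutoff <- 3 * stats::median(scores[ihc$tissue == "normal"])
  if (spec$n_normal == 0) cutoff <- 150
  ihc_label <- ifelse(scores[seq_len(spec$n_tumor)] > cutoff, "high", "low")
  clinical <- generate_clinical(tumors, ihc_label,
                                association_or = spec$clinical_association_or)

  loc <- data.frame(gene_id = gene_ids, arm = gene_arm,
                    stringsAsFactors = FALSE)
  structure(list(copy_matrix = calls,
                 expression = expression,
                 ihc = ihc,
                 clinical = clinical,
                 truth = data.frame(case_id = tumors,
                                    true_altered_arms = as.integer(true_burden),
                                    incomplete = incomplete,
                                    true_label = true_label,
                                    stringsAsFactors = FALSE),
                 arm_map = build_arm_map(loc, universe = arms),
                 spec = spec),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle: %d tumors, %d normals, %d genes on %d arms\n",
              x$spec$n_tumor, x$spec$n_normal, nrow(x$copy_matrix),
              length(x$spec$universe)))
  invisible(x)
}

#' Generate a clinical table linked to an expression label
#'
#' Age, sex and smoking are drawn independently of the label; the advanced
#' level of pT, pN and TNM stage is linked to the `"high"` label through the
#' supplied odds ratio (OR = 1 gives independence). Baseline advanced-level
#' probabilities in the low group are fixed at 0.06 (pT3/pT4), 0.16
#' (pN1-pN3) and 0.10 (stage III/IV).
#'
#' @param case_ids character vector of case ids.
#' @param label character vector (`"low"`/`"high"`), same length.
#' @param association_or odds ratio (> 0) linking advanced categories to
#'   `"high"`.
#' @return data.frame: case_id, label, age, sex, smoking, pT, pN, stage.
#' @export
generate_clinical <- function(case_ids, label, association_or = 3) {
  stopifnot(length(case_ids) == length(label),
            all(label %in% c("low", "high")))
  if (association_or <= 0) stop("odds ratio must be positive")
  n <- length(case_ids)
  high <- label == "high"
  adv_prob <- function(p0) {
    o <- p0 / (1 - p0) * ifelse(high, association_or, 1)
    o / (1 + o)
  }
  draw <- function(p, a, b) ifelse(stats::runif(n) < p, a, b)
  data.frame(case_id = case_ids, label = label,
             age = draw(0.28, "<60", ">=60"),
             sex = draw(0.41, "Female", "Male"),
             smoking = draw(0.45, "Non-smoker", "Smoker"),
             pT = draw(adv_prob(0.06), "pT3/pT4", "pT1/pT2"),
             pN = draw(adv_prob(0.16), "pN1-pN3", "pN0"),
             stage = draw(adv_prob(0.10), "III/IV", "I/II"),
             stringsAsFactors = FALSE)
}

#' Specification for the cell-assay fixtures
#'
#' Emulates the two in vitro readouts: per-cell centriole (centrin focus)
#' counts under clone x cumate conditions, and per-metaphase chromosome
#' counts. Defaults: centrosome amplification (more than four foci) in 5% of
#' baseline cells versus 30% of induced cells; chromosome counts centered on
#' a median of 100 at baseline with a +15 shift on induction.
#'
#' @param clones clone labels; those matching `induced_pattern` respond to
#'   cumate.
#' @param induced_pattern regex marking inducible clones.
#' @param cells_per_condition cells scored per condition and replicate.
#' @param metaphases_per_condition metaphase spreads counted per condition.
#' @param replicates independent replicates for the foci assay.
#' @param foci_baseline_p,foci_induced_p probability a cell has more than
#'   four foci.
#' @param chrom_baseline_median,chrom_induced_shift,chrom_sd chromosome-count
#'   model (normal, rounded, floored at 30).
#' @param seed integer seed.
#' @return an `assay_spec` list.
#' @export
assay_spec <- function(clones = c("Empty-1", "STIL-1", "STIL-2"),
                       induced_pattern = "^STIL",
                       cells_per_condition = 100L,
                       metaphases_per_condition = 50L,
                       replicates = 3L,
                       foci_baseline_p = 0.05, foci_induced_p = 0.30,
                       chrom_baseline_median = 100,
                       chrom_induced_shift = 15,
                       chrom_sd = 10,
                       seed = 1L) {
  spec <- list(clones = clones, induced_pattern = induced_pattern,
               cells_per_condition = as.integer(cells_per_condition),
               metaphases_per_condition = as.integer(metaphases_per_condition),
               replicates = as.integer(replicates),
               foci_baseline_p = foci_baseline_p,
               foci_induced_p = foci_induced_p,
               chrom_baseline_median = chrom_baseline_median,
               chrom_induced_shift = chrom_induced_shift,
               chrom_sd = chrom_sd, seed = as.integer(seed))
  if (any(c(spec$foci_baseline_p, spec$foci_induced_p) < 0 |
          c(spec$foci_baseline_p, spec$foci_induced_p) > 1)) {
    stop("foci probabilities must lie in [0, 1]")
  }
  stopifnot(spec$cells_per_condition >= 1, spec$replicates >= 1,
            spec$metaphases_per_condition >= 1, spec$chrom_sd > 0)
  structure(spec, class = "assay_spec")
}

#' Generate cell-assay fixtures
#'
#' @param spec an [assay_spec()].
#' @return list with `foci` (data.frame: condition, clone, cumate, replicate,
#'   foci_count per cell) and `chromosomes` (data.frame: condition, clone,
#'   cumate, count per metaphase).
#' @export
generate_assay_fixtures <- function(spec) {
  stopifnot(inherits(spec, "assay_spec"))
  set.seed(spec$seed)
  grid <- expand.grid(clone = spec$clones, cumate = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  grid$condition <- paste0(grid$clone, ifelse(grid$cumate, "+cumate", ""))
  grid$induced <- grepl(spec$induced_pattern, grid$clone) & grid$cumate

  foci <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    p <- if (grid$induced[i]) spec$foci_induced_p else spec$foci_baseline_p
    do.call(rbind, lapply(seq_len(spec$replicates), function(r) {
      amplified <- stats::rbinom(spec$cells_per_condition, 1, p) == 1
      # normal cells hold 2-4 centrioles over the cycle; amplified ones more
      count <- ifelse(amplified,
                      sample(5:8, spec$cells_per_condition, replace = TRUE),
                      sample(2:4, spec$cells_per_condition, replace = TRUE,
                             prob = c(0.5, 0.2, 0.3)))
      data.frame(condition = grid$condition[i], clone = grid$clone[i],
                 cumate = grid$cumate[i], replicate = r,
                 foci_count = count, stringsAsFactors = FALSE)
    }))
  }))

  chromosomes <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    mu <- spec$chrom_baseline_median +
      if (grid$induced[i]) spec$chrom_induced_shift else 0
    count <- pmax(30, round(stats::rnorm(spec$metaphases_per_condition,
                                         mu, spec$chrom_sd)))
    data.frame(condition = grid$condition[i], clone = grid$clone[i],
               cumate = grid$cumate[i], count = as.integer(count),
               stringsAsFactors = FALSE)
  }))

  list(foci = foci, chromosomes = chromosomes)
}
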