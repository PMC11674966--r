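#!/usr/bin/env Rscript
# Step 4: cell-assay summaries. Centriole-focus counts: per-replicate
# percentage of cells with more than four foci, induced vs control compared
# by unpaired t-test. Chromosome counts: per-condition median/IQR with
# cumate-vs-untreated Mann-Whitney comparisons per clone.

suppressPackageStartupMessages(library(cnaburden))

src <- "results/cohorts"
out <- "results"

foci <- utils::read.delim(file.path(src, "assay_foci.tsv"))
pct <- do.call(rbind, lapply(
  split(foci, list(foci$condition, foci$replicate), drop = TRUE),
  function(d) data.frame(condition = d$condition[1], clone = d$clone[1],
                         cumate = d$cumate[1], replicate = d$replicate[1],
                         pct_amplified = amplified_fraction(d$foci_count))))
utils::write.table(pct[order(pct$condition, pct$replicate), ],
                   file.path(out, "assay_foci_percentages.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

induced <- pct$pct_amplified[grepl("^STIL", pct$clone) & pct$cumate]
control <- pct$pct_amplified[!(grepl("^STIL", pct$clone) & pct$cumate)]
tt <- unpaired_t_test(induced, control)
cat(sprintf(
  "centriole foci: amplified fraction %.1f%% (induced) vs %.1f%% (control), t-test p = %.4g\n",
  mean(induced), mean(control), tt$p_value))

chrom <- utils::read.delim(file.path(src, "assay_chromosomes.tsv"))
samples <- split(chrom$count, chrom$condition)
pairs <- lapply(unique(chrom$clone), function(cl) {
  c(cl, paste0(cl, "+cumate"))
})
res <- summarize_chromosome_counts(samples, comparisons = pairs)
utils::write.table(res$summary, file.path(out, "assay_chromosome_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(res$comparisons,
                   file.path(out, "assay_chromosome_tests.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("chromosome counts per condition:\n")
print(res$summary, row.names = FALSE)
cat("cumate effect per clone (Mann-Whitney):\n")
print(res$comparisons, row.names = FALSE)
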