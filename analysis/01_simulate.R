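#!/usr/bin/env Rscript
# Step 1: generate the two synthetic cohorts (LUAD-shaped: 515 tumors / 59
# normals; LUSC-shaped: 501 / 51, each with 3 incomplete cases) and the
# cell-assay fixtures, and write them as TSVs so the later steps exercise the
# same readers a real cBioPortal export would go through.

suppressPackageStartupMessages(library(cnaburden))

out <- "results/cohorts"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

specs <- list(
  LUAD = cohort_spec(n_tumor = 515, n_normal = 59, seed = 101),
  LUSC = cohort_spec(n_tumor = 501, n_normal = 51,
                     expression_model = list(
                       baseline_log_mean = log(40), baseline_log_sd = 0.8,
                       tumor_log_fold = log(382 / 40),
                       burden_coupling_beta = 0.05),
                     ihc_model = list(normal_median = 50, tumor_median = 190,
                                      log_sd = 0.5),
                     seed = 102)
)

for (name in names(specs)) {
  b <- generate_cohort(specs[[name]])
  write_copy_matrix(b$copy_matrix, file.path(out, paste0(name, "_cn.tsv")))
  write_expression(b$expression, file.path(out, paste0(name, "_expr.tsv")))
  utils::write.table(b$ihc, file.path(out, paste0(name, "_ihc.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(b$clinical, file.path(out, paste0(name, "_clinical.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(b$arm_map$genes,
                     file.path(out, paste0(name, "_gene_locations.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(b$truth, file.path(out, paste0(name, "_truth.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s cohort: %d tumors (%d incomplete), %d normals, %d genes\n",
              name, specs[[name]]$n_tumor, specs[[name]]$n_incomplete_cases,
              specs[[name]]$n_normal, nrow(b$copy_matrix)))
}

fx <- generate_assay_fixtures(assay_spec(seed = 103))
utils::write.table(fx$foci, file.path(out, "assay_foci.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(fx$chromosomes, file.path(out, "assay_chromosomes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("assay fixtures: %d foci-scored cells, %d metaphases\n",
            nrow(fx$foci), nrow(fx$chromosomes)))
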