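#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-sample GWAS panel with known truth.
#
# Emits, under results/data/: one summary-statistics TSV per metabolic trait,
# the outcome GWAS, the LD matrix, the trait metadata, and the true causal
# effects (for later comparison -- nothing downstream reads the truth).

suppressMessages(library(metabomr))

seed <- 20260920L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- make_metabolomics_panel(seed = seed)

for (id in names(panel$truth$exposures)) {
  write_summary_table(panel$truth$exposures[[id]],
                      file.path(out, paste0(id, ".tsv")))
}
write_summary_table(panel$truth$outcome, file.path(out, "outcome.tsv"))
write_ld_matrix(panel$truth$ld, file.path(out, "ld.tsv"))
write_trait_metadata(panel$metadata, file.path(out, "trait_metadata.tsv"))
utils::write.table(
  data.frame(trait_id = names(panel$causal), true_effect = panel$causal),
  file.path(out, "true_effects.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
rho <- panel$truth$rho
utils::write.table(data.frame(trait_id = rownames(rho), rho,
                              check.names = FALSE),
                   file.path(out, "rho.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)

cat(sprintf(
  "Simulated %d metabolic traits x %d SNPs (exposure n = %d, outcome n = %d).\n",
  length(panel$truth$exposures), nrow(panel$truth$outcome),
  panel$truth$scenario$n_x, panel$truth$scenario$n_y))
cat("True causal effects:",
    paste(sprintf("%s = %.2f", names(panel$causal)[panel$causal != 0],
                  panel$causal[panel$causal != 0]), collapse = ", "), "\n")
cat("Tables written under", out, "\n")
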