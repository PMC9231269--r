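#!/usr/bin/env Rscript
# Stage 3: univariable two-sample MR per retained trait.
#
# Instruments: p < 5e-8, pairwise r^2 < 0.01, harmonised to the outcome with
# palindromic SNPs resolved by allele frequency (MAF > 42% removed). Method
# by instrument count: Wald ratio (1 SNP) or IVW (>1), with mean F,
# Cochran's Q and leave-one-out diagnostics. Traits with p < 0.05 become
# multivariable candidates.

suppressMessages(library(metabomr))

data_dir <- "results/data"
filter_report <- utils::read.delim("results/filter_report.tsv")
panel <- filter_report$trait_id[filter_report$stage == "kept"]
ld <- read_ld_matrix(file.path(data_dir, "ld.tsv"))
outcome <- read_summary_table(file.path(data_dir, "outcome.tsv"),
                              trait_id = "outcome")

instruments <- lapply(panel, function(id) {
  tab <- read_summary_table(file.path(data_dir, paste0(id, ".tsv")),
                            trait_id = id)
  select_instruments(tab, outcome, ld)
})
names(instruments) <- panel

results <- lapply(instruments, run_uvmr)
uvmr_tab <- mr_results_table(results)
utils::write.table(uvmr_tab, "results/uvmr_results.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

loo <- do.call(rbind, lapply(panel, function(id) {
  if (n_instruments(instruments[[id]]) < 3) return(NULL)
  cbind(exposure = id, leave_one_out(instruments[[id]]))
}))
utils::write.table(loo, "results/loo_results.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

candidates <- screen_uvmr(results, p_screen = 0.05)
utils::write.table(data.frame(trait_id = candidates),
                   "results/candidates.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cat(sprintf("UVMR across %d traits (mean F %.0f-%.0f among instrumented traits).\n",
            length(panel), min(uvmr_tab$mean_F, na.rm = TRUE),
            max(uvmr_tab$mean_F, na.rm = TRUE)))
for (id in candidates) {
  row <- uvmr_tab[uvmr_tab$exposure == id, ]
  cat(sprintf("  candidate %s: %.3f (95%% CI %.3f, %.3f), p = %.2g, K = %d\n",
              id, row$estimate, row$ci_low, row$ci_high, row$pvalue,
              row$n_snps))
}
missing <- uvmr_tab$exposure[uvmr_tab$method == "none"]
if (length(missing)) {
  cat("  no instruments selected for:", paste(missing, collapse = ", "), "\n")
}
cat(sprintf("%d candidate trait(s) proceed to multivariable MR.\n",
            length(candidates)))
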