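#!/usr/bin/env Rscript
# Stage 2: reduce the trait panel -- drop derived ratios and composites, keep
# one total-lipids measure per lipoprotein subclass, then prune traits whose
# genetic correlation is so high (rg^2 > 0.985) that a joint model cannot
# separate them.

suppressMessages(library(metabomr))

data_dir <- "results/data"
metadata <- read_trait_metadata(file.path(data_dir, "trait_metadata.tsv"))
ld <- read_ld_matrix(file.path(data_dir, "ld.tsv"))

stage1 <- filter_ratios_composites(metadata)
cat(sprintf("Stage 1 (ratios/composites): %d in, %d excluded.\n",
            nrow(metadata), nrow(stage1$excluded)))

meta2 <- metadata[metadata$trait_id %in% stage1$kept, ]
stage2 <- select_lipoprotein_subset(meta2)
cat(sprintf("Stage 2 (lipoprotein subclasses): %d excluded.\n",
            nrow(stage2$excluded)))

# genetic correlation over the union of genome-wide-significant,
# LD-independent instruments
tables <- lapply(stage2$kept, function(id) {
  read_summary_table(file.path(data_dir, paste0(id, ".tsv")), trait_id = id)
})
names(tables) <- stage2$kept
outcome <- read_summary_table(file.path(data_dir, "outcome.tsv"),
                              trait_id = "outcome")
instr <- lapply(tables, select_instruments, outcome = outcome, ld = ld)
union_snps <- unique(unlist(lapply(instr, function(s) s$records$snp)))
rg <- genetic_correlation_matrix(tables, union_snps)
stage3 <- prune_genetic_correlation(rg, priority = stage2$kept)
cat(sprintf("Stage 3 (rg^2 > 0.985): removed %s.\n",
            paste(stage3$excluded$trait_id, collapse = ", ")))

dir.create("results", showWarnings = FALSE)
excl <- rbind(stage1$excluded, stage2$excluded, stage3$excluded)
report <- rbind(data.frame(trait_id = stage3$kept, stage = "kept",
                           reason = ""), excl)
utils::write.table(report, "results/filter_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(trait_id = rownames(rg), round(rg, 6),
                              check.names = FALSE),
                   "results/genetic_correlation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("%d traits enter the univariable analysis; report in results/filter_report.tsv\n",
            length(stage3$kept)))
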