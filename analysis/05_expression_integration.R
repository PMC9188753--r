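#!/usr/bin/env Rscript
# Normalize the expression counts (median of ratios), screen for
# differential expression between mutant and sibling within each cell type
# (|log2FC| >= 1, BH-adjusted p < 0.05), and integrate promoter
# methylation with expression: genes with Pearson r < -0.3 across the nine
# sibling samples but not across the nine mutant samples are candidate
# methylation-regulated genes; the stage filter then keeps genes whose
# promoter methylation rises while expression falls across a transition in
# siblings only.

suppressMessages({library(ehtmeth); library(data.table)})

sheet <- read_sample_sheet("results/data/sample_sheet.tsv")
samples <- load_samples(sheet)
sizes <- read_chrom_sizes("results/data/chrom.sizes")
models <- read_gene_models("results/data/genes.gtf")
cts <- fread("results/data/counts.tsv")
counts <- as.matrix(cts[, -1]); rownames(counts) <- cts[[1]]
ids <- function(ct, gt) sheet[cell_type == ct & genotype == gt, sample_id]

norm <- normalize_counts(counts)
deg_union <- character()
for (ct in c("EC", "HEC", "HSPC")) {
  dg <- call_degs(norm$normalized, ids(ct, "sibling"), ids(ct, "mutant"))
  fwrite(dg, sprintf("results/deg_%s_mut_vs_sib.tsv", ct), sep = "\t")
  cat(sprintf("%-5s mutant vs sibling: %3d up, %3d down of %d genes\n", ct,
              sum(dg$passes & dg$direction == "up"),
              sum(dg$passes & dg$direction == "down"), nrow(dg)))
  deg_union <- union(deg_union, dg[passes == TRUE, gene_id])
}
cat(sprintf("DEG union across stages: %d genes (methylation-silenced genes\n",
            length(deg_union)))
cat("are derepressed when dnmt1 is lost, so DEGs skew upward)\n\n")

pm <- promoter_methylation_matrix(samples, models$genes, chrom_sizes = sizes)
int <- integrate_methylation_expression(deg_union, pm, norm$normalized, sheet)
fwrite(int, "results/integration.tsv", sep = "\t")
cat(sprintf("integration: %d of %d DEGs have r < -0.3 in siblings only\n",
            sum(int$selected), nrow(int)))

stf <- stage_transition_filter(int[selected == TRUE, gene_id], pm,
                               log2(norm$normalized + 1), sheet)
fwrite(stf, "results/stage_transition_genes.tsv", sep = "\t")
cat(sprintf("stage filter: %d genes at the specification step (EC -> HEC),\n",
            sum(stf$passes_EC_HEC, na.rm = TRUE)))
cat(sprintf("              %d genes at the generation step (HEC -> HSPC)\n",
            sum(stf$passes_HEC_HSPC, na.rm = TRUE)))
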