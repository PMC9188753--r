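#!/usr/bin/env Rscript
# Generate the synthetic WGBS + RNA-seq study: 3 cell types (EC, HEC, HSPC)
# x 2 genotypes (sibling, dnmt1 mutant) x 3 replicates on a 2 x 1 Mb
# genome, with planted six-pattern DMR tiles, a genotype-wide mutant
# hypomethylation and 200 promoter-methylation-coupled genes. Data files
# (cytosine reports, GTF, counts, sample sheet) and ground-truth sidecars
# are written under results/data/.

suppressMessages(library(ehtmeth))

cfg <- sim_config(seed = 1)
st <- simulate_study(cfg, outdir = "results/data")

cat(sprintf("genome: %d chromosomes, %d CpGs, %d tiles, %d genes (%d coupled)\n",
            cfg$n_chromosomes, nrow(st$genome$cpgs), nrow(st$genome$tiles),
            nrow(st$genome$genes), cfg$n_coupled_genes))
cat(sprintf("planted DMR tiles: %d (%d per pattern x 6 patterns)\n",
            nrow(st$genome$planted), cfg$n_planted_dmrs_per_pattern))
cat("true per-group mean tile methylation:\n")
print(st$meth$truth_global)
cat("files written to results/data/\n")
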