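#!/usr/bin/env Rscript
# Clone bisulfite-PCR summary: per-amplicon methylation percentage and
# per-CpG lollipop profile from a clones x CpG binary matrix, as used to
# validate locus-level methylation differences between sibling and mutant.
# The two amplicon matrices here are synthetic demonstrations drawn from
# the simulated study's effect sizes (a high-methylation sibling locus and
# its hypomethylated mutant counterpart).

suppressMessages({library(ehtmeth); library(data.table)})

set.seed(1)
make_amplicon <- function(p_meth, n_clones = 10, n_cpg = 12) {
  m <- matrix(rbinom(n_clones * n_cpg, 1, p_meth), n_clones, n_cpg)
  m[sample(length(m), 3)] <- NA   # a few unreadable calls
  dimnames(m) <- list(sprintf("clone%02d", 1:n_clones),
                      sprintf("cpg%02d", 1:n_cpg))
  m
}
amplicons <- list(sibling_locus = make_amplicon(0.85),
                  mutant_locus = make_amplicon(0.25))

summary_tab <- rbindlist(lapply(names(amplicons), function(nm) {
  m <- amplicons[[nm]]
  fwrite(data.table(clone = rownames(m), m),
         sprintf("results/clones_%s_synthetic.tsv", nm), sep = "\t")
  data.table(amplicon = nm, n_clones = nrow(m), n_cpg = ncol(m),
             pct_methylated = round(clone_methylation_percentage(m), 1))
}))
fwrite(summary_tab, "results/clone_summary.tsv", sep = "\t")
print(summary_tab)

prof <- per_cpg_profile(amplicons$sibling_locus)
cat("\nper-CpG methylated fraction (sibling locus):\n")
print(round(prof, 2))
cat("the sibling locus stays heavily methylated in nearly every clone;\n")
cat("the mutant locus loses methylation at most CpGs.\n")
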