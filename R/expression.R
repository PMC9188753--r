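#' Median-of-ratios count normalization
#'
#' Size factors are the per-sample median ratio of counts to the per-gene
#' geometric mean, computed over genes expressed in every sample (geometric
#' mean > 0); factors are rescaled to geometric mean 1. Output is counts
#' divided by the sample's size factor.
#'
#' @param counts Non-negative integer matrix, genes x samples (rownames =
#'   gene ids).
#' @return List with `normalized` (matrix) and `size_factors`.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  if (nrow(counts) < 2L)
    stop("need >= 2 genes for a robust median of ratios")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  log_gm <- rowMeans(log(counts))          # -Inf for genes with any zero
  use <- is.finite(log_gm)
  if (!any(use)) stop("no gene expressed in every sample")
  sf <- apply(counts[use, , drop = FALSE], 2, function(x)
    exp(stats::median(log(x) - log_gm[use])))
  sf <- sf / exp(mean(log(sf)))
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Differential-expression screen between two sample groups
#'
#' A transparent engine with the conventional thresholds: log2 fold change
#' from pseudocount-1 group means of normalized counts (group_b over
#' group_a), p-values from a two-sample t-test on log2(normalized + 1),
#' Benjamini-Hochberg adjustment over all genes, and a conjunctive pass
#' flag `p_adj < deg_alpha AND |log2fc| >= lfc_threshold`.
#'
#' @param normalized Normalized matrix from [normalize_counts()].
#' @param group_a_ids,group_b_ids Disjoint column names, >= 2 each.
#' @param deg_alpha Adjusted-p threshold (default 0.05; the looser 0.5 some
#'   studies print can be supplied explicitly).
#' @param lfc_threshold Absolute log2-fold-change threshold (default 1).
#' @return data.table `gene_id`, `mean_a`, `mean_b`, `log2fc`, `p_raw`,
#'   `p_adj`, `passes`, `direction`.
#' @export
call_degs <- function(normalized, group_a_ids, group_b_ids,
                      deg_alpha = 0.05, lfc_threshold = 1) {
  if (length(intersect(group_a_ids, group_b_ids))) stop("groups overlap")
  if (length(group_a_ids) < 2L || length(group_b_ids) < 2L)
    stop("need >= 2 replicates per group")
  la <- log2(normalized[, group_a_ids, drop = FALSE] + 1)
  lb <- log2(normalized[, group_b_ids, drop = FALSE] + 1)
  mean_a <- rowMeans(normalized[, group_a_ids, drop = FALSE])
  mean_b <- rowMeans(normalized[, group_b_ids, drop = FALSE])
  log2fc <- log2(mean_b + 1) - log2(mean_a + 1)
  p_raw <- vapply(seq_len(nrow(la)), function(i) {
    student_t_two_sample(la[i, ], lb[i, ])$p
  }, 1.0)
  p_adj <- bh_adjust(p_raw)
  out <- data.table(gene_id = rownames(normalized), mean_a = mean_a,
                    mean_b = mean_b, log2fc = log2fc, p_raw = p_raw,
                    p_adj = p_adj)
  out[, passes := p_adj < deg_alpha & abs(log2fc) >= lfc_threshold]
  out[, direction := ifelse(log2fc > 0, "up", "down")]
  out[]
}

#' Promoter methylation level per gene for one sample
#'
#' Pools methylated/total counts over the CpGs falling inside each gene's
#' strand-aware promoter window (TSS -`up`/+`down`); missing when no
#' covered CpG lies in the window.
#'
#' @param sample A `methylome_sample` or records data.table.
#' @param genes Gene models data.table (`gene_id`, `chrom`, `strand`,
#'   `tss0`).
#' @param up,down Promoter extents (default 1000/1000).
#' @param chrom_sizes Optional clipping.
#' @return data.table `gene_id`, `meth`, `total`, `level`.
#' @export
promoter_methylation_per_gene <- function(sample, genes, up = 1000L,
                                          down = 1000L, chrom_sizes = NULL) {
  rec <- if (inherits(sample, "methylome_sample")) sample$records
         else as.data.table(sample)
  prom <- promoter_region(genes, up, down, chrom_sizes)
  setkey(prom, chrom, start0, end0)
  r <- copy(rec)[total > 0L][, `:=`(start0 = pos0, end0 = pos0 + 1L)]
  hits <- foverlaps(r, prom, type = "within", nomatch = NULL)
  agg <- hits[, .(meth = sum(meth), total = sum(total)), by = gene_id]
  out <- agg[as.data.table(genes)[, .(gene_id)], on = "gene_id"]
  out[is.na(total), `:=`(meth = 0L, total = 0L)]
  out[, level := ifelse(total > 0, meth / total, NA_real_)]
  out[]
}

#' Promoter methylation matrix (genes x samples)
#'
#' @param samples Named list of `methylome_sample`.
#' @param genes Gene models.
#' @inheritParams promoter_methylation_per_gene
#' @return Numeric matrix genes x samples of promoter levels (NA where no
#'   covered CpG).
#' @export
promoter_methylation_matrix <- function(samples, genes, up = 1000L,
                                        down = 1000L, chrom_sizes = NULL) {
  cols <- lapply(samples, function(s)
    promoter_methylation_per_gene(s, genes, up, down, chrom_sizes)$level)
  m <- do.call(cbind, cols)
  rownames(m) <- genes$gene_id
  colnames(m) <- vapply(samples, `[[`, "", "sample_id")
  m
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r; returns NA (gene excluded downstream) when either
#' vector has zero variance or fewer than 3 complete pairs.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation in \[-1, 1\], or NA.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Integrate promoter methylation with expression per genotype
#'
#' For each gene, computes the Pearson correlation between log2(normalized
#' expression + 1) and promoter methylation across all samples of each
#' genotype (3 cell types x replicates). A gene is selected as putatively
#' methylation-regulated when the sibling correlation is below
#' `corr_threshold` and the mutant correlation is not
#' (`corr_mutant >= corr_threshold`), i.e. the negative coupling present in
#' siblings is lost in the mutant.
#'
#' @param gene_ids Genes to integrate (e.g. a DEG list).
#' @param promoter_meth Matrix genes x samples of promoter levels.
#' @param expression Matrix genes x samples of normalized counts.
#' @param sheet Sample sheet data.table (`sample_id`, `genotype`).
#' @param corr_threshold Correlation threshold (default -0.3).
#' @param min_meth_sd Minimum standard deviation of sibling promoter
#'   methylation across samples for a gene to be informative (default
#'   0.04, about twice the measurement noise floor at 30x coverage). A
#'   correlation against near-constant methylation carries no signal, so
#'   such genes are excluded rather than screened on noise -- the same
#'   independent-filtering logic used before differential tests.
#' @return data.table `gene_id`, `corr_sibling`, `corr_mutant`, `sd_meth_sibling`,
#'   `selected`, `n_sibling`, `n_mutant`. Genes with < 3 usable samples in
#'   a genotype or sub-threshold methylation variability get NA correlation
#'   and are never selected; their count is in attribute `n_excluded`.
#' @export
integrate_methylation_expression <- function(gene_ids, promoter_meth,
                                             expression, sheet,
                                             corr_threshold = -0.3,
                                             min_meth_sd = 0.04) {
  sib <- sheet$sample_id[sheet$genotype == "sibling"]
  mut <- sheet$sample_id[sheet$genotype == "mutant"]
  if (length(sib) < 3L || length(mut) < 3L)
    stop("need >= 3 samples per genotype")
  gene_ids <- intersect(gene_ids, rownames(promoter_meth))
  res <- rbindlist(lapply(gene_ids, function(g) {
    e <- log2(expression[g, ] + 1)
    m <- promoter_meth[g, ]
    ok_s <- sib[is.finite(m[sib]) & is.finite(e[sib])]
    ok_m <- mut[is.finite(m[mut]) & is.finite(e[mut])]
    sd_s <- if (length(ok_s) >= 3L) stats::sd(m[ok_s]) else NA_real_
    cs <- if (!is.na(sd_s) && sd_s >= min_meth_sd)
      pearson_correlation(m[ok_s], e[ok_s]) else NA_real_
    data.table(gene_id = g,
               corr_sibling = cs,
               corr_mutant = pearson_correlation(m[ok_m], e[ok_m]),
               sd_meth_sibling = sd_s,
               n_sibling = length(ok_s), n_mutant = length(ok_m))
  }))
  res[, selected := !is.na(corr_sibling) & !is.na(corr_mutant) &
        corr_sibling < corr_threshold & corr_mutant >= corr_threshold]
  setattr(res, "n_excluded",
          sum(is.na(res$corr_sibling) | is.na(res$corr_mutant)))
  res[]
}

#' Stage-transition filter on methylation gain with expression loss
#'
#' A gene passes a transition (EC to HEC, or HEC to HSPC) when its mean
#' promoter methylation increases AND its mean expression decreases across
#' that transition in sibling samples, and NOT both in mutant samples.
#' Means are over the replicates of each cell type within a genotype.
#'
#' @param gene_ids Genes to screen.
#' @param promoter_meth,expression Matrices genes x samples.
#' @param sheet Sample sheet (`sample_id`, `cell_type`, `genotype`).
#' @param transitions List of c(from, to) cell-type pairs.
#' @return data.table `gene_id`, one logical `passes_<from>_<to>` column
#'   per transition (NA when a required group mean is missing).
#' @export
stage_transition_filter <- function(gene_ids, promoter_meth, expression,
                                    sheet,
                                    transitions = list(c("EC", "HEC"),
                                                       c("HEC", "HSPC"))) {
  grp_mean <- function(mat, ct, gt) {
    ids <- sheet$sample_id[sheet$cell_type == ct & sheet$genotype == gt]
    rowMeans(mat[gene_ids, ids, drop = FALSE], na.rm = TRUE)
  }
  out <- data.table(gene_id = gene_ids)
  for (tr in transitions) {
    from <- tr[1]; to <- tr[2]
    dm_s <- grp_mean(promoter_meth, to, "sibling") -
      grp_mean(promoter_meth, from, "sibling")
    de_s <- grp_mean(expression, to, "sibling") -
      grp_mean(expression, from, "sibling")
    dm_m <- grp_mean(promoter_meth, to, "mutant") -
      grp_mean(promoter_meth, from, "mutant")
    de_m <- grp_mean(expression, to, "mutant") -
      grp_mean(expression, from, "mutant")
    pass <- (dm_s > 0) & (de_s < 0) & !((dm_m > 0) & (de_m < 0))
    pass[is.nan(dm_s) | is.nan(de_s) | is.nan(dm_m) | is.nan(de_m)] <- NA
    out[, (sprintf("passes_%s_%s", from, to)) := pass]
  }
  out[]
}
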