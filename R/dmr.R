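#' Unpaired two-tailed Student's t-test on replicate methylation levels
#'
#' Equal-variance (pooled) Student's t with `n_a + n_b - 2` degrees of
#' freedom, two-tailed. Degenerate inputs are resolved explicitly: when both
#' groups have zero variance, p is 1 for equal means and 0 for unequal means.
#'
#' @param a,b Numeric vectors of per-replicate tile levels (NA dropped).
#' @return List with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
student_t_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need >= 2 non-missing replicates per group")
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  if (sp2 <= 0) {
    if (isTRUE(all.equal(ma, mb))) {
      return(list(t = 0, p = 1, df = df, mean_a = ma, mean_b = mb))
    }
    return(list(t = sign(mb - ma) * Inf, p = 0, df = df,
                mean_a = ma, mean_b = mb))
  }
  tstat <- (mb - ma) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df), df = df,
       mean_a = ma, mean_b = mb)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1, preserving input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

group_tile_levels <- function(samples, tiles, group_a_ids, group_b_ids,
                              min_shared_cpg) {
  # Re-pool counts using only CpG sites covered (total > 0) in every sample
  # of both groups, then form per-replicate tile levels.
  ids <- c(group_a_ids, group_b_ids)
  long <- rbindlist(lapply(ids, function(id) {
    s <- samples[[id]]
    cbind(s$records[total > 0L], sample_id = id)
  }))
  n_needed <- length(ids)
  shared <- long[, .N, by = .(chrom, pos0)][N == n_needed, .(chrom, pos0)]
  long <- long[shared, on = c("chrom", "pos0")]
  long <- assign_tiles(long, tiles)[!is.na(tile_id)]
  agg <- long[, .(meth = sum(meth), total = sum(total), n_cpg = .N),
              by = .(tile_id, sample_id)]
  ncpg <- agg[sample_id == ids[1], .(tile_id, n_cpg)]
  lev <- matrix(NA_real_, nrow(tiles), length(ids),
                dimnames = list(tiles$tile_id, ids))
  lev[cbind(match(agg$tile_id, tiles$tile_id),
            match(agg$sample_id, ids))] <- agg$meth / agg$total
  n_shared <- integer(nrow(tiles))
  n_shared[match(ncpg$tile_id, tiles$tile_id)] <- ncpg$n_cpg
  list(levels = lev, n_shared_cpg = n_shared)
}

#' Call differentially methylated regions between two groups
#'
#' Per tile, counts are re-pooled over CpG sites recovered (covered) in
#' every sample of both groups; tiles with fewer than `min_shared_cpg` such
#' sites are left untested. Each tested tile gets an unpaired two-tailed
#' Student's t-test on the per-replicate tile levels; p-values are
#' Benjamini-Hochberg adjusted over all tested tiles. A tile is a DMR when
#' the absolute difference of group means exceeds `diff_threshold` AND the
#' adjusted p-value is below `alpha` (both strict).
#'
#' @param samples Named list of `methylome_sample` (names = sample ids).
#' @param tiles Tiles from [make_tiles()].
#' @param group_a_ids,group_b_ids Disjoint character vectors of sample ids.
#' @param min_shared_cpg Minimum shared covered CpGs per tile (default 3).
#' @param diff_threshold Methylation-difference threshold (default 0.2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return List with `calls` (data.table of emitted DMRs: `tile_id`,
#'   `chrom`, `start0`, `end0`, `mean_a`, `mean_b`, `diff`, `p_raw`,
#'   `p_adj`, `direction`, `n_shared_cpg`) and `tested` (all tested tiles
#'   with the same statistics).
#' @export
call_dmrs <- function(samples, tiles, group_a_ids, group_b_ids,
                      min_shared_cpg = 3L, diff_threshold = 0.2,
                      alpha = 0.05) {
  if (!length(group_a_ids) || !length(group_b_ids)) stop("empty group")
  if (length(intersect(group_a_ids, group_b_ids)))
    stop("groups must be disjoint")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  gl <- group_tile_levels(samples, tiles, group_a_ids, group_b_ids,
                          min_shared_cpg)
  la <- gl$levels[, group_a_ids, drop = FALSE]
  lb <- gl$levels[, group_b_ids, drop = FALSE]
  ok <- gl$n_shared_cpg >= min_shared_cpg &
    rowSums(!is.na(la)) >= 2L & rowSums(!is.na(lb)) >= 2L
  idx <- which(ok)
  if (!length(idx)) {
    empty <- data.table(tile_id = character(), chrom = character(),
                        start0 = integer(), end0 = integer(),
                        mean_a = numeric(), mean_b = numeric(),
                        diff = numeric(), p_raw = numeric(),
                        p_adj = numeric(), direction = character(),
                        n_shared_cpg = integer())
    return(list(calls = empty, tested = empty))
  }
  res <- vapply(idx, function(i) {
    r <- student_t_two_sample(la[i, ], lb[i, ])
    c(r$mean_a, r$mean_b, r$p)
  }, numeric(3))
  tested <- data.table(tiles[idx, .(tile_id, chrom, start0, end0)],
                       mean_a = res[1, ], mean_b = res[2, ],
                       p_raw = res[3, ],
                       n_shared_cpg = gl$n_shared_cpg[idx])
  tested[, diff := mean_b - mean_a]
  tested[, p_adj := bh_adjust(p_raw)]
  tested[, direction := ifelse(diff > 0, "hyper", "hypo")]
  setcolorder(tested, c("tile_id", "chrom", "start0", "end0", "mean_a",
                        "mean_b", "diff", "p_raw", "p_adj", "direction",
                        "n_shared_cpg"))
  calls <- tested[abs(diff) > diff_threshold & p_adj < alpha]
  list(calls = calls[], tested = tested[])
}

#' Hyper/hypo DMR direction summary
#'
#' @param calls `calls` table from [call_dmrs()].
#' @return List with `n_hyper`, `n_hypo`, `pct_hyper`, `pct_hypo`
#'   (percentages are NA when there are no calls).
#' @export
dmr_direction_summary <- function(calls) {
  n_hyper <- sum(calls$direction == "hyper")
  n_hypo <- sum(calls$direction == "hypo")
  n <- n_hyper + n_hypo
  list(n_hyper = n_hyper, n_hypo = n_hypo,
       pct_hyper = if (n > 0) 100 * n_hyper / n else NA_real_,
       pct_hypo = if (n > 0) 100 * n_hypo / n else NA_real_)
}

#' Canonical six-pattern profiles across EC, HEC, HSPC
#'
#' Min-max-normalized (EC, HEC, HSPC) methylation profiles of the six
#' canonical DMR patterns: C1 gradual gain towards HSPC, C2 HSPC-specific
#' hypermethylation, C3 HEC-specific hypomethylation, C4 HEC-specific
#' hypermethylation, C5 EC-specific hypomethylation, C6 HSPC-specific
#' hypomethylation.
#'
#' @return 6 x 3 numeric matrix, rows C1..C6, columns EC/HEC/HSPC.
#' @export
canonical_patterns <- function() {
  m <- rbind(C1 = c(0, 0.5, 1),
             C2 = c(0, 0, 1),
             C3 = c(1, 0, 1),
             C4 = c(0, 1, 0),
             C5 = c(0, 1, 1),
             C6 = c(1, 1, 0))
  colnames(m) <- CELL_TYPES
  m
}

pattern_labels <- c(C1 = "gradual-gain-to-HSPC", C2 = "HSPC-specific-hyper",
                    C3 = "HEC-specific-hypo", C4 = "HEC-specific-hyper",
                    C5 = "EC-specific-hypo", C6 = "HSPC-specific-hypo")

#' Assign DMRs to the six canonical methylation patterns
#'
#' Each DMR's (EC, HEC, HSPC) mean-level profile is min-max normalized and
#' assigned to the nearest canonical pattern centroid in Euclidean distance
#' (the rule-based default). An alternative seeded k-means backend with k=6
#' on z-scored profiles is available for sensitivity analysis; its clusters
#' are relabelled by nearest canonical centroid of the cluster means.
#'
#' @param profiles Matrix or data.frame of per-DMR mean methylation levels
#'   with columns `EC`, `HEC`, `HSPC` (rownames = DMR/tile ids).
#' @param method `"rule"` (default) or `"kmeans"`.
#' @param seed Seed for the k-means backend.
#' @return data.table with `tile_id`, `cluster` (C1..C6), `pattern`
#'   (descriptive label), `EC`, `HEC`, `HSPC`. Profiles with a missing level
#'   or zero range are returned with `cluster = NA` and counted in the
#'   `unassigned` attribute.
#' @export
assign_six_clusters <- function(profiles, method = c("rule", "kmeans"),
                                seed = 1L) {
  method <- match.arg(method)
  prof <- as.matrix(profiles)[, CELL_TYPES, drop = FALSE]
  ids <- rownames(prof)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(prof)))
  rng <- apply(prof, 1, function(x) diff(range(x)))
  ok <- stats::complete.cases(prof) & rng > 0
  cluster <- rep(NA_character_, nrow(prof))
  if (any(ok)) {
    norm <- t(apply(prof[ok, , drop = FALSE], 1,
                    function(x) (x - min(x)) / (max(x) - min(x))))
    cents <- canonical_patterns()
    d2 <- outer(seq_len(nrow(norm)), seq_len(nrow(cents)),
                Vectorize(function(i, j) sum((norm[i, ] - cents[j, ])^2)))
    if (method == "rule") {
      cluster[ok] <- rownames(cents)[max.col(-d2, ties.method = "first")]
    } else {
      set.seed(seed)
      km <- stats::kmeans(scale_rows(prof[ok, , drop = FALSE]),
                          centers = 6L, nstart = 25L, iter.max = 100L)
      cm <- km$centers
      # relabel k-means clusters by their mean profile's nearest canonical
      cm_norm <- t(apply(cm, 1, function(x) {
        r <- max(x) - min(x); if (r == 0) rep(0.5, 3) else (x - min(x)) / r
      }))
      lab <- rownames(cents)[apply(cm_norm, 1, function(x)
        which.min(colSums((t(cents) - x)^2)))]
      cluster[ok] <- lab[km$cluster]
    }
  }
  out <- data.table(tile_id = ids, cluster = cluster,
                    pattern = pattern_labels[cluster],
                    EC = prof[, "EC"], HEC = prof[, "HEC"],
                    HSPC = prof[, "HSPC"])
  setattr(out, "unassigned", sum(!ok))
  out[]
}

scale_rows <- function(m) {
  t(apply(m, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
}

#' Per-DMR mean-level profiles across the three cell types
#'
#' Builds the (EC, HEC, HSPC) profile of each tile as the mean of the
#' per-replicate tile levels within each cell type of one genotype
#' (sibling by default, the reference methylome).
#'
#' @param tm A `tile_matrix`.
#' @param tile_ids Tiles to profile.
#' @param genotype Genotype whose samples form the profiles.
#' @return Matrix tiles x (EC, HEC, HSPC).
#' @export
celltype_profiles <- function(tm, tile_ids, genotype = "sibling") {
  keep <- tm$samples$genotype == genotype
  prof <- sapply(CELL_TYPES, function(ct) {
    cols <- which(keep & tm$samples$cell_type == ct)
    rowMeans(tm$level[tile_ids, cols, drop = FALSE], na.rm = TRUE)
  })
  prof <- matrix(prof, ncol = 3,
                 dimnames = list(tile_ids, CELL_TYPES))
  prof[is.nan(prof)] <- NA_real_
  prof
}

#' Export DMR calls as BED6+ and TSV
#'
#' BED columns: chrom, start0, end0, tile_id, -10*log10(p_adj) capped score,
#' ".", then mean_a, mean_b, diff, direction, cluster (when present).
#'
#' @param calls DMR calls, optionally with a `cluster` column.
#' @param path Output path (`.bed` or `.tsv` written as given).
#' @export
export_dmr_bed <- function(calls, path) {
  dt <- as.data.table(calls)
  score <- pmin(1000, round(-10 * log10(pmax(dt$p_adj, 1e-300))))
  bed <- data.table(chrom = dt$chrom, start0 = dt$start0, end0 = dt$end0,
                    name = dt$tile_id, score = score, strand = ".",
                    mean_a = round(dt$mean_a, 6), mean_b = round(dt$mean_b, 6),
                    diff = round(dt$diff, 6), direction = dt$direction)
  if ("cluster" %in% names(dt)) bed[, cluster := dt$cluster]
  write_bed(bed, path)
}
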