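#' Pipeline configuration
#'
#' Collects paths and the analysis thresholds. Defaults are the study's
#' printed parameters: 500 bp tiles, methylation difference > 0.2,
#' adjusted p < 0.05, promoter TSS -1 kb/+1 kb, correlation threshold
#' -0.3; `min_shared_cpg` (3) and `deg_alpha` (0.05) are configurable.
#'
#' @param sample_sheet Path to the sample sheet TSV.
#' @param annotation Path to the GTF/GFF3 annotation.
#' @param counts Path to the expression counts TSV (genes x samples, first
#'   column `gene_id`); NULL skips the expression stages.
#' @param chrom_sizes Path to a chrom.sizes file; NULL infers sizes from
#'   the data (max position per chromosome, rounded up to a tile).
#' @param outdir Run directory for outputs.
#' @param tile_size,diff_threshold,alpha,min_shared_cpg,corr_threshold
#'   Analysis thresholds (see description).
#' @param deg_alpha,lfc_threshold Differential-expression thresholds.
#' @param promoter_up,promoter_down Promoter extents (bp).
#' @param seed Seed for the stochastic backends (k-means).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_sheet, annotation, outdir,
                            counts = NULL, chrom_sizes = NULL,
                            tile_size = 500L, diff_threshold = 0.2,
                            alpha = 0.05, min_shared_cpg = 3L,
                            corr_threshold = -0.3, min_meth_sd = 0.04,
                            deg_alpha = 0.05,
                            lfc_threshold = 1, promoter_up = 1000L,
                            promoter_down = 1000L, seed = 1L) {
  cfg <- as.list(environment())
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (diff_threshold <= 0 || diff_threshold >= 1)
    stop("diff_threshold must be in (0, 1)")
  if (corr_threshold <= -1 || corr_threshold >= 1)
    stop("corr_threshold must be in (-1, 1)")
  if (tile_size <= 0) stop("tile_size must be > 0")
  structure(cfg, class = "pipeline_config")
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full methylome analysis pipeline
#'
#' Stages: load samples; tile the genome and compute the tile matrix;
#' genome-wide levels and CpG category fractions; pairwise DMR calling for
#' the two consecutive sibling transitions (EC vs HEC, HEC vs HSPC) and
#' mutant-vs-sibling within each cell type; six-pattern clustering of the
#' transition DMR union on sibling profiles; feature annotation and
#' enrichment of each DMR set; expression normalization, per-cell-type
#' mutant-vs-sibling DEG screens, methylation/expression integration and
#' the stage-transition filter. Each stage writes its tables before the
#' next starts, so partial output survives a downstream failure. All
#' outputs are deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list of in-memory results; tables and the run manifest
#'   are written under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$sample_sheet))
    stop("sample sheet not found: ", config$sample_sheet)
  if (!file.exists(config$annotation))
    stop("annotation not found: ", config$annotation)
  if (!is.null(config$counts) && !file.exists(config$counts))
    stop("counts not found: ", config$counts)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$outdir, ...)

  stage_msg("load", "reading sample sheet %s", config$sample_sheet)
  sheet <- read_sample_sheet(config$sample_sheet)
  samples <- load_samples(sheet)
  stage_msg("load", "%d samples loaded", length(samples))

  if (is.null(config$chrom_sizes)) {
    all_rec <- rbindlist(lapply(samples, `[[`, "records"))
    sizes_dt <- all_rec[, .(size = max(pos0) + 2L), by = chrom]
    chrom_sizes <- stats::setNames(
      as.integer(ceiling(sizes_dt$size / config$tile_size) *
                   config$tile_size), sizes_dt$chrom)
  } else {
    chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  }

  stage_msg("tile", "tiling %d chromosome(s) at %d bp",
            length(chrom_sizes), config$tile_size)
  tiles <- make_tiles(chrom_sizes, config$tile_size)
  tm <- tile_matrix(samples, tiles)
  export_tile_tsv(tm, p("tile_levels.tsv"))

  glob <- global_methylation(tm)
  cat_fr <- t(vapply(samples, cpg_category_fractions, numeric(4)))
  global_tab <- data.table(sheet[, .(sample_id, cell_type, genotype,
                                     replicate)],
                           global_level = glob[sheet$sample_id],
                           cat_fr[sheet$sample_id, ])
  fwrite(global_tab, p("global_levels.tsv"), sep = "\t")
  stage_msg("global", "mean global level %.4f", mean(glob))

  ids_of <- function(ct, gt) sheet$sample_id[sheet$cell_type == ct &
                                               sheet$genotype == gt]
  comparisons <- list(
    EC_vs_HEC = list(a = ids_of("EC", "sibling"), b = ids_of("HEC", "sibling")),
    HEC_vs_HSPC = list(a = ids_of("HEC", "sibling"),
                       b = ids_of("HSPC", "sibling")),
    EC_mut_vs_sib = list(a = ids_of("EC", "sibling"), b = ids_of("EC", "mutant")),
    HEC_mut_vs_sib = list(a = ids_of("HEC", "sibling"),
                          b = ids_of("HEC", "mutant")),
    HSPC_mut_vs_sib = list(a = ids_of("HSPC", "sibling"),
                           b = ids_of("HSPC", "mutant")))
  comparisons <- Filter(function(x) length(x$a) >= 2 && length(x$b) >= 2,
                        comparisons)
  dmr_res <- list()
  for (nm in names(comparisons)) {
    cp <- comparisons[[nm]]
    res <- call_dmrs(samples, tiles, cp$a, cp$b,
                     min_shared_cpg = config$min_shared_cpg,
                     diff_threshold = config$diff_threshold,
                     alpha = config$alpha)
    dmr_res[[nm]] <- res
    fwrite(res$calls, p(sprintf("dmr_%s.tsv", nm)), sep = "\t")
    export_dmr_bed(res$calls, p(sprintf("dmr_%s.bed", nm)))
    ds <- dmr_direction_summary(res$calls)
    stage_msg("dmr", "%s: %d tested, %d DMRs (%d hyper / %d hypo)", nm,
              nrow(res$tested), nrow(res$calls), ds$n_hyper, ds$n_hypo)
  }

  cluster_tab <- NULL
  trans_names <- intersect(c("EC_vs_HEC", "HEC_vs_HSPC"), names(dmr_res))
  union_tiles <- unique(unlist(lapply(dmr_res[trans_names],
                                      function(r) r$calls$tile_id)))
  if (length(union_tiles)) {
    prof <- celltype_profiles(tm, union_tiles, genotype = "sibling")
    cluster_tab <- assign_six_clusters(prof, method = "rule")
    fwrite(cluster_tab, p("dmr_clusters.tsv"), sep = "\t")
    stage_msg("cluster", "%d transition DMRs in six patterns",
              length(union_tiles))
  }

  stage_msg("annotate", "reading %s", config$annotation)
  models <- read_gene_models(config$annotation)
  feats <- build_feature_sets(models, config$promoter_up,
                              config$promoter_down, chrom_sizes)
  annot <- list(); enrich <- list()
  for (nm in names(dmr_res)) {
    calls <- dmr_res[[nm]]$calls
    if (!nrow(calls)) next
    an <- annotate_dmrs(calls[, .(tile_id, chrom, start0, end0)], feats)
    annot[[nm]] <- an
    fwrite(an$distribution, p(sprintf("dmr_features_%s.tsv", nm)),
           sep = "\t")
    en <- region_set_enrichment(calls[, .(chrom, start0, end0)], feats,
                                dmr_res[[nm]]$tested[, .(chrom, start0, end0)])
    enrich[[nm]] <- en
    fwrite(en, p(sprintf("dmr_enrichment_%s.tsv", nm)), sep = "\t")
  }

  degs <- NULL; integration <- NULL; stage_genes <- NULL
  if (!is.null(config$counts)) {
    cts <- fread(config$counts)
    counts <- as.matrix(cts[, -1])
    rownames(counts) <- cts[[1]]
    counts <- counts[, sheet$sample_id, drop = FALSE]
    norm <- normalize_counts(counts)
    fwrite(data.table(sample_id = colnames(counts),
                      size_factor = norm$size_factors),
           p("size_factors.tsv"), sep = "\t")
    degs <- list()
    for (ct in intersect(CELL_TYPES, unique(sheet$cell_type))) {
      a <- ids_of(ct, "sibling"); b <- ids_of(ct, "mutant")
      if (length(a) < 2 || length(b) < 2) next
      dg <- call_degs(norm$normalized, a, b, deg_alpha = config$deg_alpha,
                      lfc_threshold = config$lfc_threshold)
      degs[[ct]] <- dg
      fwrite(dg, p(sprintf("deg_%s_mut_vs_sib.tsv", ct)), sep = "\t")
      stage_msg("deg", "%s: %d up, %d down of %d genes", ct,
                sum(dg$passes & dg$direction == "up"),
                sum(dg$passes & dg$direction == "down"), nrow(dg))
    }
    pm <- promoter_methylation_matrix(samples, models$genes,
                                      config$promoter_up,
                                      config$promoter_down, chrom_sizes)
    deg_union <- unique(unlist(lapply(degs, function(d)
      d$gene_id[d$passes])))
    int_genes <- if (length(deg_union)) deg_union else rownames(counts)
    integration <- integrate_methylation_expression(
      int_genes, pm, norm$normalized, sheet,
      corr_threshold = config$corr_threshold,
      min_meth_sd = config$min_meth_sd)
    fwrite(integration, p("integration.tsv"), sep = "\t")
    stage_msg("integrate", "%d of %d genes selected",
              sum(integration$selected), nrow(integration))
    stage_genes <- stage_transition_filter(
      integration$gene_id[integration$selected], pm,
      log2(norm$normalized + 1), sheet)
    fwrite(stage_genes, p("stage_transition_genes.tsv"), sep = "\t")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ehtmeth")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("sample_sheet", "annotation", "counts",
                                  "chrom_sizes", "outdir"))],
    n_samples = length(samples), n_tiles = nrow(tiles),
    comparisons = names(dmr_res))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(sheet = sheet, tiles = tiles, tile_matrix = tm,
                 global = global_tab, dmr = dmr_res,
                 clusters = cluster_tab, annotation = annot,
                 enrichment = enrich, degs = degs,
                 integration = integration, stage_genes = stage_genes,
                 outdir = config$outdir))
}

#' Human-readable summary of a pipeline run directory
#'
#' Re-derives every reported count from the run's written tables; gaps
#' (stages that did not run) are reported explicitly rather than failing.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return Character vector of summary lines (also printed).
#' @export
report_summary <- function(run_dir) {
  lines <- character()
  add <- function(...) lines <<- c(lines, sprintf(...))
  gp <- file.path(run_dir, "global_levels.tsv")
  if (file.exists(gp)) {
    g <- fread(gp)
    for (i in seq_len(nrow(g)))
      add("global level %s (%s/%s): %.4f", g$sample_id[i], g$cell_type[i],
          g$genotype[i], g$global_level[i])
  } else add("global levels: MISSING")
  for (f in list.files(run_dir, pattern = "^dmr_.*\\.tsv$")) {
    if (grepl("features|enrichment|clusters", f)) next
    d <- fread(file.path(run_dir, f))
    nhyp <- sum(d$direction == "hyper"); nhypo <- sum(d$direction == "hypo")
    n <- nrow(d)
    if (n > 0) {
      add("%s: %d DMRs (%.1f%% hyper / %.1f%% hypo)", f, n,
          100 * nhyp / n, 100 * nhypo / n)
    } else add("%s: 0 DMRs", f)
  }
  cp <- file.path(run_dir, "dmr_clusters.tsv")
  if (file.exists(cp)) {
    cl <- fread(cp)
    tab <- table(cl$cluster)
    add("cluster sizes: %s",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)),
              collapse = ", "))
  } else add("clusters: not computed")
  for (f in list.files(run_dir, pattern = "^deg_.*\\.tsv$")) {
    d <- fread(file.path(run_dir, f))
    add("%s: %d up, %d down of %d", f,
        sum(d$passes & d$direction == "up"),
        sum(d$passes & d$direction == "down"), nrow(d))
  }
  ip <- file.path(run_dir, "integration.tsv")
  if (file.exists(ip)) {
    it <- fread(ip)
    add("integration: %d of %d genes selected", sum(it$selected), nrow(it))
  } else add("integration: not computed")
  sp <- file.path(run_dir, "stage_transition_genes.tsv")
  if (file.exists(sp)) {
    st <- fread(sp)
    for (cn in grep("^passes_", names(st), value = TRUE))
      add("stage filter %s: %d genes", sub("passes_", "", cn),
          sum(st[[cn]], na.rm = TRUE))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
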