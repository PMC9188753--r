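#' Simulation configuration for the synthetic WGBS + RNA-seq study
#'
#' Defines the study conditions emulated by the generator: a 3 cell-type
#' (EC, HEC, HSPC) x 2 genotype (sibling, dnmt1 mutant) x `replicates`
#' design with a globally high-methylation genome (~0.8), planted
#' cell-type-specific DMR tiles in six canonical patterns, a genotype-wide
#' hypomethylation in the mutant, and promoter-methylation-coupled genes
#' whose negative methylation/expression coupling is present in siblings
#' and lost in mutants.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome (bp).
#' @param cpg_spacing_mean_bp Mean inter-CpG gap (geometric gaps).
#' @param coverage_mean Mean reads per CpG per sample (Poisson).
#' @param baseline_meth_mean Genome-wide mean latent methylation.
#' @param baseline_meth_concentration Beta concentration of per-tile base
#'   levels around the mean.
#' @param celltype_meth_sd SD of per-gene per-cell-type promoter
#'   methylation wobble (real cell-type variation, coherent across a
#'   promoter's tiles and shared across genotypes).
#' @param cpg_jitter_concentration Beta concentration of per-CpG levels
#'   around the tile's replicate latent.
#' @param replicate_noise_sd SD of per-replicate latent tile levels around
#'   the group level.
#' @param n_planted_dmrs_per_pattern Planted DMR tiles per canonical
#'   pattern (six patterns).
#' @param dmr_delta Methylation shift of planted DMRs / coupled promoters.
#' @param mutant_hypomethylation_shift Genotype-wide methylation loss in
#'   the mutant (subtracted, floored at 0).
#' @param mutant_dynamic_loss Additional loss at coupled promoter tiles in
#'   the mutant at stages where siblings gain methylation (failed de novo
#'   establishment plus passive loss at dynamic regions).
#' @param n_genes,n_coupled_genes Total and methylation-coupled gene counts.
#' @param coupling_slope Natural-log expression change per unit promoter
#'   methylation in siblings (negative).
#' @param dev_downregulation Methylation-independent developmental
#'   downregulation (natural log) of coupled genes across their transition,
#'   present in both genotypes.
#' @param celltype_expr_sd SD of per-gene per-cell-type expression effects
#'   (natural log) for uncoupled genes, shared across genotypes.
#' @param expr_base_meanlog,expr_base_sdlog Baseline log-expression
#'   distribution.
#' @param libsize_sdlog SD of per-sample log library-size factors.
#' @param nb_dispersion Negative-binomial dispersion of counts.
#' @param replicates_per_group Replicates per cell type x genotype.
#' @param tile_size Tile width used for planting (bp).
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length_bp = 1e6,
                       cpg_spacing_mean_bp = 100L,
                       coverage_mean = 30,
                       baseline_meth_mean = 0.8,
                       baseline_meth_concentration = 30,
                       celltype_meth_sd = 0.08,
                       cpg_jitter_concentration = 100,
                       replicate_noise_sd = 0.03,
                       n_planted_dmrs_per_pattern = 40L,
                       dmr_delta = 0.4,
                       mutant_hypomethylation_shift = 0.15,
                       mutant_dynamic_loss = 0.15,
                       n_genes = 2000L,
                       n_coupled_genes = 200L,
                       coupling_slope = -3,
                       dev_downregulation = 0.5,
                       celltype_expr_sd = 0.7,
                       expr_base_meanlog = log(300),
                       expr_base_sdlog = 1,
                       libsize_sdlog = 0.15,
                       nb_dispersion = 0.02,
                       replicates_per_group = 3L,
                       tile_size = 500L,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              cpg_spacing_mean_bp = as.numeric(cpg_spacing_mean_bp),
              coverage_mean = coverage_mean,
              baseline_meth_mean = baseline_meth_mean,
              baseline_meth_concentration = baseline_meth_concentration,
              celltype_meth_sd = celltype_meth_sd,
              cpg_jitter_concentration = cpg_jitter_concentration,
              replicate_noise_sd = replicate_noise_sd,
              n_planted_dmrs_per_pattern = as.integer(n_planted_dmrs_per_pattern),
              dmr_delta = dmr_delta,
              mutant_hypomethylation_shift = mutant_hypomethylation_shift,
              mutant_dynamic_loss = mutant_dynamic_loss,
              n_genes = as.integer(n_genes),
              n_coupled_genes = as.integer(n_coupled_genes),
              coupling_slope = coupling_slope,
              dev_downregulation = dev_downregulation,
              celltype_expr_sd = celltype_expr_sd,
              expr_base_meanlog = expr_base_meanlog,
              expr_base_sdlog = expr_base_sdlog,
              libsize_sdlog = libsize_sdlog,
              nb_dispersion = nb_dispersion,
              replicates_per_group = as.integer(replicates_per_group),
              tile_size = as.integer(tile_size),
              seed = as.integer(seed))
  with(cfg, {
    if (n_chromosomes < 1L) stop("n_chromosomes must be >= 1")
    if (chrom_length_bp < 10 * tile_size)
      stop("chrom_length_bp must be >= 10 * tile_size")
    if (cpg_spacing_mean_bp < 2) stop("cpg_spacing_mean_bp must be >= 2")
    if (coverage_mean <= 0) stop("coverage_mean must be > 0")
    for (f in c("baseline_meth_mean"))
      if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
    if (dmr_delta <= 0 || dmr_delta >= 1) stop("dmr_delta must be in (0,1)")
    if (mutant_hypomethylation_shift < 0 || mutant_hypomethylation_shift > 1)
      stop("mutant_hypomethylation_shift must be in [0, 1]")
    if (n_coupled_genes > n_genes) stop("n_coupled_genes > n_genes")
    if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
    if (replicates_per_group < 2L)
      stop("replicates_per_group must be >= 2")
  })
  structure(cfg, class = "sim_config")
}

# Beta draw parameterized by mean and concentration (shape1+shape2)
rbeta_mc <- function(n, mean, conc) {
  mean <- pmin(pmax(mean, 1e-3), 1 - 1e-3)
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

# Beta draw parameterized by mean and sd (concentration derived per element)
rbeta_ms <- function(n, mean, sd) {
  mean <- pmin(pmax(mean, 1e-3), 1 - 1e-3)
  v <- mean * (1 - mean)
  conc <- pmax(v / sd^2 - 1, 2)
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Simulate the synthetic genome
#'
#' Chromosome sizes, a CpG position map with geometric inter-CpG gaps, the
#' tile partition, and gene models (strand-aware TSS/TES, exons). Coupled
#' genes are placed so that their promoter tiles are pairwise disjoint and
#' not shared with other promoters, and planted DMR tiles avoid coupled
#' promoters, keeping ground-truth labels unambiguous.
#'
#' @param config A [sim_config()].
#' @return List with `chrom_sizes`, `cpgs` (data.table `chrom`, `pos0`),
#'   `tiles`, `genes` (with `coupled`, `transition`), `exons`, and
#'   `planted` (tile_id, pattern).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$chrom_length_bp
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_sizes <- stats::setNames(rep(as.integer(L), length(chroms)), chroms)

  cpgs <- rbindlist(lapply(chroms, function(ch) {
    n_max <- ceiling(2.5 * L / config$cpg_spacing_mean_bp) + 100L
    gaps <- 1L + stats::rgeom(n_max, 1 / config$cpg_spacing_mean_bp)
    pos <- cumsum(gaps)
    data.table(chrom = ch, pos0 = as.integer(pos[pos < L - 1]))
  }))
  tiles <- make_tiles(chrom_sizes, config$tile_size)

  ts <- config$tile_size
  prom_tiles <- function(ch, tss) {
    lo <- max(0L, tss - 1000L) %/% ts
    hi <- min(L - 1, tss + 999L) %/% ts
    sprintf("%s:%d-%d", ch, (lo:hi) * ts, pmin((lo:hi + 1) * ts, L))
  }

  reserved <- new.env(hash = TRUE)
  n_c <- config$n_coupled_genes
  transitions <- rep(c("EC_HEC", "HEC_HSPC"), length.out = n_c)
  place_gene <- function(avoid_reserved) {
    for (try in seq_len(5000L)) {
      ch <- sample(chroms, 1L)
      tss <- sample.int(as.integer(L) - 4000L, 1L) + 2000L
      pt <- prom_tiles(ch, tss)
      if (!avoid_reserved ||
          !any(vapply(pt, exists, TRUE, envir = reserved)))
        return(list(chrom = ch, tss = tss, tiles = pt))
    }
    stop("could not place gene; genome too small for the design")
  }
  coupled_rows <- vector("list", n_c)
  for (i in seq_len(n_c)) {
    g <- place_gene(avoid_reserved = TRUE)
    for (t in g$tiles) assign(t, TRUE, envir = reserved)
    coupled_rows[[i]] <- data.table(chrom = g$chrom, tss0 = g$tss,
                                    coupled = TRUE,
                                    transition = transitions[i])
  }
  n_u <- config$n_genes - n_c
  uncoupled_rows <- vector("list", n_u)
  for (i in seq_len(n_u)) {
    g <- place_gene(avoid_reserved = TRUE)
    uncoupled_rows[[i]] <- data.table(chrom = g$chrom, tss0 = g$tss,
                                      coupled = FALSE,
                                      transition = NA_character_)
  }
  genes <- rbindlist(c(coupled_rows, uncoupled_rows))
  genes[, gene_id := sprintf("g%04d", .I)]
  genes[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  genes[, gene_len := sample(1500:4000, .N, replace = TRUE)]
  genes[, `:=`(
    start0 = ifelse(strand == "+", tss0, pmax(0L, tss0 - gene_len + 1L)),
    end0 = ifelse(strand == "+", pmin(as.integer(L), tss0 + gene_len),
                  tss0 + 1L))]
  genes[, gene_len := NULL]
  genes[, tes0 := ifelse(strand == "+", end0 - 1L, start0)]
  setcolorder(genes, c("gene_id", "chrom", "strand", "start0", "end0",
                       "tss0", "tes0", "coupled", "transition"))

  # two exons per gene separated by one intron, inside the gene span
  exons <- genes[, {
    span <- end0 - start0
    e1 <- as.integer(round(span * 0.3))
    i1 <- as.integer(round(span * 0.4))
    rbind(data.table(chrom = chrom, start0 = start0, end0 = start0 + e1),
          data.table(chrom = chrom, start0 = start0 + e1 + i1, end0 = end0))
  }, by = gene_id]

  # planted six-pattern DMR tiles among unreserved full-width tiles
  patt <- rep(rownames(canonical_patterns()),
              each = config$n_planted_dmrs_per_pattern)
  free <- tiles[end0 - start0 == ts &
                  !vapply(tile_id, exists, TRUE, envir = reserved)]
  if (nrow(free) < length(patt))
    stop("not enough free tiles to plant DMRs")
  planted <- data.table(tile_id = sample(free$tile_id, length(patt)),
                        pattern = patt)

  list(chrom_sizes = chrom_sizes, cpgs = cpgs, tiles = tiles,
       genes = genes[], exons = exons[, .(gene_id, chrom, start0, end0)],
       planted = planted)
}

# Per-tile latent methylation level for each cell type x genotype group.
# Returns matrix tiles x 6 groups named "<genotype>.<cell_type>".
group_latent_levels <- function(genome, config) {
  tiles <- genome$tiles
  nt <- nrow(tiles)
  base <- rbeta_mc(nt, config$baseline_meth_mean,
                   config$baseline_meth_concentration)
  # cell-type wobble: genuine cell-type variation, shared across genotypes,
  # coherent at promoter-region scale (methylation varies regionally, not
  # tile by tile): one draw per gene, added to all its promoter tiles
  wob <- matrix(0, nt, 3L, dimnames = list(NULL, CELL_TYPES))
  if (nrow(genome$genes) && config$celltype_meth_sd > 0) {
    # variation along the EC -> HEC -> HSPC axis is predominantly a
    # per-gene monotone trend, plus a smaller non-monotone deviation
    ngn <- nrow(genome$genes)
    trend <- stats::rnorm(ngn, 0, config$celltype_meth_sd)
    gw <- outer(trend, c(-1, 0, 1)) +
      matrix(stats::rnorm(ngn * 3L, 0, config$celltype_meth_sd / 4),
             ngn, 3L)
    dimnames(gw) <- list(genome$genes$gene_id, CELL_TYPES)
    promg <- promoter_region(genome$genes, 1000L, 1000L,
                             genome$chrom_sizes)
    t2w <- copy(tiles); setkey(t2w, chrom, start0, end0)
    setkey(promg, chrom, start0, end0)
    ovw <- foverlaps(t2w, promg, type = "any", nomatch = NULL)
    # where promoter domains overlap, each tile belongs to the promoter
    # whose TSS is nearest (regional methylation has one owner)
    ovw <- merge(ovw[, .(tile_id, gene_id, i.start0, i.end0)],
                 genome$genes[, .(gene_id, tss0)], by = "gene_id")
    ovw[, dist := abs((i.start0 + i.end0) / 2 - tss0)]
    setorder(ovw, tile_id, dist, gene_id)
    owner <- ovw[!duplicated(tile_id)]
    wob[match(owner$tile_id, tiles$tile_id), ] <- gw[owner$gene_id, ]
  }
  delta <- config$dmr_delta
  # signed pattern shifts: hyper patterns add, hypo patterns subtract
  shift <- rbind(C1 = c(0, 0.5, 1), C2 = c(0, 0, 1), C3 = c(0, -1, 0),
                 C4 = c(0, 1, 0), C5 = c(-1, 0, 0), C6 = c(0, 0, -1)) * delta
  colnames(shift) <- CELL_TYPES

  sib <- matrix(base, nt, 3L, dimnames = list(tiles$tile_id, CELL_TYPES)) +
    wob
  # planted pattern tiles: mid-range base so both directions stay in (0,1)
  pi_idx <- match(genome$planted$tile_id, tiles$tile_id)
  pbase <- stats::runif(length(pi_idx), 0.45, 0.55)
  sib[pi_idx, ] <- pbase + wob[pi_idx, ] +
    shift[genome$planted$pattern, , drop = FALSE]

  # coupled promoters: low start, +delta from the transition's later stage
  mut <- sib - config$mutant_hypomethylation_shift
  cg <- genome$genes[coupled == TRUE]
  if (nrow(cg)) {
    prom <- promoter_region(cg, 1000L, 1000L, genome$chrom_sizes)
    setkey(prom, chrom, start0, end0)
    t2 <- copy(tiles); setkey(t2, chrom, start0, end0)
    ov <- foverlaps(t2, prom, type = "any", nomatch = NULL)
    ov <- merge(ov[, .(tile_id, gene_id)], cg[, .(gene_id, transition)],
                by = "gene_id")
    start_lev <- stats::runif(nrow(cg), 0.3, 0.4)
    names(start_lev) <- cg$gene_id
    gain <- function(tr) switch(tr, EC_HEC = c(0, 1, 1),
                                HEC_HSPC = c(0, 0, 1))
    for (k in seq_len(nrow(ov))) {
      ti <- match(ov$tile_id[k], tiles$tile_id)
      g <- gain(ov$transition[k])
      s0 <- start_lev[ov$gene_id[k]]
      # planted stage trajectories replace the wobble at coupled tiles:
      # the dynamic-region signal dominates regional cell-type variation
      sib[ti, ] <- s0 + g * config$dmr_delta
      # mutant: the gain fails and the region loses methylation instead
      mut[ti, ] <- s0 - g * config$mutant_dynamic_loss -
        config$mutant_hypomethylation_shift
    }
  }
  out <- cbind(sib, mut)
  colnames(out) <- c(paste0("sibling.", CELL_TYPES),
                     paste0("mutant.", CELL_TYPES))
  pmin(pmax(out, 0.001), 0.999)
}

#' Simulate the WGBS methylomes of the full design
#'
#' Per CpG and sample, the total read count is Poisson(`coverage_mean`)
#' split over the two strands and the methylated count is binomial with a
#' per-CpG probability drawn around the tile's per-replicate latent level.
#' Latent structure: per-tile base (beta around the baseline mean),
#' per-cell-type wobble shared across genotypes, planted six-pattern DMR
#' shifts, coupled-promoter stage trajectories (gain in sibling, loss in
#' mutant), and the genotype-wide mutant hypomethylation (floored at 0).
#'
#' @param genome From [simulate_genome()].
#' @param config The same [sim_config()].
#' @return List: `samples` (named list of `methylome_sample`), `sheet`
#'   (design metadata, `file` unset), `stranded` (per-sample records with
#'   plus-strand count split, for writing cytosine reports),
#'   `latent` (tiles x samples replicate latent levels), `group_latent`
#'   (tiles x 6 groups), `truth_global` (per-group true mean tile level).
#' @export
simulate_methylomes <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$coverage_mean <= 0) stop("coverage_mean must be > 0")
  set.seed(config$seed + 1L)
  gl <- group_latent_levels(genome, config)
  tiles <- genome$tiles
  reps <- config$replicates_per_group
  sheet <- CJ(genotype = GENOTYPES, cell_type = CELL_TYPES,
              replicate = seq_len(reps), sorted = FALSE)
  sheet[, sample_id := sprintf("%s_%s_%d",
                               ifelse(genotype == "sibling", "sib", "mut"),
                               cell_type, replicate)]
  setcolorder(sheet, c("sample_id", "cell_type", "genotype", "replicate"))

  cpg_tile <- assign_tiles(genome$cpgs[, .(chrom, pos0, meth = 0L,
                                           total = 0L)],
                           tiles)$tile_id
  tile_idx <- match(cpg_tile, tiles$tile_id)
  n_cpg <- nrow(genome$cpgs)
  nt <- nrow(tiles)

  latent <- matrix(NA_real_, nt, nrow(sheet),
                   dimnames = list(tiles$tile_id, sheet$sample_id))
  samples <- vector("list", nrow(sheet))
  stranded <- vector("list", nrow(sheet))
  names(samples) <- names(stranded) <- sheet$sample_id
  for (i in seq_len(nrow(sheet))) {
    grp <- paste0(sheet$genotype[i], ".", sheet$cell_type[i])
    lam <- rbeta_ms(nt, gl[, grp], config$replicate_noise_sd)
    latent[, i] <- lam
    pi_cpg <- rbeta_mc(n_cpg, lam[tile_idx],
                       config$cpg_jitter_concentration)
    tp <- stats::rpois(n_cpg, config$coverage_mean / 2)
    tm <- stats::rpois(n_cpg, config$coverage_mean / 2)
    mp <- stats::rbinom(n_cpg, tp, pi_cpg)
    mm <- stats::rbinom(n_cpg, tm, pi_cpg)
    rec <- data.table(chrom = genome$cpgs$chrom, pos0 = genome$cpgs$pos0,
                      meth = mp + mm, total = tp + tm,
                      plus_meth = mp, plus_total = tp)
    stranded[[i]] <- rec
    samples[[i]] <- methylome_sample(
      rec[, .(chrom, pos0, meth, total)],
      sample_id = sheet$sample_id[i], cell_type = sheet$cell_type[i],
      genotype = sheet$genotype[i], replicate = sheet$replicate[i])
  }
  truth_global <- data.table(group = colnames(gl),
                             true_level = colMeans(gl))
  list(samples = samples, sheet = sheet, stranded = stranded,
       latent = latent, group_latent = gl, truth_global = truth_global)
}

#' Simulate expression counts coupled to promoter methylation
#'
#' Coupled genes: sibling log-mean expression is
#' `base + dev(cell type) + coupling_slope * promoter latent methylation`;
#' in the mutant the coupling term is absent (slope 0) and only the
#' methylation-independent developmental component `dev` remains. Uncoupled
#' genes get per-cell-type expression effects shared across genotypes.
#' Counts are negative binomial with dispersion `nb_dispersion` and
#' per-sample library-size factors.
#'
#' @param genome From [simulate_genome()].
#' @param meth From [simulate_methylomes()].
#' @param config The same [sim_config()].
#' @return List: `counts` (genes x samples integer matrix), `truth_genes`
#'   (gene_id, coupled, transition, slope, promoter latent per sample mean
#'   columns omitted), `lib_factors`.
#' @export
simulate_expression <- function(genome, meth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  genes <- genome$genes
  sheet <- meth$sheet
  ng <- nrow(genes); ns <- nrow(sheet)

  # per-gene, per-sample latent promoter methylation: mean of the latent
  # levels of tiles overlapping the promoter window
  prom <- promoter_region(genes, 1000L, 1000L, genome$chrom_sizes)
  t2 <- copy(genome$tiles); setkey(t2, chrom, start0, end0)
  setkey(prom, chrom, start0, end0)
  ov <- foverlaps(t2, prom, type = "any", nomatch = NULL)[, .(gene_id, tile_id)]
  prom_lat <- matrix(NA_real_, ng, ns,
                     dimnames = list(genes$gene_id, sheet$sample_id))
  ti <- match(ov$tile_id, genome$tiles$tile_id)
  for (j in seq_len(ns)) {
    v <- rowsum(meth$latent[ti, j], ov$gene_id)
    n <- rowsum(rep(1, nrow(ov)), ov$gene_id)
    prom_lat[rownames(v), j] <- v / n
  }

  base <- stats::rnorm(ng, config$expr_base_meanlog, config$expr_base_sdlog)
  # same trend-plus-deviation structure as the promoter methylation wobble
  cell_eff <- outer(stats::rnorm(ng, 0, config$celltype_expr_sd),
                    c(-1, 0, 1)) +
    matrix(stats::rnorm(ng * 3L, 0, config$celltype_expr_sd / 4), ng, 3L)
  dimnames(cell_eff) <- list(genes$gene_id, CELL_TYPES)
  dev_shape <- rbind(EC_HEC = c(0, -1, -1), HEC_HSPC = c(0, 0, -1))
  colnames(dev_shape) <- CELL_TYPES
  lib <- exp(stats::rnorm(ns, 0, config$libsize_sdlog))
  names(lib) <- sheet$sample_id

  logmu <- matrix(base, ng, ns,
                  dimnames = list(genes$gene_id, sheet$sample_id))
  for (j in seq_len(ns)) {
    ct <- sheet$cell_type[j]
    is_c <- genes$coupled
    logmu[!is_c, j] <- logmu[!is_c, j] + cell_eff[!is_c, ct]
    if (any(is_c)) {
      dev <- config$dev_downregulation *
        dev_shape[cbind(genes$transition[is_c], ct)]
      logmu[is_c, j] <- logmu[is_c, j] + dev
      if (sheet$genotype[j] == "sibling") {
        logmu[is_c, j] <- logmu[is_c, j] +
          config$coupling_slope * prom_lat[is_c, j]
      }
    }
    logmu[, j] <- logmu[, j] + log(lib[j])
  }
  counts <- matrix(stats::rnbinom(ng * ns, mu = exp(logmu),
                                  size = 1 / config$nb_dispersion),
                   ng, ns, dimnames = dimnames(logmu))
  truth_genes <- genes[, .(gene_id, coupled, transition)]
  truth_genes[, slope := ifelse(coupled, config$coupling_slope, 0)]
  list(counts = counts, truth_genes = truth_genes[], lib_factors = lib,
       promoter_latent = prom_lat)
}

#' Run the whole generator and (optionally) write the study to disk
#'
#' Writes per-sample bismark-style CpG cytosine reports, a chrom.sizes
#' file, a GTF with gene/transcript/exon rows, the expression counts TSV,
#' the sample sheet TSV, and ground-truth sidecar TSVs (planted tiles,
#' per-group latent tile levels, coupled genes, true global levels). Data
#' files carry no truth; truth lives only in the sidecars.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created); NULL for in-memory only.
#' @return List: `genome`, `meth`, `expr`, `paths` (when written).
#' @export
simulate_study <- function(config, outdir = NULL) {
  genome <- simulate_genome(config)
  meth <- simulate_methylomes(genome, config)
  expr <- simulate_expression(genome, meth, config)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(outdir, ...)
    write_chrom_sizes(genome$chrom_sizes, p("chrom.sizes"))
    write_gtf(genome, p("genes.gtf"))
    for (id in names(meth$stranded))
      write_cytosine_report(meth$stranded[[id]],
                            p(sprintf("%s.CpG_report.txt", id)))
    sheet <- copy(meth$sheet)
    sheet[, file := sprintf("%s.CpG_report.txt", sample_id)]
    fwrite(sheet, p("sample_sheet.tsv"), sep = "\t")
    fwrite(data.table(gene_id = rownames(expr$counts), expr$counts),
           p("counts.tsv"), sep = "\t")
    fwrite(genome$planted, p("truth_planted_tiles.tsv"), sep = "\t")
    fwrite(data.table(tile_id = rownames(meth$group_latent),
                      round(meth$group_latent, 6)),
           p("truth_tile_latent.tsv"), sep = "\t")
    fwrite(expr$truth_genes, p("truth_genes.tsv"), sep = "\t")
    fwrite(meth$truth_global, p("truth_global.tsv"), sep = "\t")
    paths <- list(outdir = outdir, sheet = p("sample_sheet.tsv"),
                  gtf = p("genes.gtf"), counts = p("counts.tsv"),
                  chrom_sizes = p("chrom.sizes"))
  }
  list(genome = genome, meth = meth, expr = expr, paths = paths,
       config = config)
}

write_gtf <- function(genome, path) {
  g <- genome$genes
  ex <- genome$exons
  attr_g <- sprintf('gene_id "%s";', g$gene_id)
  attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                    g$gene_id, g$gene_id)
  rows_g <- data.table(g$chrom, "ehtmeth_sim", "gene", g$start0 + 1L,
                       g$end0, ".", g$strand, ".", attr_g)
  rows_t <- data.table(g$chrom, "ehtmeth_sim", "transcript", g$start0 + 1L,
                       g$end0, ".", g$strand, ".", attr_t)
  exm <- merge(ex, g[, .(gene_id, strand)], by = "gene_id")
  attr_e <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                    exm$gene_id, exm$gene_id)
  rows_e <- data.table(exm$chrom, "ehtmeth_sim", "exon", exm$start0 + 1L,
                       exm$end0, ".", exm$strand, ".", attr_e)
  out <- rbindlist(list(rows_g, rows_t, rows_e), use.names = FALSE)
  setnames(out, c("chrom", "src", "type", "start", "end", "score",
                  "strand", "frame", "attr"))
  setorder(out, chrom, start, type)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
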