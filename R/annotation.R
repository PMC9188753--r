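#' Read gene models from a GTF/GFF3 annotation
#'
#' Builds one gene-level model per gene from the outermost span of its
#' transcripts, with a strand-aware TSS/TES and merged exon intervals.
#' Internally 0-based half-open.
#'
#' @param path GTF or GFF3 file.
#' @param gene_id_attr Attribute holding the gene identifier
#'   (default `"gene_id"`; use `"ID"` for bare GFF3).
#' @return List with `genes` (data.table: `gene_id`, `chrom`, `strand`,
#'   `start0`, `end0`, `tss0`, `tes0`) and `exons` (data.table: `gene_id`,
#'   `chrom`, `start0`, `end0`).
#' @export
read_gene_models <- function(path, gene_id_attr = "gene_id") {
  if (!file.exists(path)) stop("annotation not found: ", path)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (!gene_id_attr %in% names(md))
    stop("annotation lacks attribute ", gene_id_attr)
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start0 = GenomicRanges::start(gr) - 1L,
                   end0 = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(md$type),
                   gene_id = as.character(md[[gene_id_attr]]))
  dt <- dt[!is.na(gene_id) & strand %in% c("+", "-")]
  if (!nrow(dt)) stop("no stranded gene features in ", path)
  genes <- dt[, .(chrom = chrom[1], strand = strand[1],
                  start0 = min(start0), end0 = max(end0)), by = gene_id]
  genes[, `:=`(tss0 = ifelse(strand == "+", start0, end0 - 1L),
               tes0 = ifelse(strand == "+", end0 - 1L, start0))]
  exons <- dt[type == "exon", .(gene_id, chrom, start0, end0)]
  if (!nrow(exons)) exons <- genes[, .(gene_id, chrom, start0, end0)]
  list(genes = genes[], exons = exons[])
}

#' Strand-aware promoter window of a gene
#'
#' The promoter is the window from `up` bp upstream to `down` bp downstream
#' of the TSS (defaults 1000/1000), oriented by strand and clipped at
#' chromosome bounds when sizes are supplied.
#'
#' @param genes data.table of gene models (`chrom`, `strand`, `tss0`).
#' @param up,down Upstream/downstream extents in bp.
#' @param chrom_sizes Optional named vector for clipping.
#' @return data.table `gene_id`, `chrom`, `start0`, `end0`.
#' @export
promoter_region <- function(genes, up = 1000L, down = 1000L,
                            chrom_sizes = NULL) {
  g <- as.data.table(genes)
  out <- g[, .(gene_id, chrom,
               start0 = ifelse(strand == "+", tss0 - up, tss0 - down),
               end0 = ifelse(strand == "+", tss0 + down, tss0 + up))]
  out[, start0 := pmax(0L, as.integer(start0))]
  if (!is.null(chrom_sizes)) {
    out[, end0 := pmin(as.integer(end0),
                       as.integer(chrom_sizes[chrom]))]
  }
  out[]
}

#' Gene body (TSS to TES) of each gene
#'
#' @param genes data.table of gene models.
#' @return data.table `gene_id`, `chrom`, `start0`, `end0`.
#' @export
gene_body_region <- function(genes) {
  g <- as.data.table(genes)
  g[, .(gene_id, chrom, start0, end0)]
}

merge_intervals <- function(dt) {
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    dt$chrom, IRanges::IRanges(dt$start0 + 1L, dt$end0)))
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr))
}

#' Build standard feature sets from gene models
#'
#' Returns merged, sorted 0-based half-open interval sets for `promoter`,
#' `exon`, `intron` (gene body minus exons) and `gene_body`. Intergenic
#' space is implicit: a region overlapping none of the sets is intergenic.
#' User-supplied BED feature sets (e.g. repeats, CpG islands) can be added
#' to the returned list by name.
#'
#' @param models List from [read_gene_models()].
#' @param up,down Promoter extents.
#' @param chrom_sizes Optional named vector for clipping.
#' @return Named list of data.tables (`chrom`, `start0`, `end0`).
#' @export
build_feature_sets <- function(models, up = 1000L, down = 1000L,
                               chrom_sizes = NULL) {
  prom <- promoter_region(models$genes, up, down, chrom_sizes)
  body <- gene_body_region(models$genes)
  ex <- models$exons
  body_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    body$chrom, IRanges::IRanges(body$start0 + 1L, body$end0)))
  ex_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start0 + 1L, ex$end0)))
  intron_gr <- GenomicRanges::setdiff(body_gr, ex_gr)
  to_dt <- function(gr) data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr))
  list(promoter = merge_intervals(prom),
       exon = to_dt(ex_gr),
       intron = to_dt(intron_gr),
       gene_body = to_dt(body_gr))
}

overlaps_any <- function(query, features) {
  # logical: does each query interval overlap >= 1 bp of the feature set
  if (!nrow(features)) return(rep(FALSE, nrow(query)))
  qgr <- GenomicRanges::GRanges(query$chrom,
                                IRanges::IRanges(query$start0 + 1L,
                                                 query$end0))
  fgr <- GenomicRanges::GRanges(features$chrom,
                                IRanges::IRanges(features$start0 + 1L,
                                                 features$end0))
  GenomicRanges::countOverlaps(qgr, fgr) > 0L
}

#' Annotate DMRs with a single genomic feature label
#'
#' A DMR overlapping at least 1 bp of a feature is assignable to it; a
#' single label is chosen by precedence (default
#' promoter > exon > intron > intergenic). DMRs overlapping none of the
#' feature sets are intergenic.
#'
#' @param regions data.table of regions (`chrom`, `start0`, `end0`, and a
#'   `tile_id`/`name` column carried through if present).
#' @param feature_sets Named list from [build_feature_sets()] (intergenic is
#'   implicit and must not be supplied).
#' @param precedence Character vector ordering the feature names.
#' @return List with `labels` (data.table region + `feature`) and
#'   `distribution` (data.table `feature`, `n`, `pct`; percentages sum
#'   to 100).
#' @export
annotate_dmrs <- function(regions, feature_sets,
                          precedence = c("promoter", "exon", "intron")) {
  if (!length(feature_sets) || !any(vapply(feature_sets, nrow, 1L) > 0))
    stop("empty feature universe")
  reg <- as.data.table(regions)
  precedence <- intersect(precedence, names(feature_sets))
  lab <- rep("intergenic", nrow(reg))
  assigned <- rep(FALSE, nrow(reg))
  for (f in precedence) {
    hit <- overlaps_any(reg, feature_sets[[f]]) & !assigned
    lab[hit] <- f
    assigned <- assigned | hit
  }
  reg[, feature := lab]
  lv <- c(precedence, "intergenic")
  dist <- reg[, .N, by = feature][
    data.table(feature = lv), on = "feature"][is.na(N), N := 0L]
  dist[, pct := 100 * N / max(1L, sum(N))]
  setnames(dist, "N", "n")
  list(labels = reg[], distribution = dist[])
}

#' Fisher-exact region-set enrichment
#'
#' Tests whether query regions overlap a feature set more often than the
#' rest of a universe of regions (typically all tested tiles), via the
#' one-sided (greater) Fisher exact test on the 2x2 table
#' query/background x overlap/no-overlap. When several feature sets are
#' given, p-values are Benjamini-Hochberg adjusted across them.
#'
#' @param query data.table of query regions (must be a subset of the
#'   universe in count: `nrow(query) <= nrow(universe)`).
#' @param feature_sets Named list of feature interval tables (a single
#'   data.table is treated as one set named `"feature"`).
#' @param universe data.table of universe regions (including the query).
#' @return data.table `feature`, `n_query_hit`, `n_query`, `n_bg_hit`,
#'   `n_bg`, `odds_ratio`, `p`, `q`.
#' @export
region_set_enrichment <- function(query, feature_sets, universe) {
  if (is.data.frame(feature_sets)) feature_sets <- list(feature = feature_sets)
  q <- as.data.table(query); u <- as.data.table(universe)
  if (nrow(u) < nrow(q)) stop("universe smaller than query")
  qid <- paste(q$chrom, q$start0, q$end0)
  uid <- paste(u$chrom, u$start0, u$end0)
  bg <- u[!(uid %in% qid)]
  rows <- rbindlist(lapply(names(feature_sets), function(f) {
    qa <- sum(overlaps_any(q, feature_sets[[f]]))
    ba <- sum(overlaps_any(bg, feature_sets[[f]]))
    nq <- nrow(q); nb <- nrow(bg)
    tab <- matrix(c(qa, nq - qa, ba, nb - ba), 2, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    or <- if (qa == nq && ba == nb) NA_real_  # feature covers everything
          else if ((nq - qa) == 0 || ba == 0) Inf
          else (qa / (nq - qa)) / (ba / (nb - ba))
    if (qa == 0) or <- 0
    data.table(feature = f, n_query_hit = qa, n_query = nq,
               n_bg_hit = ba, n_bg = nb, odds_ratio = or, p = p)
  }))
  rows[, q := bh_adjust(p)]
  rows[]
}
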