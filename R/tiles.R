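#' Partition chromosomes into consecutive fixed-width tiles
#'
#' The genome is divided into consecutive non-overlapping tiles of
#' `tile_size` bp (default 500); the final tile of each chromosome is kept
#' even when shorter, so tiles partition each chromosome exactly.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param tile_size Tile width in bp (default 500).
#' @return data.table with `tile_id`, `chrom`, `start0`, `end0`
#'   (0-based half-open).
#' @export
make_tiles <- function(chrom_sizes, tile_size = 500L) {
  tile_size <- as.integer(tile_size)
  if (is.na(tile_size) || tile_size <= 0L) stop("tile_size must be > 0")
  if (!length(chrom_sizes) || any(chrom_sizes <= 0))
    stop("chromosome sizes must be positive")
  tiles <- rbindlist(lapply(names(chrom_sizes), function(ch) {
    size <- as.integer(chrom_sizes[[ch]])
    start0 <- seq.int(0L, size - 1L, by = tile_size)
    data.table(chrom = ch, start0 = start0,
               end0 = pmin(start0 + tile_size, size))
  }))
  tiles[, tile_id := sprintf("%s:%d-%d", chrom, start0, end0)]
  setcolorder(tiles, c("tile_id", "chrom", "start0", "end0"))
  tiles[]
}

assign_tiles <- function(records, tiles, tile_size = NULL) {
  # map CpG pos0 to tile by join; tiles are regular except the last per chrom
  rec <- as.data.table(records)
  t2 <- copy(tiles)
  setkey(t2, chrom, start0, end0)
  rec[, `:=`(start0 = pos0, end0 = pos0 + 1L)]
  hit <- foverlaps(rec, t2, type = "within", nomatch = NA)
  hit[, `:=`(start0 = NULL, end0 = NULL, i.start0 = NULL, i.end0 = NULL)]
  hit[]
}

#' Tile methylation matrix from a set of samples
#'
#' For each tile and sample, pools methylated and total read counts over the
#' CpGs falling in the tile and computes the methylation level as
#' `pooled meth / pooled total` (missing when no read covers the tile).
#' `n_cpg_covered` counts CpGs with at least one read.
#'
#' @param samples List of `methylome_sample`.
#' @param tiles Tiles from [make_tiles()].
#' @return Object of class `tile_matrix`: list with `tiles`, `samples`
#'   (metadata data.table), and tile-by-sample matrices `level`, `meth`,
#'   `total`, `n_cpg`.
#' @export
tile_matrix <- function(samples, tiles) {
  if (!length(samples)) stop("no samples")
  ids <- vapply(samples, `[[`, "", "sample_id")
  nt <- nrow(tiles)
  mk <- function() matrix(0, nt, length(samples),
                          dimnames = list(tiles$tile_id, ids))
  meth <- mk(); total <- mk(); ncpg <- mk()
  for (j in seq_along(samples)) {
    rec <- assign_tiles(samples[[j]]$records, tiles)
    agg <- rec[!is.na(tile_id),
               .(meth = sum(meth), total = sum(total),
                 n_cpg = sum(total > 0L)), by = tile_id]
    idx <- match(agg$tile_id, tiles$tile_id)
    meth[idx, j] <- agg$meth
    total[idx, j] <- agg$total
    ncpg[idx, j] <- agg$n_cpg
  }
  level <- ifelse(total > 0, meth / total, NA_real_)
  meta <- data.table(
    sample_id = ids,
    cell_type = vapply(samples, `[[`, "", "cell_type"),
    genotype = vapply(samples, `[[`, "", "genotype"),
    replicate = vapply(samples, function(s) s$replicate, 1L))
  structure(list(tiles = tiles, samples = meta, level = level,
                 meth = meth, total = total, n_cpg = ncpg),
            class = "tile_matrix")
}

#' @export
print.tile_matrix <- function(x, ...) {
  cat(sprintf("<tile_matrix> %d tiles x %d samples (%.1f%% tiles covered)\n",
              nrow(x$level), ncol(x$level),
              100 * mean(rowSums(x$total) > 0)))
  invisible(x)
}

#' One sample's tile methylation levels
#'
#' Convenience wrapper around [tile_matrix()] for a single sample.
#'
#' @param sample A `methylome_sample`.
#' @param tiles Tiles from [make_tiles()].
#' @return data.table with `tile_id`, `meth`, `total`, `n_cpg_covered`,
#'   `level`.
#' @export
tile_methylation <- function(sample, tiles) {
  tm <- tile_matrix(list(sample), tiles)
  data.table(tile_id = tiles$tile_id, meth = tm$meth[, 1],
             total = tm$total[, 1], n_cpg_covered = tm$n_cpg[, 1],
             level = tm$level[, 1])
}

#' Genome-wide methylation level of a sample
#'
#' The unweighted mean of the non-missing tile methylation levels, which is
#' the tile-based summary used as the genome-wide 5mC level.
#'
#' @param tm A `tile_matrix`.
#' @param sample_id Sample to summarise; default all samples.
#' @return Named numeric vector of genome-wide levels.
#' @export
global_methylation <- function(tm, sample_id = NULL) {
  lev <- tm$level
  if (!is.null(sample_id)) {
    if (!all(sample_id %in% colnames(lev)))
      stop("unknown sample_id")
    lev <- lev[, sample_id, drop = FALSE]
  }
  out <- colMeans(lev, na.rm = TRUE)
  if (any(is.nan(out))) stop("sample with no covered tile")
  out
}

#' Per-CpG methylation category fractions
#'
#' Classifies every covered CpG (total > 0) of a sample by its methylation
#' level meth/total into: high (> 0.8), intermediate (>= 0.2 and < 0.8,
#' including exactly 0.8), low (> 0 and < 0.2), none (= 0). Fractions are
#' over covered CpGs and sum to 1.
#'
#' @param sample A `methylome_sample`, or a data.table of records with
#'   `meth` and `total`.
#' @return Named numeric vector over `high`, `intermediate`, `low`, `none`.
#' @export
cpg_category_fractions <- function(sample) {
  rec <- if (inherits(sample, "methylome_sample")) sample$records
         else as.data.table(sample)
  rec <- rec[rec$total > 0L]
  if (!nrow(rec)) stop("no covered CpG")
  lev <- rec$meth / rec$total
  cat_of <- ifelse(lev > 0.8, "high",
            ifelse(lev >= 0.2, "intermediate",
            ifelse(lev > 0, "low", "none")))
  counts <- table(factor(cat_of, levels = c("high", "intermediate",
                                            "low", "none")))
  stats::setNames(as.numeric(counts) / length(lev),
                  c("high", "intermediate", "low", "none"))
}

#' Export tile levels
#'
#' `export_tile_tsv()` writes a wide tile x sample TSV of levels;
#' `export_tile_bedgraph()` writes one sample's levels as bedGraph
#' (0-based half-open, missing tiles omitted).
#'
#' @param tm A `tile_matrix`.
#' @param path Output path.
#' @param sample_id Sample for the bedGraph export.
#' @export
export_tile_tsv <- function(tm, path) {
  wide <- data.table(tm$tiles[, .(tile_id, chrom, start0, end0)],
                     as.data.table(tm$level))
  fwrite(wide, path, sep = "\t")
  invisible(path)
}

#' @rdname export_tile_tsv
#' @export
export_tile_bedgraph <- function(tm, sample_id, path) {
  lev <- tm$level[, sample_id]
  keep <- !is.na(lev)
  fwrite(data.table(tm$tiles$chrom[keep], tm$tiles$start0[keep],
                    tm$tiles$end0[keep], round(lev[keep], 6)),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}
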