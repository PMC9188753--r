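#' @importFrom data.table data.table fread fwrite setkey setkeyv as.data.table
#'   rbindlist setorder setnames setcolorder copy foverlaps CJ setattr
#'   := .N .SD .I
NULL

CELL_TYPES <- c("EC", "HEC", "HSPC")
GENOTYPES <- c("sibling", "mutant")

#' Construct a methylome sample
#'
#' A lightweight container for one sample's CpG-level methylation calls plus
#' its design metadata. Records are kept 0-based (position of the C of the
#' CpG dyad on the plus strand), sorted and unique by `(chrom, pos0)`.
#'
#' @param records data.frame/data.table with columns `chrom`, `pos0`, `meth`,
#'   `total` (counts; `total >= meth >= 0`).
#' @param sample_id Unique sample identifier.
#' @param cell_type One of `"EC"`, `"HEC"`, `"HSPC"`.
#' @param genotype One of `"sibling"`, `"mutant"`.
#' @param replicate Positive integer replicate index.
#' @return An object of class `methylome_sample`.
#' @export
methylome_sample <- function(records, sample_id, cell_type, genotype,
                             replicate) {
  if (!nzchar(sample_id)) stop("sample_id must be non-empty")
  cell_type <- match.arg(cell_type, CELL_TYPES)
  genotype <- match.arg(genotype, GENOTYPES)
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) stop("replicate must be >= 1")
  rec <- as.data.table(records)[, .(chrom = as.character(chrom),
                                    pos0 = as.integer(pos0),
                                    meth = as.integer(meth),
                                    total = as.integer(total))]
  if (nrow(rec)) {
    if (any(rec$pos0 < 0L)) stop("pos0 must be >= 0")
    if (any(rec$meth < 0L) || any(rec$total < rec$meth))
      stop("counts must satisfy total >= meth >= 0")
    setorder(rec, chrom, pos0)
    if (anyDuplicated(rec, by = c("chrom", "pos0")))
      stop("duplicate (chrom, pos0) records")
  }
  structure(list(sample_id = sample_id, cell_type = cell_type,
                 genotype = genotype, replicate = replicate, records = rec),
            class = "methylome_sample")
}

#' @export
print.methylome_sample <- function(x, ...) {
  cat(sprintf("<methylome_sample> %s (%s, %s, rep %d): %d CpGs, %d covered\n",
              x$sample_id, x$cell_type, x$genotype, x$replicate,
              nrow(x$records), sum(x$records$total > 0L)))
  invisible(x)
}

#' Read a bismark-style CpG cytosine report
#'
#' Expects tab-separated columns: chrom, 1-based position, strand,
#' methylated count, unmethylated count, context, trinucleotide. Rows whose
#' context differs from `context` are dropped. Plus- and minus-strand calls
#' of the same CpG dyad are merged by summing counts onto the plus-strand C
#' position, which is converted to a 0-based coordinate.
#'
#' @param path Path to the report.
#' @param context Context to retain (default `"CG"`).
#' @return data.table with columns `chrom`, `pos0`, `meth`, `total`.
#' @export
read_cytosine_report <- function(path, context = "CG") {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.table(chrom = character(), pos0 = integer(),
                      meth = integer(), total = integer())
  if (file.size(path) == 0) {
    warning("empty cytosine report: ", path)
    return(empty)
  }
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = c(1, 3, 6, 7)))
  if (!nrow(dt)) {
    warning("empty cytosine report: ", path)
    return(empty)
  }
  if (ncol(dt) < 6L)
    stop("malformed cytosine report (expected >= 6 tab-separated columns): ",
         path)
  setnames(dt, 1:6, c("chrom", "pos", "strand", "meth", "unmeth", "context"))
  for (cl in c("pos", "meth", "unmeth"))
    if (!is.numeric(dt[[cl]]))
      dt[, (cl) := suppressWarnings(as.numeric(get(cl)))]
  bad <- which(is.na(dt$pos) | is.na(dt$meth) | is.na(dt$unmeth) |
                 !(dt$strand %in% c("+", "-")))
  if (length(bad))
    stop(sprintf("malformed row %d in %s", bad[1], path))
  ctx_keep <- context
  dt <- dt[dt$context == ctx_keep]
  if (!nrow(dt)) {
    warning("no rows with context ", context, " in ", path)
    return(empty)
  }
  if (any(dt$meth < 0) || any(dt$unmeth < 0))
    stop("negative counts in ", path)
  # plus-strand C at 1-based p -> pos0 = p - 1; minus-strand C at p sits on
  # the G of the dyad, whose plus-strand C is at p - 1 -> pos0 = p - 2
  dt[, pos0 := as.integer(ifelse(strand == "+", pos - 1, pos - 2))]
  if (any(dt$pos0 < 0L)) stop("minus-strand call at position 1 in ", path)
  out <- dt[, .(meth = sum(as.integer(meth)),
                total = sum(as.integer(meth) + as.integer(unmeth))),
            by = .(chrom = as.character(chrom), pos0)]
  setorder(out, chrom, pos0)
  out[]
}

#' Write a bismark-style CpG cytosine report
#'
#' Inverse of [read_cytosine_report()] for merged records: each CpG dyad is
#' written as two stranded rows (plus-strand C and minus-strand G) with the
#' counts split as given in `plus_meth`/`plus_total` if present, otherwise
#' all counts on the plus strand.
#'
#' @param records data.table with `chrom`, `pos0`, `meth`, `total` and
#'   optionally `plus_meth`, `plus_total` (counts attributed to the plus
#'   strand; the remainder goes to the minus strand).
#' @param path Output path.
#' @export
write_cytosine_report <- function(records, path) {
  rec <- as.data.table(records)
  if (!all(c("plus_meth", "plus_total") %in% names(rec))) {
    rec[, `:=`(plus_meth = meth, plus_total = total)]
  }
  plus <- rec[, .(chrom, pos = pos0 + 1L, strand = "+",
                  meth = plus_meth, unmeth = plus_total - plus_meth)]
  minus <- rec[, .(chrom, pos = pos0 + 2L, strand = "-",
                   meth = meth - plus_meth,
                   unmeth = (total - plus_total) - (meth - plus_meth))]
  out <- rbind(plus, minus)
  out[, `:=`(context = "CG", tri = "CGN")]
  setorder(out, chrom, pos)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Requires columns `sample_id`, `cell_type`, `genotype`, `replicate`,
#' `file`. Fails fast on duplicate sample ids, unknown cell types or
#' genotypes, and missing files, so that errors surface at load rather than
#' mid-pipeline.
#'
#' @param path Path to a TSV sample sheet.
#' @param check_files Verify that every `file` exists (default TRUE). Paths
#'   are resolved relative to the sheet's directory when not absolute.
#' @return data.table of sample metadata.
#' @export
read_sample_sheet <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- fread(path, sep = "\t", colClasses = list(character = "sample_id"))
  need <- c("sample_id", "cell_type", "genotype", "replicate", "file")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", dup[1])
  bad_ct <- which(!(sheet$cell_type %in% CELL_TYPES))
  if (length(bad_ct))
    stop(sprintf("unknown cell_type '%s' in row %d",
                 sheet$cell_type[bad_ct[1]], bad_ct[1]))
  bad_gt <- which(!(sheet$genotype %in% GENOTYPES))
  if (length(bad_gt))
    stop(sprintf("unknown genotype '%s' in row %d",
                 sheet$genotype[bad_gt[1]], bad_gt[1]))
  dir <- dirname(path)
  resolved <- ifelse(grepl("^(/|[A-Za-z]:)", sheet$file), sheet$file,
                     file.path(dir, sheet$file))
  if (check_files) {
    gone <- which(!file.exists(resolved))
    if (length(gone))
      stop("sample sheet lists missing file: ", sheet$file[gone[1]])
  }
  sheet[, file := resolved]
  sheet[]
}

#' Load every sample listed in a sample sheet
#'
#' @param sheet data.table from [read_sample_sheet()].
#' @return Named list of `methylome_sample`, in sheet order.
#' @export
load_samples <- function(sheet) {
  out <- lapply(seq_len(nrow(sheet)), function(i) {
    methylome_sample(read_cytosine_report(sheet$file[i]),
                     sample_id = sheet$sample_id[i],
                     cell_type = sheet$cell_type[i],
                     genotype = sheet$genotype[i],
                     replicate = sheet$replicate[i])
  })
  names(out) <- sheet$sample_id
  out
}

#' Write / read BED intervals (0-based half-open)
#'
#' @param regions data.frame with `chrom`, `start0`, `end0` and optionally
#'   `name`, `score`, `strand` plus extra columns (written in order).
#' @param path File path.
#' @return `read_bed()` returns a data.table with `chrom`, `start0`, `end0`
#'   and any further columns named `name`, `score`, `strand`, `V7`, ...
#' @export
write_bed <- function(regions, path) {
  reg <- as.data.table(regions)
  if (!all(c("chrom", "start0", "end0") %in% names(reg)))
    stop("regions need chrom, start0, end0")
  if (any(reg$end0 < reg$start0)) stop("end0 < start0")
  core <- c("chrom", "start0", "end0", "name", "score", "strand")
  cols <- c(intersect(core, names(reg)), setdiff(names(reg), core))
  fwrite(reg[, cols, with = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, header = FALSE, sep = "\t")
  nm <- c("chrom", "start0", "end0", "name", "score", "strand")
  setnames(dt, seq_len(min(ncol(dt), 6L)), nm[seq_len(min(ncol(dt), 6L))])
  dt[]
}

#' Write / read a chrom.sizes table (two-column TSV: chrom, length)
#'
#' @param sizes Named integer vector of chromosome lengths, or data.frame
#'   with `chrom` and `size`.
#' @param path File path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  if (is.data.frame(sizes)) {
    dt <- as.data.table(sizes)[, .(chrom, size)]
  } else {
    dt <- data.table(chrom = names(sizes), size = as.integer(sizes))
  }
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "size"))
  stats::setNames(as.integer(dt$size), dt$chrom)
}
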