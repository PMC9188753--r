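#' Read a clonal bisulfite-sequencing matrix
#'
#' TSV with one row per sequenced clone and one column per CpG position of
#' the amplicon; entries are 1 (methylated), 0 (unmethylated) or NA
#' (no call). An optional first column `clone` is used as rownames.
#'
#' @param path TSV path.
#' @return Integer matrix clones x CpGs with NA for missing calls.
#' @export
read_clone_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, sep = "\t")
  if ("clone" %in% names(dt)) {
    rn <- as.character(dt$clone)
    dt[, clone := NULL]
  } else rn <- as.character(seq_len(nrow(dt)))
  m <- as.matrix(dt)
  if (!nrow(m) || !ncol(m)) stop("clone matrix needs >= 1 clone and CpG")
  if (!all(m %in% c(0L, 1L, NA)))
    stop("clone matrix entries must be 0, 1 or NA")
  rownames(m) <- rn
  m
}

#' Amplicon methylation percentage from a clone matrix
#'
#' The percentage of methylated CpG sites over the total number of called
#' CpG sites across all sequenced clones:
#' `100 * methylated / (methylated + unmethylated)`, missing calls excluded
#' from both numerator and denominator.
#'
#' @param m Clones x CpGs matrix of 1/0/NA.
#' @return Percentage in \[0, 100\].
#' @export
clone_methylation_percentage <- function(m) {
  m <- as.matrix(m)
  called <- sum(!is.na(m))
  if (called == 0L) stop("all clone calls missing")
  100 * sum(m, na.rm = TRUE) / called
}

#' Per-CpG methylated fraction across clones
#'
#' Column-wise fraction of methylated calls over non-missing clones; the
#' numeric backbone of a lollipop diagram.
#'
#' @param m Clones x CpGs matrix of 1/0/NA.
#' @return Numeric vector, one fraction per CpG column (NaN when a column
#'   has no call).
#' @export
per_cpg_profile <- function(m) {
  m <- as.matrix(m)
  colMeans(m, na.rm = TRUE)
}
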