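suppressMessages(library(data.table))

# ---- fixture builders ------------------------------------------------------

rand_records <- function(n = 50, seed = 1, chroms = c("chrA", "chrB"),
                         max_pos = 5000L, max_cov = 40L) {
  set.seed(seed)
  dt <- data.table(chrom = sample(chroms, n, replace = TRUE),
                   pos0 = sample.int(max_pos, n))
  dt <- unique(dt, by = c("chrom", "pos0"))
  dt[, total := rpois(.N, max_cov / 2)]
  dt[, meth := rbinom(.N, total, runif(.N))]
  setorder(dt, chrom, pos0)
  dt[]
}

mk_sample <- function(records, id = "s1", ct = "EC", gt = "sibling",
                      rep = 1L) {
  methylome_sample(records, sample_id = id, cell_type = ct, genotype = gt,
                   replicate = rep)
}

# samples whose per-replicate tile levels are controlled exactly: one tile
# per chromosome, `ncpg` CpGs each with `cov` reads at level `lev`
level_sample <- function(levels_by_tile, id, ct, gt, rep, ncpg = 4L,
                         cov = 20L, tile_size = 500L) {
  rec <- rbindlist(lapply(seq_along(levels_by_tile), function(i) {
    data.table(chrom = names(levels_by_tile)[i],
               pos0 = seq(10L, by = 50L, length.out = ncpg),
               meth = as.integer(round(levels_by_tile[i] * cov)),
               total = cov)
  }))
  mk_sample(rec, id, ct, gt, rep)
}

# ---- independent brute-force oracles ---------------------------------------

brute_tile_levels <- function(records, tiles) {
  out <- rep(NA_real_, nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    m <- 0; tt <- 0
    for (j in seq_len(nrow(records))) {
      if (records$chrom[j] == tiles$chrom[i] &&
          records$pos0[j] >= tiles$start0[i] &&
          records$pos0[j] < tiles$end0[i]) {
        m <- m + records$meth[j]
        tt <- tt + records$total[j]
      }
    }
    if (tt > 0) out[i] <- m / tt
  }
  out
}

brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# one-sided (enrichment) hypergeometric tail by explicit summation
brute_hyper_p <- function(qa, nq, ba, nb) {
  white <- qa + ba          # universe regions overlapping the feature
  total <- nq + nb
  kmax <- min(nq, white)
  sum(vapply(qa:kmax, function(k)
    choose(white, k) * choose(total - white, nq - k) / choose(total, nq),
    1.0))
}

brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

brute_category <- function(meth, total) {
  out <- c(high = 0, intermediate = 0, low = 0, none = 0)
  n <- 0
  for (j in seq_along(meth)) {
    if (total[j] == 0) next
    n <- n + 1
    lv <- meth[j] / total[j]
    if (lv > 0.8) out["high"] <- out["high"] + 1
    else if (lv >= 0.2) out["intermediate"] <- out["intermediate"] + 1
    else if (lv > 0) out["low"] <- out["low"] + 1
    else out["none"] <- out["none"] + 1
  }
  out / n
}

brute_promoter_level <- function(records, start0, end0) {
  m <- 0; tt <- 0
  for (j in seq_len(nrow(records))) {
    if (records$pos0[j] >= start0 && records$pos0[j] < end0) {
      m <- m + records$meth[j]; tt <- tt + records$total[j]
    }
  }
  if (tt > 0) m / tt else NA_real_
}

brute_clone_pct <- function(m) {
  meth <- 0; called <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (!is.na(m[i, j])) {
      called <- called + 1
      meth <- meth + m[i, j]
    }
  }
  100 * meth / called
}

# vectors with an exact sample Pearson correlation r against x
with_exact_cor <- function(x, r, seed = 1) {
  set.seed(seed)
  z <- rnorm(length(x))
  z <- residuals(lm(z ~ x))
  xs <- (x - mean(x)) / sd(x)
  zs <- (z - mean(z)) / sd(z)
  r * xs + sqrt(1 - r^2) * zs
}
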