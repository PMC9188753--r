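test_that("median-of-ratios size factors behave on constructed matrices", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  nf <- normalize_counts(m)
  expect_equal(unname(nf$size_factors), c(1, 1))
  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(m2) <- paste0("g", 1:3)
  nf2 <- normalize_counts(m2)
  expect_equal(unname(nf2$size_factors[2] / nf2$size_factors[1]), 2)
  expect_equal(unname(nf2$normalized[, 1]), unname(nf2$normalized[, 2]))
  expect_error(normalize_counts(matrix(c(1, 2), 1)), ">= 2 genes")
  expect_error(normalize_counts(cbind(a = c(0, 0), b = c(1, 2))),
               "all-zero")
})

test_that("the DEG screen applies conjunctive thresholds", {
  set.seed(2)
  base <- rnbinom(300, mu = 200, size = 50) + 1
  # identical columns keep every size factor at exactly 1
  m <- matrix(rep(base, 6), ncol = 6,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:6)))
  # g1: flat; g2: 8-fold up; g3: ~1.87-fold (|lfc| = 0.9) made obvious
  m["g1", ] <- 100
  m["g2", ] <- c(50, 52, 48, 400, 410, 390)
  m["g3", ] <- c(999, 1000, 1001, round(1000 * 2^0.9) + c(-1, 0, 1))
  nf <- normalize_counts(m)
  dg <- call_degs(nf$normalized, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(dg[gene_id == "g1", log2fc], 0)
  expect_false(dg[gene_id == "g1", passes])
  expect_true(dg[gene_id == "g2", passes])
  expect_equal(dg[gene_id == "g2", direction], "up")
  g3 <- dg[gene_id == "g3"]
  expect_lt(g3$p_adj, 0.05)
  expect_false(g3$passes)          # |log2fc| < 1 despite tiny p
  expect_error(call_degs(nf$normalized, paste0("s", 1:3), paste0("s", 3:5)),
               "overlap")
})

test_that("the DEG screen is quiet under the null", {
  set.seed(8)
  m <- matrix(rnbinom(2000 * 6, mu = 150, size = 20), ncol = 6,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
  nf <- normalize_counts(m)
  dg <- call_degs(nf$normalized, paste0("s", 1:3), paste0("s", 4:6))
  expect_lt(mean(dg$passes), 0.01)
})

test_that("promoter methylation pools counts inside the window", {
  g <- data.table(gene_id = "g1", chrom = "c1", strand = "+",
                  tss0 = 2000L)
  rec <- data.table(chrom = "c1", pos0 = c(1500L, 2500L, 5000L),
                    meth = c(2L, 2L, 9L), total = c(4L, 4L, 9L))
  pl <- promoter_methylation_per_gene(rec, g)
  expect_equal(pl$level, 0.5)
  g2 <- data.table(gene_id = "g2", chrom = "c1", strand = "+",
                   tss0 = 8000L)
  expect_true(is.na(promoter_methylation_per_gene(rec, g2)$level))
  # random fixtures vs a brute-force window scan
  for (seed in 1:5) {
    rr <- rand_records(150, seed = seed + 80, chroms = "c1",
                       max_pos = 20000L)
    gg <- data.table(gene_id = sprintf("g%d", 1:6), chrom = "c1",
                     strand = rep(c("+", "-"), 3),
                     tss0 = as.integer(seq(2000, 18000, length.out = 6)))
    got <- promoter_methylation_per_gene(rr, gg)
    for (i in seq_len(nrow(gg))) {
      expect_equal(got$level[got$gene_id == gg$gene_id[i]],
                   brute_promoter_level(rr[total > 0], gg$tss0[i] - 1000L,
                                        gg$tss0[i] + 1000L))
    }
  }
})

test_that("pearson correlation matches the direct formula and its edge cases", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(-1, -2, -3)), -1)
  expect_true(is.na(pearson_correlation(c(1, 2, 3), c(2, 2, 2))))
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
  set.seed(13)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson_correlation(x, y), brute_pearson(x, y),
                 tolerance = 1e-12)
    # symmetry and affine invariance
    expect_equal(pearson_correlation(x, y), pearson_correlation(y, x))
    expect_equal(pearson_correlation(2 * x + 5, y),
                 pearson_correlation(x, y))
    expect_lte(abs(pearson_correlation(x, y)), 1)
  }
})

integration_fixture <- function(rs, rm, seed = 1) {
  # one gene whose sibling/mutant correlations are exactly rs and rm
  sheet <- data.table(
    sample_id = c(paste0("sib", 1:9), paste0("mut", 1:9)),
    cell_type = rep(rep(c("EC", "HEC", "HSPC"), each = 3), 2),
    genotype = rep(c("sibling", "mutant"), each = 9),
    replicate = rep(1:3, 6))
  set.seed(seed)
  meth <- c(rnorm(9, 0.5, 0.1), rnorm(9, 0.4, 0.1))
  expr_log <- c(with_exact_cor(meth[1:9], rs, seed),
                with_exact_cor(meth[10:18], rm, seed + 1))
  expr <- matrix(2^(expr_log + 6) - 1, nrow = 1,
                 dimnames = list("g1", sheet$sample_id))
  pm <- matrix(meth, nrow = 1, dimnames = list("g1", sheet$sample_id))
  list(sheet = sheet, pm = pm, expr = expr)
}

test_that("integration selects sibling-specific negative correlations", {
  fx <- integration_fixture(-0.5, -0.1)
  it <- integrate_methylation_expression("g1", fx$pm, fx$expr, fx$sheet)
  expect_equal(it$corr_sibling, -0.5, tolerance = 1e-10)
  expect_equal(it$corr_mutant, -0.1, tolerance = 1e-10)
  expect_true(it$selected)
  # corr_sibling above the threshold is never selected
  fx2 <- integration_fixture(-0.2, -0.9)
  expect_false(integrate_methylation_expression("g1", fx2$pm, fx2$expr,
                                                fx2$sheet)$selected)
  # both negative: coupling not sibling-specific
  fx3 <- integration_fixture(-0.6, -0.6)
  expect_false(integrate_methylation_expression("g1", fx3$pm, fx3$expr,
                                                fx3$sheet)$selected)
})

test_that("integration selection is monotone in the sibling correlation", {
  sel <- vapply(seq(-0.05, -0.95, by = -0.1), function(rs) {
    fx <- integration_fixture(rs, 0.1, seed = 3)
    integrate_methylation_expression("g1", fx$pm, fx$expr, fx$sheet)$selected
  }, TRUE)
  # once selected while corr_sibling decreases, it stays selected
  expect_true(all(diff(as.integer(sel)) >= 0))
  expect_true(any(sel) && !all(sel))
})

test_that("near-constant promoter methylation is excluded as uninformative", {
  fx <- integration_fixture(-0.9, 0, seed = 5)
  fx$pm[1, 1:9] <- 0.5 + seq(-0.01, 0.01, length.out = 9)  # sd ~ 0.007
  it <- integrate_methylation_expression("g1", fx$pm, fx$expr, fx$sheet)
  expect_true(is.na(it$corr_sibling))
  expect_false(it$selected)
  expect_equal(attr(it, "n_excluded"), 1L)
})

test_that("the stage filter requires sibling-specific meth-up/expr-down", {
  sheet <- data.table(
    sample_id = sprintf("s%02d", 1:18),
    cell_type = rep(rep(c("EC", "HEC", "HSPC"), each = 3), 2),
    genotype = rep(c("sibling", "mutant"), each = 9),
    replicate = rep(1:3, 6))
  mkmat <- function(sib_by_ct, mut_by_ct) {
    v <- c(rep(sib_by_ct, each = 3), rep(mut_by_ct, each = 3))
    matrix(v, nrow = 1, dimnames = list("g1", sheet$sample_id))
  }
  # sibling: meth 0.5 -> 0.7 and expr 100 -> 40; mutant flat
  pm <- mkmat(c(0.5, 0.7, 0.7), c(0.5, 0.5, 0.5))
  ex <- mkmat(c(100, 40, 40), c(100, 100, 100))
  st <- stage_transition_filter("g1", pm, ex, sheet)
  expect_true(st$passes_EC_HEC)
  expect_false(st$passes_HEC_HSPC)   # no sibling change at that step
  # sibling methylation decreasing fails
  pm2 <- mkmat(c(0.7, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_false(stage_transition_filter("g1", pm2, ex, sheet)$passes_EC_HEC)
  # mutant mirroring the sibling change fails the "not in mutant" clause
  pm3 <- mkmat(c(0.5, 0.7, 0.7), c(0.4, 0.6, 0.6))
  ex3 <- mkmat(c(100, 40, 40), c(100, 40, 40))
  expect_false(stage_transition_filter("g1", pm3, ex3, sheet)$passes_EC_HEC)
})
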