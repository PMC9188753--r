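test_that("pooled Student's t matches the textbook formula and t.test", {
  a <- c(0.1, 0.2, 0.15); b <- c(0.8, 0.9, 0.85)
  r <- student_t_two_sample(a, b)
  # independent evaluation of the pooled-variance formula
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(b) - mean(a)) / sqrt(sp2 * (2 / 3))
  expect_equal(r$t, t_hand)
  expect_equal(r$p, 2 * pt(-abs(t_hand), 4))
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(r$p, tt$p.value)
  expect_equal(unname(r$t), unname(tt$statistic))
})

test_that("t-test degenerate cases follow the stated conventions", {
  r <- student_t_two_sample(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  # both groups zero variance
  expect_equal(student_t_two_sample(c(0.4, 0.4), c(0.4, 0.4))$p, 1)
  expect_equal(student_t_two_sample(c(0.4, 0.4), c(0.6, 0.6))$p, 0)
  expect_error(student_t_two_sample(0.5, c(0.4, 0.5)), ">= 2")
  # swapping groups flips t, keeps p
  a <- c(0.2, 0.3, 0.25); b <- c(0.5, 0.45, 0.6)
  r1 <- student_t_two_sample(a, b); r2 <- student_t_two_sample(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
})

# six samples, three tiles on chromosomes c1..c3 with controlled levels
dmr_fixture <- function(lev_a, lev_b, ncpg = 4L, cov = 50L) {
  stopifnot(length(lev_a) == length(lev_b))
  names(lev_a) <- names(lev_b) <- paste0("c", seq_along(lev_a))
  eps <- c(0, 0.02, -0.02)  # deterministic replicate scatter
  samples <- c(
    lapply(1:3, function(r) level_sample(pmin(lev_a + eps[r], 1),
                                         paste0("a", r), "EC", "sibling", r,
                                         ncpg, cov)),
    lapply(1:3, function(r) level_sample(pmin(lev_b + eps[r], 1),
                                         paste0("b", r), "HEC", "sibling", r,
                                         ncpg, cov)))
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  samples
}

test_that("DMR calling applies the conjunctive difference and FDR filters", {
  sizes <- setNames(rep(500L, 3), paste0("c", 1:3))
  tiles <- make_tiles(sizes)
  # tile 1: big real difference; tile 2: small difference, tiny p;
  # tile 3: no difference
  samples <- dmr_fixture(c(0.30, 0.50, 0.70), c(0.80, 0.58, 0.70))
  res <- call_dmrs(samples, tiles, paste0("a", 1:3), paste0("b", 1:3))
  expect_equal(res$calls$tile_id, "c1:0-500")
  expect_equal(res$calls$direction, "hyper")
  expect_equal(nrow(res$tested), 3L)
  c2 <- res$tested[tile_id == "c2:0-500"]
  expect_lt(c2$p_adj, 0.05)        # significant ...
  expect_lt(abs(c2$diff), 0.2)     # ... but fails the effect-size filter
})

test_that("direction labels are antisymmetric under group swap", {
  sizes <- setNames(rep(500L, 3), paste0("c", 1:3))
  tiles <- make_tiles(sizes)
  samples <- dmr_fixture(c(0.2, 0.9, 0.5), c(0.7, 0.3, 0.5))
  r1 <- call_dmrs(samples, tiles, paste0("a", 1:3), paste0("b", 1:3))
  r2 <- call_dmrs(samples, tiles, paste0("b", 1:3), paste0("a", 1:3))
  expect_equal(sort(r1$calls$tile_id), sort(r2$calls$tile_id))
  m <- merge(r1$calls[, .(tile_id, d1 = direction)],
             r2$calls[, .(tile_id, d2 = direction)], by = "tile_id")
  expect_true(all(m$d1 != m$d2))
  expect_equal(r1$tested$p_raw, r2$tested$p_raw)
})

test_that("only CpG sites recovered by both groups enter the pooled counts", {
  tiles <- make_tiles(c(c1 = 500L))
  mk <- function(id, ct, rep, meth1, tot1, meth2, tot2) {
    mk_sample(data.table(chrom = "c1", pos0 = c(10L, 60L, 110L),
                         meth = c(meth1, meth2, 5L),
                         total = c(tot1, tot2, 10L)),
              id, ct, "sibling", rep)
  }
  # CpG at 60 has zero coverage in one group-b sample -> dropped everywhere
  samples <- list(
    a1 = mk("a1", "EC", 1, 10L, 10L, 0L, 10L),
    a2 = mk("a2", "EC", 2, 10L, 10L, 0L, 10L),
    b1 = mk("b1", "HEC", 1, 0L, 10L, 10L, 10L),
    b2 = mk("b2", "HEC", 2, 0L, 10L, 0L, 0L))
  res <- call_dmrs(samples, tiles, c("a1", "a2"), c("b1", "b2"),
                   min_shared_cpg = 2L)
  expect_equal(res$tested$n_shared_cpg, 2L)
  # shared sites are 10 and 110: group a level (10+5)/20, group b (0+5)/20
  expect_equal(res$tested$mean_a, 15 / 20)
  expect_equal(res$tested$mean_b, 5 / 20)
  # raising min_shared_cpg above the shared count leaves the tile untested
  res3 <- call_dmrs(samples, tiles, c("a1", "a2"), c("b1", "b2"),
                    min_shared_cpg = 3L)
  expect_equal(nrow(res3$tested), 0L)
})

test_that("call_dmrs validates its groups", {
  tiles <- make_tiles(c(c1 = 500L))
  samples <- dmr_fixture(0.5, 0.5)
  expect_error(call_dmrs(samples, tiles, character(), "b1"), "empty group")
  expect_error(call_dmrs(samples, tiles, c("a1", "a2"), c("a2", "b1")),
               "disjoint")
  expect_error(call_dmrs(samples, tiles, paste0("a", 1:3), paste0("b", 1:3),
                         alpha = 1.5), "alpha")
})

test_that("direction summaries report counts and percentages", {
  calls <- data.table(direction = c("hyper", "hyper", "hyper", "hypo"))
  s <- dmr_direction_summary(calls)
  expect_equal(s$n_hyper, 3L); expect_equal(s$n_hypo, 1L)
  expect_equal(s$pct_hyper, 75); expect_equal(s$pct_hypo, 25)
  s0 <- dmr_direction_summary(data.table(direction = character()))
  expect_equal(s0$n_hyper + s0$n_hypo, 0L)
  expect_true(is.na(s0$pct_hyper))
})

test_that("canonical profiles get their six distinct labels", {
  prof <- canonical_patterns() * 0.4 + 0.3
  rownames(prof) <- paste0("t", 1:6)
  a <- assign_six_clusters(prof)
  expect_equal(a$cluster, paste0("C", 1:6))
  expect_equal(length(unique(a$cluster)), 6L)
  # the two quoted examples
  ex <- rbind(x = c(EC = 0.2, HEC = 0.8, HSPC = 0.8),
              y = c(0.8, 0.2, 0.8))
  ae <- assign_six_clusters(ex)
  expect_equal(ae$cluster, c("C5", "C3"))
  expect_equal(ae$pattern, c("EC-specific-hypo", "HEC-specific-hypo"))
})

test_that("cluster assignment is invariant to row order and flags gaps", {
  set.seed(3)
  prof <- canonical_patterns()[sample(1:6, 40, replace = TRUE), ] * 0.4 +
    0.3 + matrix(rnorm(120, 0, 0.02), 40)
  rownames(prof) <- sprintf("t%02d", 1:40)
  a1 <- assign_six_clusters(prof)
  perm <- sample(1:40)
  a2 <- assign_six_clusters(prof[perm, ])
  expect_equal(a1$cluster[perm], a2$cluster)
  withna <- rbind(prof, tNA = c(0.5, NA, 0.7))
  a3 <- assign_six_clusters(withna)
  expect_true(is.na(a3[tile_id == "tNA", cluster]))
  expect_equal(attr(a3, "unassigned"), 1L)
})

test_that("the k-means backend reproduces the rule labels on separated data", {
  set.seed(11)
  idx <- rep(1:6, each = 30)
  prof <- canonical_patterns()[idx, ] * 0.4 + 0.3 +
    matrix(rnorm(180 * 3, 0, 0.02), 180)
  rownames(prof) <- sprintf("t%03d", 1:180)
  ar <- assign_six_clusters(prof, method = "rule")
  ak <- assign_six_clusters(prof, method = "kmeans", seed = 4)
  expect_gt(mean(ar$cluster == ak$cluster), 0.95)
  expect_equal(ar$cluster, paste0("C", idx))
})
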