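genes_fixture <- function() {
  data.table(gene_id = c("gp", "gm", "ge"),
             chrom = c("c1", "c1", "c2"),
             strand = c("+", "-", "+"),
             start0 = c(5000L, 2000L, 100L),
             end0 = c(8000L, 5001L, 2100L),
             tss0 = c(5000L, 5000L, 100L),
             tes0 = c(7999L, 2000L, 2099L))
}

test_that("promoter windows are strand-aware and clipped", {
  g <- genes_fixture()
  prom <- promoter_region(g)
  expect_equal(prom[gene_id == "gp", .(start0, end0)],
               data.table(start0 = 4000L, end0 = 6000L))
  # minus strand, same TSS coordinate: mirrored roles, same window here
  expect_equal(prom[gene_id == "gm", .(start0, end0)],
               data.table(start0 = 4000L, end0 = 6000L))
  # clipping at the chromosome start and end
  promc <- promoter_region(g, chrom_sizes = c(c1 = 10000L, c2 = 10000L))
  expect_equal(promc[gene_id == "ge", .(start0, end0)],
               data.table(start0 = 0L, end0 = 1100L))
  # asymmetric extents expose the strand orientation
  p2 <- promoter_region(g, up = 500L, down = 100L)
  expect_equal(p2[gene_id == "gp", .(start0, end0)],
               data.table(start0 = 4500L, end0 = 5100L))
  expect_equal(p2[gene_id == "gm", .(start0, end0)],
               data.table(start0 = 4900L, end0 = 5500L))
  # windows have length up + down away from edges
  expect_true(all((prom$end0 - prom$start0)[prom$gene_id != "ge"] == 2000L))
})

test_that("gene models are read from a GTF with strand-aware TSS", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'c1\tsrc\tgene\t101\t400\t.\t+\t.\tgene_id "gA";',
    'c1\tsrc\texon\t101\t180\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'c1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'c1\tsrc\tgene\t601\t900\t.\t-\t.\tgene_id "gB";',
    'c1\tsrc\texon\t601\t900\t.\t-\t.\tgene_id "gB"; transcript_id "gB.t1";'),
    f)
  m <- read_gene_models(f)
  gA <- m$genes[gene_id == "gA"]
  expect_equal(gA$start0, 100L); expect_equal(gA$end0, 400L)
  expect_equal(gA$tss0, 100L); expect_equal(gA$tes0, 399L)
  gB <- m$genes[gene_id == "gB"]
  expect_equal(gB$tss0, 899L); expect_equal(gB$tes0, 600L)
  expect_equal(nrow(m$exons[gene_id == "gA"]), 2L)
})

test_that("DMR feature labels follow the precedence rule", {
  feats <- list(
    promoter = data.table(chrom = "c1", start0 = 1000L, end0 = 2000L),
    exon = data.table(chrom = "c1", start0 = c(1500L, 3000L),
                      end0 = c(2500L, 3500L)),
    intron = data.table(chrom = "c1", start0 = 3500L, end0 = 5000L))
  reg <- data.table(tile_id = c("in_both", "in_exon", "in_intron", "nowhere"),
                    chrom = "c1",
                    start0 = c(1600L, 2400L, 4000L, 9000L),
                    end0 = c(1700L, 2600L, 4100L, 9100L))
  an <- annotate_dmrs(reg, feats)
  expect_equal(an$labels$feature,
               c("promoter", "exon", "intron", "intergenic"))
  expect_equal(sum(an$distribution$pct), 100)
  expect_error(annotate_dmrs(reg, list(promoter = feats$promoter[0])),
               "empty feature universe")
})

test_that("feature labels match a brute-force interval scan", {
  set.seed(21)
  for (rep in 1:10) {
    feats <- lapply(setNames(nm = c("promoter", "exon", "intron")),
                    function(nm) {
                      s <- sort(sample.int(10000L, 6))
                      data.table(chrom = "c1", start0 = s[c(1, 3, 5)],
                                 end0 = s[c(2, 4, 6)])
                    })
    s <- sample.int(9900L, 30)
    reg <- data.table(tile_id = sprintf("r%02d", 1:30), chrom = "c1",
                      start0 = s, end0 = s + sample.int(100L, 30))
    got <- annotate_dmrs(reg, feats)$labels$feature
    brute <- vapply(seq_len(nrow(reg)), function(i) {
      for (f in c("promoter", "exon", "intron")) {
        fs <- feats[[f]]
        for (j in seq_len(nrow(fs))) {
          if (reg$start0[i] < fs$end0[j] && fs$start0[j] < reg$end0[i])
            return(f)
        }
      }
      "intergenic"
    }, "")
    expect_equal(got, brute)
    # invariance to interval input order within each feature set
    feats_sh <- lapply(feats, function(d) d[sample(.N)])
    expect_equal(annotate_dmrs(reg, feats_sh)$labels$feature, got)
  }
})

test_that("enrichment p equals the hypergeometric tail", {
  # 10 of 15 query regions overlap; 20 of 220 background regions overlap
  universe <- data.table(chrom = "c1",
                         start0 = seq(0L, by = 1000L, length.out = 235L))
  universe[, end0 := start0 + 500L]
  query <- universe[1:15]
  hit <- rbind(query[1:10], universe[16:35])
  feat <- hit[, .(chrom, start0, end0)]
  en <- region_set_enrichment(query, list(f = feat), universe)
  expect_equal(en$n_query_hit, 10L); expect_equal(en$n_bg_hit, 20L)
  expect_equal(en$p, brute_hyper_p(10, 15, 20, 220), tolerance = 1e-12)
  expect_equal(en$odds_ratio, (10 / 5) / (20 / 200))
})

test_that("enrichment degenerate cases are guarded", {
  universe <- data.table(chrom = "c1",
                         start0 = seq(0L, by = 1000L, length.out = 50L))
  universe[, end0 := start0 + 500L]
  query <- universe[1:10]
  # feature covering the whole universe
  whole <- data.table(chrom = "c1", start0 = 0L, end0 = 100000L)
  en <- region_set_enrichment(query, list(all = whole), universe)
  expect_equal(en$p, 1)
  expect_true(is.na(en$odds_ratio))
  expect_error(region_set_enrichment(universe, list(f = whole), query),
               "universe smaller")
  # null construction: a uniformly drawn query is unenriched
  set.seed(5)
  feat <- universe[sample(50, 25), .(chrom, start0, end0)]
  ps <- replicate(20, {
    q <- universe[sample(50, 10)]
    region_set_enrichment(q, list(f = feat), universe)$p
  })
  expect_gt(mean(ps > 0.05), 0.7)
})

test_that("fisher p matches explicit summation on random small tables", {
  set.seed(31)
  for (i in 1:30) {
    nq <- sample(3:40, 1); nb <- sample(10:400, 1)
    qa <- sample(0:nq, 1); ba <- sample(0:nb, 1)
    p_pkg <- fisher.test(matrix(c(qa, nq - qa, ba, nb - ba), 2,
                                byrow = TRUE),
                         alternative = "greater")$p.value
    expect_equal(p_pkg, brute_hyper_p(qa, nq, ba, nb), tolerance = 1e-9)
  }
})

test_that("feature sets built from gene models are disjoint where expected", {
  g <- genes_fixture()
  models <- list(genes = g,
                 exons = data.table(gene_id = "gp", chrom = "c1",
                                    start0 = c(5000L, 7000L),
                                    end0 = c(5500L, 8000L)))
  fs <- build_feature_sets(models, chrom_sizes = c(c1 = 10000L, c2 = 10000L))
  expect_named(fs, c("promoter", "exon", "intron", "gene_body"))
  # introns = gene bodies minus exons
  expect_false(any(overlaps_any <- sapply(seq_len(nrow(fs$intron)),
    function(i) any(fs$exon$chrom == fs$intron$chrom[i] &
                    fs$exon$start0 < fs$intron$end0[i] &
                    fs$intron$start0[i] < fs$exon$end0))))
})
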