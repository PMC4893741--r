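# A hand-built two-gene annotation used across the region tests.
toy_models <- function() {
  gm <- list(
    genes = data.table::data.table(
      gene_id = c("gp", "gm"), chrom = "chr1", strand = c("+", "-"),
      start = c(10000L, 30000L), end = c(12000L, 32000L)),
    exons = data.table::data.table(
      gene_id = c("gp", "gp", "gm", "gm"),
      start = c(10000L, 11000L, 30000L, 31500L),
      end = c(10500L, 12000L, 30500L, 32000L)),
    utr5 = data.table::data.table(gene_id = c("gp", "gm"),
                                  start = c(10000L, 31850L),
                                  end = c(10150L, 32000L)),
    utr3 = data.table::data.table(gene_id = c("gp", "gm"),
                                  start = c(11850L, 30000L),
                                  end = c(12000L, 30150L)))
  class(gm) <- "gene_models"
  gm
}

test_that("derived regions follow the strand-aware definitions", {
  feats <- derive_regions(toy_models(), c(chr1 = 50000L), promoter_len = 2000)
  iv <- feats$intervals
  # plus-strand promoter abuts the TSS upstream
  expect_equal(iv[gene_id == "gp" & region == "promoter", .(start, end)],
               data.table::data.table(start = 8000L, end = 10000L))
  # minus-strand promoter mirrors: 3' of the gene end in plus coordinates
  expect_equal(iv[gene_id == "gm" & region == "promoter", .(start, end)],
               data.table::data.table(start = 32000L, end = 34000L))
  # introns are the span minus the exons
  expect_equal(iv[gene_id == "gp" & region == "intron", .(start, end)],
               data.table::data.table(start = 10500L, end = 11000L))
  expect_equal(iv[gene_id == "gm" & region == "intron", .(start, end)],
               data.table::data.table(start = 30500L, end = 31500L))
  # clipping to chromosome bounds
  near0 <- toy_models()
  near0$genes$start[1] <- 500L
  near0$exons <- near0$exons[gene_id == "gm"]
  near0$genes <- near0$genes[gene_id == "gm"]
  near0$genes$end <- 49500L
  near0$genes$start <- 47000L
  near0$exons <- data.table::data.table(gene_id = "gm",
                                        start = c(47000L, 49000L),
                                        end = c(48000L, 49500L))
  near0$utr5 <- near0$utr3 <- NULL
  f2 <- derive_regions(near0, c(chr1 = 50000L), promoter_len = 2000)
  expect_equal(f2$intervals[region == "promoter"]$end, 50000L)

  bad <- toy_models()
  bad$exons$end[1] <- 99999L
  expect_error(derive_regions(bad, c(chr1 = 50000L)), "exon outside")
})

test_that("region levels pool calls and match an interval-membership oracle", {
  # all covered sites inside gp's exons, mC = umC -> exon level 0.5
  sites <- make_sites(c(10100, 10200, 11100), mC = c(3, 3, 3), umC = c(3, 3, 3))
  feats <- derive_regions(toy_models(), c(chr1 = 50000L))
  lv <- region_levels(sites, feats)
  expect_equal(lv[region == "exon"]$ml, 0.5)
  expect_false("intron" %in% lv$region)

  # oracle: brute-force membership sums on random sites
  g <- generate_genome(50000, 0.4, seed = 31)
  tm <- plant_methylomes(g, c(CG = 0.5, CHG = 0.02, CHH = 0.02))
  rsites <- simulate_site_counts(tm$truth_a, 6, r = 0, seed = 32)
  lv2 <- region_levels(rsites, feats)
  iv <- feats$intervals
  for (reg in unique(lv2$region)) {
    for (ctx in lv2[region == reg]$context) {
      rows <- iv[region == reg]
      inside <- rsites[context == ctx &
                         vapply(pos0, function(p)
                           any(p >= rows$start & p < rows$end), logical(1))]
      expect_equal(lv2[region == reg & context == ctx]$mC, sum(inside$mC))
      expect_equal(lv2[region == reg & context == ctx]$n_sites, nrow(inside))
    }
  }
})

test_that("metagene bins partition each instance and orient 5' to 3'", {
  feats <- derive_regions(toy_models(), c(chr1 = 50000L))
  # a site in the first 10 bp of a 200 bp element maps to bin 1 (5' end)
  s5 <- make_sites(11855, 5, 5)    # inside gp utr3 [11850,12000): offset 5
  prof <- metagene_profile(s5, feats, n_bins = 20)
  expect_equal(prof[region == "utr3"]$bin, 1L)
  # minus-strand instance: genomic 3'-most positions map to bin 1
  s3 <- make_sites(32000 + 1999, 5, 5)   # last base of gm promoter [32000,34000)
  # promoter of gm is [32000,34000) on minus strand; its 5' end is 33999
  prof3 <- metagene_profile(s3, feats, n_bins = 20)
  expect_equal(prof3[region == "promoter"]$bin, 1L)

  # bin occupancy: positions of an instance distribute over all 20 bins
  inst_sites <- make_sites(8000:9999, mC = rep(1, 2000), umC = rep(0, 2000))
  profu <- metagene_profile(inst_sites, feats, n_bins = 20)
  prom <- profu[region == "promoter"]
  expect_equal(sort(unique(prom$bin)), 1:20)
  expect_equal(sum(prom$n_sites), 2000)
  expect_true(all(prom$n_sites == 100))   # 2000 bp / 20 bins

  # region_levels and metagene_profile agree when n_bins = 1
  g <- generate_genome(50000, 0.4, seed = 33)
  tm <- plant_methylomes(g, c(CG = 0.4, CHG = 0.02, CHH = 0.02))
  rs <- simulate_site_counts(tm$truth_a, 6, r = 0, seed = 34)
  one <- metagene_profile(rs, feats, n_bins = 1)
  lv <- region_levels(rs, feats)
  m <- merge(one[, .(region, context, ml1 = ml)],
             lv[, .(region, context, ml)], by = c("region", "context"))
  expect_equal(m$ml1, m$ml)
})

test_that("uniform methylation gives flat profiles; strand flip reverses them", {
  g <- generate_genome(60000, 0.4, seed = 35)
  gmod <- generate_gene_models(g, 5, seed = 36)
  feats <- derive_regions(gmod, g)
  tm <- plant_methylomes(g, c(CG = 0.5, CHG = 0.5, CHH = 0.5))
  sites <- simulate_site_counts(tm$truth_a, 15, r = 0, seed = 37)
  prof <- metagene_profile(sites, feats, n_bins = 20)
  cg <- prof[context == "CG" & region == "intron"]
  se <- sqrt(0.25 / (cg$mC + cg$umC))
  expect_true(all(abs(cg$ml - 0.5) < 3 * se))

  # flipping every gene's strand reverses each profile vector exactly
  flipped <- feats
  flipped$intervals <- data.table::copy(feats$intervals)
  flipped$intervals[, strand := ifelse(strand == "+", "-", "+")]
  pf <- metagene_profile(sites, flipped, n_bins = 20)
  # exact reversal on the promoter class, whose 2000 bp length is a
  # multiple of the bin count (floor binning is only approximately
  # symmetric for non-divisible lengths)
  a <- prof[region == "promoter" & context == "CG"][order(bin)]
  b <- pf[region == "promoter" & context == "CG"][order(bin)]
  expect_equal(a$mC, rev(b$mC))
  expect_equal(a$n_sites, rev(b$n_sites))
})
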