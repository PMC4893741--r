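test_that("Fisher two-sided p matches closed forms and enumeration", {
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact_two_sided(10, 0, 0, 10), 2 / 184756)
  expect_equal(fisher_exact_two_sided(3, 1, 1, 3), 34 / 70)
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "non-negative")
  expect_error(fisher_exact_two_sided(1.5, 1, 1, 1), "non-negative integers")

  set.seed(42)
  for (i in 1:200) {
    tb <- matrix(rpois(4, 8), 2)
    if (sum(tb) == 0) next
    p <- fisher_exact_two_sided(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(p, oracle_fisher(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tb)$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment reproduces hand-computed vectors and properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.009, 0.05, 0.1, 0.2)),
               c(0.0225, 0.0225, 0.05 * 5 / 3, 0.125, 0.2))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1")

  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(2:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))       # monotone along sorted p
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])           # permutation-consistent
  }
})

test_that("window tests pool counts, orient fold change, and skip empties", {
  # A: 12/8 (ml 0.6) vs B: 4/16 (ml 0.2) in one window -> fold change 3
  sa <- make_sites(10:19, mC = c(2, 2, 2, 1, 1, 1, 1, 1, 1, 0),
                   umC = c(0, 0, 0, 1, 1, 1, 1, 1, 1, 2))
  sb <- make_sites(10:19, mC = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                   umC = c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2))
  wt <- window_tests(sa, sb, c(chr1 = 1000L), 1000L, 100L)
  expect_equal(nrow(wt), 1)
  expect_equal(wt$ml_a, 0.6)
  expect_equal(wt$ml_b, 0.2)
  expect_equal(wt$fold_change, 3.0)
  expect_equal(wt$direction, "hypo")
  expect_equal(wt$p, fisher_exact_two_sided(12, 8, 4, 16))

  # identical tables: fold change 1 everywhere
  wt0 <- window_tests(sa, sa, c(chr1 = 1000L), 1000L, 100L)
  expect_true(all(wt0$fold_change == 1))
  expect_true(all(wt0$p == 1))

  expect_error(window_tests(sa, make_sites(1, 1, 1, chrom = "chrX"),
                            c(chr1 = 1000L)), "chromosome sets")
})

test_that("window pooled counts equal brute-force sums on simulated data", {
  g <- generate_genome(20000, 0.4, seed = 13)
  tm <- plant_methylomes(g, c(CG = 0.5, CHG = 0.02, CHH = 0.02))
  sa <- simulate_site_counts(tm$truth_a, 8, r = 0, seed = 14)
  sb <- simulate_site_counts(tm$truth_b, 8, r = 0, seed = 15)
  wt <- window_tests(sa, sb, g)
  for (i in sample(nrow(wt), 5)) {
    sel <- sa[pos0 >= wt$start[i] & pos0 < wt$end[i] & context == wt$context[i]]
    expect_equal(wt$mC_a[i], sum(sel$mC))
    expect_equal(wt$n_sites_a[i], nrow(sel))
    expect_equal(wt$mean_depth_a[i], sum(sel$mC + sel$umC) / nrow(sel))
  }
  # q is BH within context over all tested windows
  for (ctx in unique(wt$context))
    expect_equal(wt[context == ctx]$q, bh_adjust(wt[context == ctx]$p))
})

# Build a minimal window_tests-like table for merge tests.
mkwt <- function(start, end, direction, q = 1e-6, context = "CG") {
  data.table::data.table(chrom = "chr1", start = as.integer(start),
                         end = as.integer(end), context = context,
                         mC_a = 60L, umC_a = 40L, mC_b = 10L, umC_b = 90L,
                         n_sites_a = 10L, n_sites_b = 10L,
                         mean_depth_a = 10, mean_depth_b = 10,
                         ml_a = 0.6, ml_b = 0.1, direction = direction,
                         fold_change = 6, p = q, q = q)
}

test_that("kept windows merge by overlap/book-end within direction", {
  sa <- make_sites(c(150, 700, 1150), mC = c(6, 6, 6), umC = c(4, 4, 4))
  sb <- make_sites(c(150, 700, 1150), mC = c(1, 1, 1), umC = c(9, 9, 9))
  two <- rbind(mkwt(100, 1100, "hypo"), mkwt(200, 1200, "hypo"))
  m <- filter_and_merge(two, sa, sb)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 1200L)
  expect_equal(m$n_windows, 2L)
  # merged-span stats recomputed from raw counts
  expect_equal(m$mC_a, 18L)
  expect_equal(m$ml_a, 0.6)

  # adjacent windows of opposite direction stay separate
  opp <- rbind(mkwt(100, 1100, "hypo"), mkwt(1100, 2100, "hyper"))
  m2 <- filter_and_merge(opp, rbind(sa, make_sites(1500, 2, 8)),
                         rbind(sb, make_sites(1500, 8, 2)))
  expect_equal(nrow(m2), 2)

  # merging is idempotent and order-invariant
  m3 <- filter_and_merge(two[2:1], sa, sb)
  expect_equal(m, m3)

  # filters are strict: q = 0.05, depth = 5 or fc = 2 do not pass
  at_thr <- mkwt(100, 1100, "hypo", q = 0.05)
  expect_equal(nrow(filter_and_merge(at_thr, sa, sb)), 0)
  low_depth <- mkwt(100, 1100, "hypo")[, `:=`(mean_depth_a = 5, mean_depth_b = 5)]
  expect_equal(nrow(filter_and_merge(low_depth, sa, sb)), 0)
  low_fc <- mkwt(100, 1100, "hypo")[, fold_change := 2]
  expect_equal(nrow(filter_and_merge(low_fc, sa, sb)), 0)
})

test_that("planted DMRs are recovered with direction and few false calls", {
  cfg <- sim_config(genome_length_bp = 200000L, n_genes = 5L, n_dmrs = 20L,
                    dmr_width = 2000L, dmr_rate_a = 0.6, dmr_rate_b = 0.1,
                    mean_depth = 20, seed = 21L)
  ds <- simulate_dataset(cfg)
  r <- estimate_nonconversion(ds$spike_in)$r
  wt <- window_tests(ds$sites_a, ds$sites_b, ds$genome, r_a = r, r_b = r)
  dmrs <- filter_and_merge(wt, ds$sites_a, ds$sites_b, r_a = r, r_b = r)
  plan <- ds$truth$dmrs
  hit <- vapply(seq_len(nrow(plan)), function(i) {
    any(dmrs$start < plan$end[i] & dmrs$end > plan$start[i] &
          dmrs$direction == plan$direction[i])
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  fp <- vapply(seq_len(nrow(dmrs)), function(i) {
    !any(plan$start < dmrs$end[i] & plan$end > dmrs$start[i])
  }, logical(1))
  expect_lte(mean(fp), 0.1)
  # every kept window lies inside exactly one merged DMR
  kept <- wt[q < 0.05 & mean_depth_a > 5 & mean_depth_b > 5 & fold_change > 2]
  inside <- vapply(seq_len(nrow(kept)), function(i) {
    sum(dmrs$chrom == kept$chrom[i] & dmrs$context == kept$context[i] &
          dmrs$direction == kept$direction[i] &
          dmrs$start <= kept$start[i] & dmrs$end >= kept$end[i])
  }, numeric(1))
  expect_true(all(inside == 1))
})

test_that("DMRs map to genes with arrow rendering and region shares", {
  gm <- list(genes = data.table::data.table(
    gene_id = "g1", chrom = "chr1", strand = "+", start = 10000L, end = 14000L),
    exons = data.table::data.table(gene_id = "g1",
                                   start = c(10000L, 12000L),
                                   end = c(11000L, 14000L)),
    utr5 = data.table::data.table(gene_id = "g1", start = 10000L, end = 10150L),
    utr3 = data.table::data.table(gene_id = "g1", start = 13850L, end = 14000L))
  class(gm) <- "gene_models"
  feats <- derive_regions(gm, c(chr1 = 20000L))
  dmrs <- rbind(mkwt(10100, 10500, "hyper"),
                mkwt(12100, 12500, "hypo"),
                mkwt(11200, 11600, "hypo"),     # intron
                mkwt(18000, 18500, "hypo"))     # intergenic
  dmrs[, `:=`(n_windows = 1L, q_min = q)]
  res <- assign_dmgs(dmrs, feats)
  expect_equal(res$dmgs$gene_id, "g1")
  expect_equal(res$dmgs$n_up, 1L)
  expect_equal(res$dmgs$n_down, 2L)
  expect_equal(res$dmgs$updown, "↑(1)↓(2)")
  dist <- res$region_distribution
  expect_equal(dist[region == "intergenic"]$n, 1L)
  expect_true(dist[region == "intron"]$n >= 1L)
  # intron-only DMRs give a 100% intronic share
  only <- assign_dmgs(dmrs[3][, `:=`(n_windows = 1L, q_min = q)], feats)
  expect_equal(only$region_distribution[region == "intron"]$fraction, 1)
})

test_that("DMR level quartiles match a sort-based oracle", {
  one <- mkwt(0, 1000, "hypo")[, `:=`(n_windows = 1L, q_min = 1e-6)]
  s <- dmr_level_summary(one)
  expect_equal(s[group == "A"]$median, 0.6)
  expect_equal(s[group == "B"]$median, 0.1)

  set.seed(3)
  many <- data.table::rbindlist(lapply(1:40, function(i) mkwt(i * 2000, i * 2000 + 1000, "hypo")))
  many[, `:=`(ml_a = runif(40), ml_b = runif(40), n_windows = 1L, q_min = 1e-6)]
  s2 <- dmr_level_summary(many)
  expect_equal(s2[group == "A"]$q25, oracle_quantile(many$ml_a, 0.25))
  expect_equal(s2[group == "B"]$q75, oracle_quantile(many$ml_b, 0.75))
  expect_error(dmr_level_summary(many[0]), "no DMRs")
})
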