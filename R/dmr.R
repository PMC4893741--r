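#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the
#' probability of the observed table (with a relative slack of 1e-7 to
#' absorb floating-point ties).
#'
#' @param a,b,c,d cell counts: rows are groups, columns are
#'   methylated/unmethylated, i.e. `rbind(c(a, b), c(c, d))`.
#' @return two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("at least one margin must be positive")
  m <- a + c          # column margin: methylated calls
  n <- b + d          # column margin: unmethylated calls
  k <- a + b          # row margin: group A calls
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n, k)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values): q_(i) = min over j >= i of
#' p_(j) * m / j on the sorted p-values, capped at 1 and returned in the
#' input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot_prob(p, "p-values")
  p.adjust(p, method = "BH")
}

#' Per-window differential-methylation tests between two groups
#'
#' Sliding windows (default 1000 bp, step 100 bp) tile the genome; in
#' each window and context, methylated/unmethylated call counts are
#' pooled per group into a 2x2 table and a two-sided Fisher exact test
#' is applied. Levels are corrected per group for non-conversion; fold
#' change is the ratio of the larger to the smaller corrected level with
#' a floor of `eps` on the denominator. BH adjustment is applied within
#' each context across all tested windows.
#'
#' @param sites_a,sites_b site tables of group A (reference/control
#'   analog) and group B, sorted by (chrom, pos0).
#' @param chrom_lengths named chromosome lengths, or a genome.
#' @param width,step window geometry (defaults 1000 / 100).
#' @param r_a,r_b non-conversion rate per group.
#' @param min_sites minimum covered cytosines required in each group.
#' @param eps fold-change denominator floor.
#' @return data.table with one row per tested (window, context):
#'   pooled counts and covered-site numbers per group, mean per-site
#'   depths, corrected levels, direction (group B vs A), fold_change,
#'   p and q. Attribute `n_skipped` counts windows lacking coverage in
#'   either group.
#' @export
window_tests <- function(sites_a, sites_b, chrom_lengths, width = 1000L,
                         step = 100L, r_a = 0, r_b = 0, min_sites = 1L,
                         eps = 0.001) {
  chrs_a <- unique(sites_a$chrom); chrs_b <- unique(sites_b$chrom)
  if (!setequal(chrs_a, chrs_b))
    stop("the two groups cover different chromosome sets")
  wa <- window_ml(sites_a, chrom_lengths, width, step, r = r_a)
  wb <- window_ml(sites_b, chrom_lengths, width, step, r = r_b)
  setnames(wa, c("mC", "umC", "n_sites", "ml_raw", "ml_corrected"),
           c("mC_a", "umC_a", "n_sites_a", "ml_raw_a", "ml_a"))
  setnames(wb, c("mC", "umC", "n_sites", "ml_raw", "ml_corrected"),
           c("mC_b", "umC_b", "n_sites_b", "ml_raw_b", "ml_b"))
  j <- merge(wa, wb, by = c("chrom", "start", "end", "context"))
  n_union <- nrow(unique(rbind(wa[, .(chrom, start, context)],
                               wb[, .(chrom, start, context)])))
  tested <- j[n_sites_a >= min_sites & n_sites_b >= min_sites &
                mC_a + umC_a > 0 & mC_b + umC_b > 0]
  n_skipped <- n_union - nrow(tested)
  if (!nrow(tested)) {
    setattr(tested, "n_skipped", n_skipped)
    return(tested)
  }
  tested[, `:=`(
    mean_depth_a = (mC_a + umC_a) / n_sites_a,
    mean_depth_b = (mC_b + umC_b) / n_sites_b)]
  tested[, direction := fifelse(ml_b > ml_a, "hyper", "hypo")]
  tested[, fold_change := pmax(ml_a, ml_b) / pmax(pmin(ml_a, ml_b), eps)]
  tested[, p := mapply(fisher_exact_two_sided, mC_a, umC_a, mC_b, umC_b)]
  tested[, q := bh_adjust(p), by = context]
  setorder(tested, chrom, start, context)
  setattr(tested, "n_skipped", n_skipped)
  tested[]
}

#' Filter tested windows and merge survivors into DMRs
#'
#' Windows are kept when q < `q_max`, the mean per-site depth exceeds
#' `min_depth` in both groups, and fold change exceeds `min_fc` (all
#' strict, matching "less than 0.05", "greater than 5", "greater than
#' 2"). Overlapping or book-ended kept windows of the same context and
#' direction are merged; merged-span statistics are recomputed from the
#' raw site counts.
#'
#' @param wt output of [window_tests()].
#' @param sites_a,sites_b the raw site tables (for recomputation).
#' @param q_max,min_depth,min_fc thresholds (defaults 0.05, 5, 2).
#' @param r_a,r_b non-conversion rates.
#' @param max_gap maximum gap between kept windows that still merges
#'   (default 0: book-ended or overlapping only).
#' @param eps fold-change denominator floor.
#' @return data.table of DMRs: chrom, start, end, context, direction,
#'   n_windows, pooled counts and corrected levels per group,
#'   fold_change and Fisher p recomputed on the merged span, and q_min
#'   (smallest constituent window q).
#' @export
filter_and_merge <- function(wt, sites_a, sites_b, q_max = 0.05,
                             min_depth = 5, min_fc = 2, r_a = 0, r_b = 0,
                             max_gap = 0L, eps = 0.001) {
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      direction = character(), n_windows = integer(),
                      mC_a = integer(), umC_a = integer(),
                      mC_b = integer(), umC_b = integer(),
                      ml_a = numeric(), ml_b = numeric(),
                      fold_change = numeric(), p = numeric(),
                      q_min = numeric())
  if (!nrow(wt)) return(empty)
  kept <- wt[q < q_max & mean_depth_a > min_depth & mean_depth_b > min_depth &
               fold_change > min_fc]
  if (!nrow(kept)) return(empty)
  out <- kept[, {
    ir <- IRanges::IRanges(start + 1L, end)
    red <- IRanges::reduce(ir, min.gapwidth = as.integer(max_gap) + 1L)
    hit <- IRanges::findOverlaps(ir, red)
    nw <- tabulate(S4Vectors::subjectHits(hit), nbins = length(red))
    .(start = IRanges::start(red) - 1L, end = IRanges::end(red),
      n_windows = nw, q_min = vapply(seq_along(red), function(k) {
        min(q[S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == k]])
      }, numeric(1)))
  }, by = .(chrom, context, direction)]
  # recompute pooled statistics over each merged span from raw sites
  stats <- lapply(seq_len(nrow(out)), function(i) {
    sel_a <- sites_a[chrom == out$chrom[i] & pos0 >= out$start[i] &
                       pos0 < out$end[i] & context == out$context[i]]
    sel_b <- sites_b[chrom == out$chrom[i] & pos0 >= out$start[i] &
                       pos0 < out$end[i] & context == out$context[i]]
    mC_a <- sum(sel_a$mC); umC_a <- sum(sel_a$umC)
    mC_b <- sum(sel_b$mC); umC_b <- sum(sel_b$umC)
    ml_a <- correct_ml(mC_a / max(mC_a + umC_a, 1L), r_a)
    ml_b <- correct_ml(mC_b / max(mC_b + umC_b, 1L), r_b)
    data.table(mC_a = mC_a, umC_a = umC_a, mC_b = mC_b, umC_b = umC_b,
               ml_a = ml_a, ml_b = ml_b,
               fold_change = pmax(ml_a, ml_b) / pmax(pmin(ml_a, ml_b), eps),
               p = fisher_exact_two_sided(mC_a, umC_a, mC_b, umC_b))
  })
  res <- cbind(out, rbindlist(stats))
  setcolorder(res, c("chrom", "start", "end", "context", "direction",
                     "n_windows", "mC_a", "umC_a", "mC_b", "umC_b",
                     "ml_a", "ml_b", "fold_change", "p", "q_min"))
  setorder(res, chrom, start, context)
  res[]
}

#' Assign DMRs to genes and summarise the regional distribution
#'
#' A DMR is assigned to every gene whose footprint (promoter through
#' 3'UTR) it overlaps by at least 1 bp. Per gene, hyper ("up") and hypo
#' ("down") DMR counts are reported with the conventional arrow
#' rendering. The regional distribution gives the fraction of
#' DMR-region assignments falling in each region class; a DMR
#' overlapping no gene footprint counts as intergenic.
#'
#' @param dmrs DMR data.table from [filter_and_merge()].
#' @param features feature intervals from [derive_regions()].
#' @return list with `dmgs` (gene_id, n_up, n_down, updown string) and
#'   `region_distribution` (region, n, fraction).
#' @export
assign_dmgs <- function(dmrs, features) {
  feats <- features$intervals
  if (!nrow(dmrs)) {
    return(list(dmgs = data.table(gene_id = character(), n_up = integer(),
                                  n_down = integer(), updown = character()),
                region_distribution = data.table(region = character(),
                                                 n = integer(),
                                                 fraction = numeric())))
  }
  foot <- feats[, .(start = min(start), end = max(end)),
                by = .(gene_id, chrom)]
  dmr_gr <- GenomicRanges::GRanges(dmrs$chrom,
                                   IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  foot_gr <- GenomicRanges::GRanges(foot$chrom,
                                    IRanges::IRanges(foot$start + 1L, foot$end))
  hit <- GenomicRanges::findOverlaps(dmr_gr, foot_gr)
  asn <- data.table(dmr = S4Vectors::queryHits(hit),
                    gene_id = foot$gene_id[S4Vectors::subjectHits(hit)])
  asn[, direction := dmrs$direction[dmr]]
  dmgs <- asn[, .(n_up = sum(direction == "hyper"),
                  n_down = sum(direction == "hypo")), by = gene_id]
  dmgs[, updown := sprintf("\u2191(%d)\u2193(%d)", n_up, n_down)]
  setorder(dmgs, gene_id)

  # region distribution over DMR-region assignments
  feat_gr <- GenomicRanges::GRanges(feats$chrom,
                                    IRanges::IRanges(feats$start + 1L, feats$end))
  rhit <- GenomicRanges::findOverlaps(dmr_gr, feat_gr)
  rasn <- unique(data.table(dmr = S4Vectors::queryHits(rhit),
                            region = feats$region[S4Vectors::subjectHits(rhit)]))
  inter <- setdiff(seq_len(nrow(dmrs)), unique(asn$dmr))
  if (length(inter))
    rasn <- rbind(rasn, data.table(dmr = inter, region = "intergenic"))
  dist <- rasn[, .(n = .N), by = region]
  dist[, fraction := n / sum(n)]
  setorder(dist, -n)
  list(dmgs = dmgs[], region_distribution = dist[])
}

#' Quartiles of per-DMR methylation levels per group
#'
#' For each DMR, the corrected pooled level of each group over the DMR
#' span is computed from the raw site counts; the 25/50/75% quantiles of
#' those per-DMR levels are reported per group.
#'
#' @param dmrs DMR data.table (must contain ml_a, ml_b; recomputed by
#'   [filter_and_merge()]).
#' @return data.table: group, q25, median, q75, n_dmrs.
#' @export
dmr_level_summary <- function(dmrs) {
  if (!nrow(dmrs)) stop("no DMRs")
  one <- function(g, ml) {
    qs <- quantile(ml, c(.25, .5, .75), names = FALSE)
    data.table(group = g, q25 = qs[1], median = qs[2], q75 = qs[3],
               n_dmrs = length(ml))
  }
  rbind(one("A", dmrs$ml_a), one("B", dmrs$ml_b))
}
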