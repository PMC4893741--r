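#' Derive the five functional element classes from gene models
#'
#' Promoter = `promoter_len` bp immediately upstream of the TSS
#' (strand-aware); exons and UTRs come from the model; introns are the
#' gene span minus the exons. Intervals are clipped to chromosome
#' bounds.
#'
#' @param gene_models a `gene_models` object ([generate_gene_models()]
#'   or [read_gene_models()]).
#' @param chrom_lengths named chromosome lengths (or a genome); used for
#'   clipping. NULL skips clipping.
#' @param promoter_len promoter length in bp (default 2000).
#' @return list of class `feature_intervals` with element `intervals`: a
#'   data.table (gene_id, chrom, strand, region, start, end), regions in
#'   {promoter, utr5, exon, intron, utr3}, 0-based half-open.
#' @export
derive_regions <- function(gene_models, chrom_lengths = NULL,
                           promoter_len = 2000L) {
  if (promoter_len <= 0) stop("promoter_len must be > 0")
  g <- gene_models$genes
  ex <- gene_models$exons
  if (any(ex$start < g$start[match(ex$gene_id, g$gene_id)]) ||
      any(ex$end > g$end[match(ex$gene_id, g$gene_id)]))
    stop("malformed gene model: exon outside gene span")
  if (!is.null(chrom_lengths) &&
      (is.character(chrom_lengths) || methods::is(chrom_lengths, "DNAStringSet")))
    chrom_lengths <- genome_lengths(chrom_lengths)

  prom <- g[, .(gene_id, chrom, strand,
                start = fifelse(strand == "+", start - as.integer(promoter_len), end),
                end = fifelse(strand == "+", start, end + as.integer(promoter_len)))]
  prom[, region := "promoter"]

  strand_of <- g$strand[match(ex$gene_id, g$gene_id)]
  chrom_of <- g$chrom[match(ex$gene_id, g$gene_id)]
  exd <- data.table(gene_id = ex$gene_id, chrom = chrom_of,
                    strand = strand_of, start = ex$start, end = ex$end,
                    region = "exon")

  introns <- ex[order(gene_id, start)][, {
    if (.N > 1) .(start = end[-.N], end = start[-1]) else
      .(start = integer(0), end = integer(0))
  }, by = gene_id]
  introns <- introns[end > start]
  introns[, `:=`(chrom = g$chrom[match(gene_id, g$gene_id)],
                 strand = g$strand[match(gene_id, g$gene_id)],
                 region = "intron")]

  mk_utr <- function(u, label) {
    if (is.null(u) || !nrow(u)) return(NULL)
    data.table(gene_id = u$gene_id,
               chrom = g$chrom[match(u$gene_id, g$gene_id)],
               strand = g$strand[match(u$gene_id, g$gene_id)],
               start = u$start, end = u$end, region = label)
  }
  iv <- rbindlist(list(prom, exd, introns, mk_utr(gene_models$utr5, "utr5"),
                       mk_utr(gene_models$utr3, "utr3")), use.names = TRUE)
  if (!is.null(chrom_lengths)) {
    iv[, start := pmax(start, 0L)]
    iv[, end := pmin(end, chrom_lengths[chrom])]
    iv <- iv[end > start]
  }
  setcolorder(iv, c("gene_id", "chrom", "strand", "region", "start", "end"))
  setorder(iv, chrom, start, gene_id)
  out <- list(intervals = iv[], promoter_len = as.integer(promoter_len))
  class(out) <- "feature_intervals"
  out
}

#' @export
print.feature_intervals <- function(x, ...) {
  cat(sprintf("feature_intervals: %d intervals, %d genes, promoter %d bp\n",
              nrow(x$intervals), length(unique(x$intervals$gene_id)),
              x$promoter_len))
  invisible(x)
}

# Overlap sites with feature intervals; returns one row per
# (site, interval) hit with the interval's metadata attached.
site_feature_hits <- function(sites, features) {
  iv <- features$intervals
  s_gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos0 + 1L, width = 1L))
  f_gr <- GenomicRanges::GRanges(iv$chrom,
                                 IRanges::IRanges(iv$start + 1L, iv$end))
  hit <- GenomicRanges::findOverlaps(s_gr, f_gr)
  qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
  data.table(chrom = sites$chrom[qi], context = sites$context[qi],
             mC = sites$mC[qi], umC = sites$umC[qi], pos0 = sites$pos0[qi],
             gene_id = iv$gene_id[si], region = iv$region[si],
             strand = iv$strand[si], f_start = iv$start[si],
             f_end = iv$end[si])
}

#' Pooled methylation level per functional region class
#'
#' Pools methylated/unmethylated calls of all sites falling in any
#' interval of each region class, per context, and applies the
#' non-conversion correction to the pooled level. A site inside
#' intervals of several classes (across genes) counts in each.
#'
#' @param sites site data.table.
#' @param features `feature_intervals` from [derive_regions()].
#' @param r non-conversion rate.
#' @return data.table: region, context, mC, umC, n_sites, ml.
#' @export
region_levels <- function(sites, features, r = 0) {
  assert_site_table(sites)
  h <- site_feature_hits(sites, features)
  # one vote per (site, region class): a site in two exons still counts once
  h <- unique(h[, .(region, context, chrom, pos0, mC, umC)],
              by = c("region", "context", "chrom", "pos0"))
  agg <- h[, .(mC = sum(mC), umC = sum(umC), n_sites = .N),
           by = .(region, context)]
  agg[, ml := fifelse(mC + umC > 0, correct_ml(mC / (mC + umC), r), NA_real_)]
  setorder(agg, region, context)
  agg[]
}

#' 20-bin metagene methylation profiles per region class
#'
#' Each feature instance is split into `n_bins` equal-width bins in
#' 5'->3' transcript orientation (minus-strand instances reversed);
#' calls are pooled per (region class, context, bin) across instances
#' and the pooled level corrected for non-conversion. Bin 1 is the 5'
#' end.
#'
#' @param sites site data.table.
#' @param features `feature_intervals`.
#' @param r non-conversion rate.
#' @param n_bins number of bins (default 20).
#' @return data.table: region, context, bin (1..n_bins), mC, umC,
#'   n_sites, ml.
#' @export
metagene_profile <- function(sites, features, r = 0, n_bins = 20L) {
  assert_site_table(sites)
  if (n_bins < 1) stop("n_bins must be >= 1")
  h <- site_feature_hits(sites, features)
  if (!nrow(h)) {
    return(data.table(region = character(), context = character(),
                      bin = integer(), mC = integer(), umC = integer(),
                      n_sites = integer(), ml = numeric()))
  }
  len <- h$f_end - h$f_start
  off <- ifelse(h$strand == "+", h$pos0 - h$f_start, h$f_end - 1L - h$pos0)
  h[, bin := pmin(as.integer(floor(off * n_bins / len)) + 1L, as.integer(n_bins))]
  agg <- h[, .(mC = sum(mC), umC = sum(umC), n_sites = .N),
           by = .(region, context, bin)]
  agg[, ml := fifelse(mC + umC > 0, correct_ml(mC / (mC + umC), r), NA_real_)]
  setorder(agg, region, context, bin)
  agg[]
}
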