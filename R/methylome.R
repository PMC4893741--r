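#' Estimate the bisulfite non-conversion rate from a spike-in table
#'
#' The non-conversion rate r is the fraction of calls at cytosine
#' reference positions of the unmethylated spike-in genome (lambda) that
#' were nevertheless sequenced as cytosine.
#'
#' @param spike_in site data.table (chrom, pos0, strand, context, mC, umC).
#' @return list with `r` and `n_calls`.
#' @export
estimate_nonconversion <- function(spike_in) {
  assert_site_table(spike_in)
  total <- sum(spike_in$mC) + sum(spike_in$umC)
  if (nrow(spike_in) == 0L || total == 0L)
    stop("spike-in table has no calls; cannot estimate non-conversion")
  list(r = sum(spike_in$mC) / total, n_calls = total)
}

#' Correct a raw methylation level for bisulfite non-conversion
#'
#' With non-conversion rate r, the expected raw call-level fraction at a
#' site of true level ML is ML + (1 - ML) r; inverting gives
#' ML = (raw - r) / (1 - r), clamped to [0, 1].
#'
#' @param ml_raw raw methylated-call fraction(s).
#' @param r non-conversion rate in [0, 1).
#' @return corrected level(s) in [0, 1].
#' @export
correct_ml <- function(ml_raw, r) {
  stopifnot_prob(r, "r", open_right = TRUE)
  clamp01((ml_raw - r) / (1 - r))
}

#' Per-site methylation level estimate
#'
#' @param mC,umC methylated / unmethylated call counts (vectors).
#' @param r non-conversion rate.
#' @return data.table with depth, ml_raw, ml_corrected; sites with zero
#'   depth have both levels NA (missing).
#' @export
site_ml <- function(mC, umC, r = 0) {
  if (any(mC < 0) || any(umC < 0)) stop("counts must be >= 0")
  depth <- mC + umC
  raw <- ifelse(depth > 0, mC / depth, NA_real_)
  data.table(depth = as.integer(depth), ml_raw = raw,
             ml_corrected = ifelse(is.na(raw), NA_real_, correct_ml(raw, r)))
}

# Window starts tiling [0, L): full windows only; one truncated window
# when the chromosome is shorter than the window.
window_starts <- function(L, width, step) {
  if (L < width) return(0L)
  as.integer(seq(0L, L - width, by = step))
}

#' Pooled methylation levels in sliding windows
#'
#' Windows of `width` bp tile each chromosome at `step` bp; within each
#' window and context, methylated and unmethylated call counts are
#' summed, the pooled raw level is their ratio, and the non-conversion
#' correction is applied to the pooled level.
#'
#' @param sites site data.table sorted by (chrom, pos0).
#' @param chrom_lengths named integer vector of chromosome lengths (or a
#'   genome, from which lengths are taken).
#' @param width,step window geometry in bp (width >= step >= 1).
#' @param r non-conversion rate.
#' @return data.table: chrom, start, end, context, mC, umC, n_sites,
#'   ml_raw, ml_corrected. Windows with no covered site in a context are
#'   omitted (empty windows).
#' @export
window_ml <- function(sites, chrom_lengths, width = 3000L, step = 600L, r = 0) {
  assert_site_table(sites)
  if (!(width >= step && step >= 1)) stop("need width >= step >= 1")
  if (is.character(chrom_lengths) || methods::is(chrom_lengths, "DNAStringSet"))
    chrom_lengths <- genome_lengths(chrom_lengths)
  if (nrow(sites) && any(sites[, is.unsorted(pos0), by = chrom]$V1))
    stop("sites must be sorted by (chrom, pos0)")
  out <- lapply(names(chrom_lengths), function(chr) {
    s <- sites[chrom == chr]
    if (!nrow(s)) return(NULL)
    starts <- window_starts(chrom_lengths[[chr]], width, step)
    wins <- IRanges::IRanges(start = starts + 1L,
                             width = pmin(width, chrom_lengths[[chr]]))
    hits <- IRanges::findOverlaps(IRanges::IRanges(s$pos0 + 1L, width = 1L), wins)
    if (!length(hits)) return(NULL)
    dt <- data.table(win = S4Vectors::subjectHits(hits),
                     context = s$context[S4Vectors::queryHits(hits)],
                     mC = s$mC[S4Vectors::queryHits(hits)],
                     umC = s$umC[S4Vectors::queryHits(hits)])
    agg <- dt[, .(mC = sum(mC), umC = sum(umC), n_sites = .N),
              by = .(win, context)]
    agg[, `:=`(chrom = chr, start = starts[win],
               end = pmin(starts[win] + as.integer(width),
                          chrom_lengths[[chr]]))]
    agg[, win := NULL]
    agg
  })
  res <- rbindlist(out)
  if (!nrow(res)) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), mC = integer(), umC = integer(),
                      n_sites = integer(), ml_raw = numeric(),
                      ml_corrected = numeric()))
  }
  res[, ml_raw := fifelse(mC + umC > 0, mC / (mC + umC), NA_real_)]
  res[, ml_corrected := fifelse(is.na(ml_raw), NA_real_, correct_ml(ml_raw, r))]
  setcolorder(res, c("chrom", "start", "end", "context", "mC", "umC",
                     "n_sites", "ml_raw", "ml_corrected"))
  setorder(res, chrom, start, context)
  res[]
}

#' Classify a methylation level as hyper- or hypomethylated
#'
#' CG sites are hypermethylated above 75% and non-CG (CHG/CHH) sites
#' above 25%; the thresholds are strict ("over"), so equality falls to
#' hypo.
#'
#' @param ml_corrected corrected level(s) in [0, 1].
#' @param context context label(s): CG, CHG or CHH.
#' @return character vector, "hyper" or "hypo".
#' @export
classify_hyper_hypo <- function(ml_corrected, context) {
  stopifnot_prob(ml_corrected, "ml")
  thr <- ifelse(context == "CG", 0.75, 0.25)
  ifelse(ml_corrected > thr, "hyper", "hypo")
}

#' Genome-wide methylation summary
#'
#' Produces the dataset-level quantities usually tabulated for a WGBS
#' sample: (a) the pooled corrected methylation level per context (as a
#' percentage); (b) the percentage of covered genomic cytosines called
#' methylated; and (c) the composition of methylcytosines by context.
#'
#' A covered site (depth >= `min_depth`) is called methylated when its
#' methylated-call count is incompatible with the non-conversion rate
#' alone: one-sided binomial test of mC out of depth against rate r,
#' p < `site_alpha` (with r = 0 this reduces to mC >= 1). Set
#' `site_rule = "any"` to call any site with mC >= 1 methylated instead.
#'
#' @param sites site data.table.
#' @param r non-conversion rate.
#' @param min_depth minimum depth for per-site classification (default 5).
#' @param site_alpha significance level of the per-site binomial test.
#' @param site_rule "binomial" (default) or "any".
#' @return list with `level_pct` (named per-context pooled levels, %),
#'   `mc_pct` (% of covered Cs methylated), `composition_pct` (named,
#'   sums to 100), `n_covered`, `n_methylated`.
#' @export
genome_summary <- function(sites, r = 0, min_depth = 5L, site_alpha = 0.05,
                           site_rule = c("binomial", "any")) {
  assert_site_table(sites)
  site_rule <- match.arg(site_rule)
  if (!nrow(sites)) stop("no sites")
  lv <- sites[, .(mC = sum(mC), umC = sum(umC)), by = context]
  lv <- lv[mC + umC > 0]
  if (!nrow(lv)) stop("no covered sites")
  level_pct <- setNames(100 * correct_ml(lv$mC / (lv$mC + lv$umC), r),
                        lv$context)
  cov <- sites[mC + umC >= min_depth]
  if (nrow(cov)) {
    if (site_rule == "binomial") {
      pm <- pbinom(cov$mC - 1L, cov$mC + cov$umC, r, lower.tail = FALSE)
      meth <- cov$mC >= 1L & pm < site_alpha
    } else {
      meth <- cov$mC >= 1L
    }
  } else meth <- logical(0)
  n_meth_by_ctx <- cov[meth, .N, by = context]
  comp <- setNames(rep(0, 3), c("CG", "CHG", "CHH"))
  if (nrow(n_meth_by_ctx) && sum(n_meth_by_ctx$N) > 0)
    comp[n_meth_by_ctx$context] <- 100 * n_meth_by_ctx$N / sum(n_meth_by_ctx$N)
  list(level_pct = level_pct,
       mc_pct = if (nrow(cov)) 100 * sum(meth) / nrow(cov) else NA_real_,
       composition_pct = comp,
       n_covered = nrow(cov), n_methylated = sum(meth))
}

#' Fold change between two composition percentages
#'
#' Ratio of two percentages, rounded to one decimal, as used when
#' comparing the context composition of methylcytosines between groups.
#'
#' @param pct_a,pct_b percentages (numerator / denominator).
#' @return `round(pct_a / pct_b, 1)`.
#' @export
composition_fold_change <- function(pct_a, pct_b) {
  if (any(pct_b <= 0)) stop("denominator percentage must be > 0")
  round(pct_a / pct_b, 1)
}
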