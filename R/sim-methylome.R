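#' Plan disjoint differentially methylated intervals
#'
#' Places `n` pairwise-disjoint intervals of fixed width on the first
#' chromosome and records the true within-interval methylation rate of
#' each group for the chosen context.
#'
#' @param genome named character vector / DNAStringSet.
#' @param n number of intervals.
#' @param width interval width in bp (default 2000).
#' @param rate_a,rate_b true methylation level inside the interval for
#'   group A and group B.
#' @param context context the effect applies to (default "CG").
#' @param seed integer seed.
#' @return data.table with chrom, start, end (0-based half-open),
#'   context, rate_a, rate_b, direction ("hyper"/"hypo": group B
#'   relative to group A).
#' @export
plan_dmrs <- function(genome, n, width = 2000L, rate_a = 0.6, rate_b = 0.1,
                      context = "CG", seed = 1L) {
  genome <- as_genome(genome)
  stopifnot_prob(c(rate_a, rate_b), "rates")
  chr <- names(genome)[1]
  L <- nchar(genome[[1]])
  if (n * 2L * width > L)
    stop("genome too short to place ", n, " disjoint intervals of ", width, " bp")
  with_seed(seed, {
    slot <- L %/% n
    starts <- vapply(seq_len(n), function(k) {
      lo <- (k - 1L) * slot
      hi <- k * slot - width
      if (hi > lo) sample(lo:hi, 1L) else lo
    }, integer(1))
    data.table(chrom = chr, start = starts, end = starts + as.integer(width),
               context = context, rate_a = rate_a, rate_b = rate_b,
               direction = ifelse(rate_b > rate_a, "hyper", "hypo"))
  })
}

#' Assign true methylation rates to every cytosine of two groups
#'
#' Outside planted intervals both groups share the per-context baseline
#' rates; inside a planted interval, sites of the interval's context take
#' the interval's group-specific rates.
#'
#' @param genome named character vector / DNAStringSet.
#' @param baselines per-context baseline rates: either one named vector
#'   `c(CG=, CHG=, CHH=)` shared by both groups, or a list with elements
#'   `a` and `b` of that form.
#' @param dmr_plan data.table as returned by [plan_dmrs()], or NULL for
#'   a null methylome.
#' @return list with `truth_a`, `truth_b` (data.tables: chrom, pos0,
#'   strand, context, trinuc, rate) and `dmrs` (the plan).
#' @export
plant_methylomes <- function(genome, baselines, dmr_plan = NULL) {
  if (!is.list(baselines)) baselines <- list(a = baselines, b = baselines)
  for (g in c("a", "b")) {
    b <- baselines[[g]]
    if (!all(c("CG", "CHG", "CHH") %in% names(b)))
      stop("baselines need named rates for CG, CHG and CHH")
    stopifnot_prob(b, "baseline rates")
  }
  ctx <- call_contexts(genome)
  truth <- lapply(c("a", "b"), function(g) {
    t <- copy(ctx)
    t[, rate := unname(baselines[[g]][context])]
    t
  })
  names(truth) <- c("truth_a", "truth_b")
  if (!is.null(dmr_plan) && nrow(dmr_plan)) {
    stopifnot_prob(c(dmr_plan$rate_a, dmr_plan$rate_b), "planted rates")
    o <- order(dmr_plan$chrom, dmr_plan$start)
    dp <- dmr_plan[o]
    bad <- dp[, any(head(end, -1) > tail(start, -1)), by = chrom][V1 == TRUE]
    if (nrow(bad)) stop("planted intervals overlap")
    for (i in seq_len(nrow(dp))) {
      idx <- truth$truth_a[, which(chrom == dp$chrom[i] & pos0 >= dp$start[i] &
                                     pos0 < dp$end[i] & context == dp$context[i])]
      if (length(idx)) {
        set(truth$truth_a, idx, "rate", dp$rate_a[i])
        set(truth$truth_b, idx, "rate", dp$rate_b[i])
      }
    }
  }
  c(truth, list(dmrs = dmr_plan))
}

#' Simulate per-site bisulfite call counts from a true methylome
#'
#' Site depth is Poisson around `mean_depth`; the methylated call count
#' is Binomial(depth, ML_true + (1 - ML_true) * r): a truly unmethylated
#' cytosine escapes conversion with probability `r` and then reads as
#' methylated. Sites drawing depth 0 are emitted with zero counts.
#'
#' @param truth data.table with chrom, pos0, strand, context, trinuc, rate.
#' @param mean_depth mean per-site read depth (> 0).
#' @param r bisulfite non-conversion rate, in [0, 1).
#' @param seed integer seed.
#' @return site data.table: chrom, pos0, strand, context, trinuc, mC, umC.
#' @export
simulate_site_counts <- function(truth, mean_depth, r = 0, seed = 1L) {
  if (!is.numeric(mean_depth) || mean_depth <= 0) stop("mean_depth must be > 0")
  stopifnot_prob(r, "r", open_right = TRUE)
  stopifnot_prob(truth$rate, "true rates")
  with_seed(seed, {
    n <- nrow(truth)
    depth <- rpois(n, mean_depth)
    p <- truth$rate + (1 - truth$rate) * r
    mC <- rbinom(n, depth, p)
    out <- truth[, .(chrom, pos0, strand, context, trinuc)]
    out[, `:=`(mC = as.integer(mC), umC = as.integer(depth - mC))]
    out[]
  })
}

#' Simulate an unmethylated spike-in control table
#'
#' Emulates the lambda-phage spike-in used to estimate the bisulfite
#' non-conversion rate: every cytosine is truly unmethylated, so each
#' methylated call is a conversion failure with probability `r`.
#'
#' @param n_c_positions number of cytosine positions (>= 1).
#' @param mean_depth mean per-position depth.
#' @param r true non-conversion rate in [0, 1).
#' @param seed integer seed.
#' @return site data.table on chromosome "lambda".
#' @export
simulate_spike_in <- function(n_c_positions, mean_depth, r, seed = 1L) {
  if (!is.numeric(n_c_positions) || n_c_positions < 1)
    stop("n_c_positions must be >= 1")
  stopifnot_prob(r, "r", open_right = TRUE)
  truth <- data.table(chrom = "lambda",
                      pos0 = seq_len(as.integer(n_c_positions)) - 1L,
                      strand = "+", context = "CHH", trinuc = "CTT",
                      rate = 0)
  simulate_site_counts(truth, mean_depth, r, seed = seed)
}
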