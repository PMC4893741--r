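#' Tabulate methylation by 9-mer sequence context
#'
#' For every covered cytosine with depth >= `min_depth`, the 9-mer with
#' the cytosine at position 4 (three bases upstream, five downstream, on
#' the cytosine's own strand; minus-strand windows reverse-complemented)
#' is extracted, and calls are pooled per distinct 9-mer. Sites whose
#' window runs off the chromosome or contains an N are skipped and
#' tallied.
#'
#' @param genome named character vector / DNAStringSet.
#' @param sites site data.table.
#' @param min_depth minimum site depth (default 5).
#' @param r non-conversion rate.
#' @return data.table: ninemer, context (of the central C), mC, umC,
#'   n_sites, ml (pooled corrected level); attribute `n_skipped`.
#' @export
tabulate_ninemers <- function(genome, sites, min_depth = 5L, r = 0) {
  assert_site_table(sites)
  if (min_depth < 1) stop("min_depth must be >= 1")
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  s <- as.data.table(sites)[mC + umC >= min_depth]
  skipped <- 0L
  parts <- lapply(names(genome), function(chr) {
    sc <- s[chrom == chr]
    if (!nrow(sc)) return(NULL)
    # plus strand: window [pos0-3, pos0+6); minus: [pos0-5, pos0+4) revcomp
    w_start <- ifelse(sc$strand == "+", sc$pos0 - 3L, sc$pos0 - 5L)
    w_end <- w_start + 9L
    ok <- w_start >= 0L & w_end <= lens[[chr]]
    skipped <<- skipped + sum(!ok)
    sc <- sc[ok]; w_start <- w_start[ok]
    if (!nrow(sc)) return(NULL)
    kmer <- substring(genome[[chr]], w_start + 1L, w_start + 9L)
    minus <- sc$strand == "-"
    if (any(minus)) kmer[minus] <- revcomp(kmer[minus])
    has_n <- grepl("N", kmer, fixed = TRUE)
    skipped <<- skipped + sum(has_n)
    sc <- sc[!has_n]; kmer <- kmer[!has_n]
    if (!nrow(sc)) return(NULL)
    data.table(ninemer = kmer, context = sc$context, mC = sc$mC, umC = sc$umC)
  })
  dt <- rbindlist(parts)
  if (!nrow(dt)) {
    out <- data.table(ninemer = character(), context = character(),
                      mC = integer(), umC = integer(), n_sites = integer(),
                      ml = numeric())
    setattr(out, "n_skipped", skipped)
    return(out)
  }
  agg <- dt[, .(mC = sum(mC), umC = sum(umC), n_sites = .N),
            by = .(ninemer, context)]
  agg[, ml := correct_ml(mC / (mC + umC), r)]
  setorder(agg, ninemer)
  setattr(agg, "n_skipped", skipped)
  agg[]
}

#' Position frequency matrices of high- and low-methylation 9-mers
#'
#' 9-mers are split into a high and a low set using the hyper/hypo
#' thresholds of their central-cytosine context (CG: level > 0.75;
#' non-CG: level > 0.25). Per set, base frequencies are computed per
#' position, weighted by the number of contributing sites (set
#' `weight = "equal"` for one vote per distinct 9-mer).
#'
#' @param ninemer_stats output of [tabulate_ninemers()].
#' @param context context to analyse ("CG", "CHG" or "CHH").
#' @param weight "sites" (default) or "equal".
#' @return list with `high` and `low`: 4x9 matrices (rows A, C, G, T;
#'   columns sum to 1), or NULL when a side is empty; plus `n_high`,
#'   `n_low` (distinct 9-mers per side).
#' @export
preference_matrices <- function(ninemer_stats, context = "CG",
                                weight = c("sites", "equal")) {
  weight <- match.arg(weight)
  ns <- ninemer_stats[ninemer_stats$context == context]
  if (!nrow(ns)) stop("no 9-mers in context ", context)
  thr <- if (context == "CG") 0.75 else 0.25
  hi <- ns[ns$ml > thr]
  lo <- ns[ns$ml <= thr]
  pfm <- function(x) {
    if (!nrow(x)) return(NULL)
    w <- if (weight == "sites") x$n_sites else rep(1L, nrow(x))
    mat <- matrix(0, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
    chars <- strsplit(x$ninemer, "", fixed = TRUE)
    for (i in seq_along(chars)) {
      for (j in 1:9) mat[chars[[i]][j], j] <- mat[chars[[i]][j], j] + w[i]
    }
    sweep(mat, 2, colSums(mat), "/")
  }
  list(high = pfm(hi), low = pfm(lo), n_high = nrow(hi), n_low = nrow(lo))
}
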