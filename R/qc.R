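## FASTQ read filtering and quality summaries.
##
## Three read-level rules, applied in order with each removed read
## attributed to exactly one rule:
##   1. adapter contamination: the adapter literal occurs as a substring;
##   2. ambiguity: fraction of N bases > max_n_fraction (0.10);
##   3. low quality: fraction of bases with PHRED <= lowq_phred_cutoff
##      (5) is >= lowq_base_fraction (0.50).
## PHRED encoding is Sanger/Illumina 1.8+ (offset 33). The low-quality
## criterion is read-level, so the whole read is removed.

#' Default QC thresholds
#'
#' @param adapter adapter literal to scan for (default: Illumina TruSeq
#'   adapter prefix).
#' @param max_n_fraction maximum tolerated N fraction (strict >).
#' @param lowq_phred_cutoff PHRED score at or below which a base counts
#'   as low quality.
#' @param lowq_base_fraction fraction of low-quality bases at or above
#'   which the read is removed.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(adapter = "AGATCGGAAGAGC", max_n_fraction = 0.10,
                          lowq_phred_cutoff = 5L, lowq_base_fraction = 0.50) {
  stopifnot_prob(c(max_n_fraction, lowq_base_fraction), "fractions")
  if (nchar(adapter) < 8) stop("adapter literal must be >= 8 nt")
  if (lowq_phred_cutoff < 0) stop("phred cutoff must be >= 0")
  list(adapter = adapter, max_n_fraction = max_n_fraction,
       lowq_phred_cutoff = as.integer(lowq_phred_cutoff),
       lowq_base_fraction = lowq_base_fraction)
}

validate_reads <- function(reads) {
  need <- c("id", "seq", "qual")
  if (!is.data.frame(reads) || !all(need %in% names(reads)))
    stop("reads must have columns id, seq, qual")
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad))
    stop("malformed FASTQ record (sequence/quality length mismatch): ",
         reads$id[bad[1]])
  invisible(reads)
}

#' Filter reads by adapter, N content and base quality
#'
#' @param reads a data.table with columns id, seq, qual (see
#'   [read_fastq()]), or a path to a FASTQ file.
#' @param thresholds list from [qc_thresholds()].
#' @return list with `kept` (the surviving reads, unchanged) and
#'   `report`: reads in, removed per rule, reads kept, plus the Q20/Q30/GC
#'   summaries of the kept reads.
#' @export
filter_reads <- function(reads, thresholds = qc_thresholds()) {
  if (is.character(reads)) reads <- read_fastq(reads)
  reads <- as.data.table(reads)
  validate_reads(reads)
  n_in <- nrow(reads)
  if (!n_in) {
    rep <- list(reads_in = 0L, removed_adapter = 0L, removed_n = 0L,
                removed_lowq = 0L, reads_kept = 0L,
                q20 = NA_real_, q30 = NA_real_, gc = NA_real_)
    return(list(kept = reads, report = rep))
  }
  has_adapter <- grepl(thresholds$adapter, reads$seq, fixed = TRUE)
  len <- nchar(reads$seq)
  n_frac <- (len - nchar(gsub("N", "", reads$seq, fixed = TRUE))) / len
  qs <- vapply(reads$qual, function(q) {
    ph <- utf8ToInt(q) - 33L
    mean(ph <= thresholds$lowq_phred_cutoff)
  }, numeric(1), USE.NAMES = FALSE)
  rule <- rep("kept", n_in)
  rule[!has_adapter & n_frac > thresholds$max_n_fraction] <- "n"
  rule[!has_adapter & rule == "kept" &
         qs >= thresholds$lowq_base_fraction] <- "lowq"
  rule[has_adapter] <- "adapter"
  kept <- reads[rule == "kept"]
  qsum <- summarize_quality(kept)
  report <- list(reads_in = n_in,
                 removed_adapter = sum(rule == "adapter"),
                 removed_n = sum(rule == "n"),
                 removed_lowq = sum(rule == "lowq"),
                 reads_kept = nrow(kept),
                 q20 = qsum$q20, q30 = qsum$q30, gc = qsum$gc)
  list(kept = kept, report = report)
}

#' Q20, Q30 and GC content of a read set
#'
#' Q20/Q30 are the fractions of base calls with PHRED >= 20 / >= 30;
#' GC is (G+C)/(A+C+G+T) over all bases, Ns excluded from the
#' denominator.
#'
#' @param reads data.table with columns id, seq, qual.
#' @return list with q20, q30, gc (NA on empty input).
#' @export
summarize_quality <- function(reads) {
  reads <- as.data.table(reads)
  validate_reads(reads)
  if (!nrow(reads)) return(list(q20 = NA_real_, q30 = NA_real_, gc = NA_real_))
  ph <- utf8ToInt(paste(reads$qual, collapse = "")) - 33L
  seq_all <- paste(reads$seq, collapse = "")
  counts <- table(strsplit(seq_all, "", fixed = TRUE)[[1]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  list(q20 = mean(ph >= 20L), q30 = mean(ph >= 30L),
       gc = if (acgt > 0) gc / acgt else NA_real_)
}
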