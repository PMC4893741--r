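#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc_fraction/2 and
#' P(A) = P(T) = (1 - gc_fraction)/2.
#'
#' @param length_bp total length in bp (>= 1000).
#' @param gc_fraction target GC content, strictly inside (0, 1).
#' @param seed integer seed; the same seed yields an identical sequence.
#' @param name chromosome name.
#' @return named character vector of length 1 (the chromosome).
#' @export
generate_genome <- function(length_bp, gc_fraction = 0.4, seed = 1L,
                            name = "chr1") {
  if (!is.numeric(length_bp) || length_bp < 1000)
    stop("length_bp must be >= 1000")
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must lie strictly inside (0, 1)")
  with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    bases <- sample(names(p), size = as.integer(length_bp),
                    replace = TRUE, prob = p)
    setNames(paste(bases, collapse = ""), name)
  })
}

#' Generate non-overlapping gene models on a genome
#'
#' Genes are laid left to right with random inter-gene gaps large enough
#' to hold a promoter, on random strands. Each gene has >= 2 exons with
#' introns between them, a 5'UTR at the start of the first exon and a
#' 3'UTR at the end of the last exon (in transcript orientation).
#'
#' @param genome named character vector / DNAStringSet.
#' @param n_genes number of genes to place.
#' @param seed integer seed.
#' @param gene_len_range span length range in bp.
#' @param exon_range range for the number of exons per gene.
#' @param utr_len UTR length in bp (each).
#' @param min_gap minimum inter-gene gap (>= promoter length is sensible).
#' @return An object of class `gene_models`: a list with data.tables
#'   `genes` (gene_id, chrom, strand, start, end), `exons`, `utr5`,
#'   `utr3` (gene_id, start, end); all coordinates 0-based half-open.
#' @export
generate_gene_models <- function(genome, n_genes, seed = 1L,
                                 gene_len_range = c(2000L, 6000L),
                                 exon_range = c(2L, 5L),
                                 utr_len = 150L, min_gap = 2500L) {
  genome <- as_genome(genome)
  chr <- names(genome)[1]
  L <- nchar(genome[[1]])
  max_len <- gene_len_range[2]
  need <- min_gap + n_genes * (max_len + min_gap)
  if (L < need)
    stop("genome too short for ", n_genes, " genes: need >= ", need, " bp")
  with_seed(seed, {
    genes <- vector("list", n_genes)
    exons <- vector("list", n_genes)
    utr5 <- vector("list", n_genes)
    utr3 <- vector("list", n_genes)
    slot <- (L - min_gap) %/% n_genes
    sample_range <- function(a, b) if (a >= b) as.integer(a) else sample(a:b, 1L)
    for (k in seq_len(n_genes)) {
      len <- sample_range(gene_len_range[1], gene_len_range[2])
      lo <- (k - 1L) * slot + min_gap
      hi <- k * slot - len
      g_start <- if (hi > lo) sample(lo:hi, 1L) else lo
      g_end <- g_start + len
      strand <- sample(c("+", "-"), 1L)
      min_piece <- max(2L * utr_len, 100L)
      n_ex_fit <- max(2L, (len %/% min_piece + 1L) %/% 2L)
      n_ex <- sample_range(exon_range[1], min(exon_range[2], n_ex_fit))
      # split the span into 2*n_ex - 1 alternating exon/intron pieces
      n_piece <- 2L * n_ex - 1L
      w <- rmultinom_lengths(len, n_piece, min_piece = min_piece)
      bounds <- g_start + cumsum(c(0L, w))
      piece <- data.table(start = bounds[-length(bounds)], end = bounds[-1])
      ex <- piece[seq(1L, n_piece, by = 2L)]
      genes[[k]] <- data.table(gene_id = sprintf("gene%03d", k), chrom = chr,
                               strand = strand, start = g_start, end = g_end)
      exons[[k]] <- data.table(gene_id = sprintf("gene%03d", k),
                               start = ex$start, end = ex$end)
      # UTRs in transcript orientation: 5' at TSS-side exon
      if (strand == "+") {
        utr5[[k]] <- data.table(gene_id = sprintf("gene%03d", k),
                                start = ex$start[1], end = ex$start[1] + utr_len)
        utr3[[k]] <- data.table(gene_id = sprintf("gene%03d", k),
                                start = ex$end[n_ex] - utr_len, end = ex$end[n_ex])
      } else {
        utr5[[k]] <- data.table(gene_id = sprintf("gene%03d", k),
                                start = ex$end[n_ex] - utr_len, end = ex$end[n_ex])
        utr3[[k]] <- data.table(gene_id = sprintf("gene%03d", k),
                                start = ex$start[1], end = ex$start[1] + utr_len)
      }
    }
    out <- list(genes = rbindlist(genes), exons = rbindlist(exons),
                utr5 = rbindlist(utr5), utr3 = rbindlist(utr3))
    class(out) <- "gene_models"
    out
  })
}

# Partition `total` into n positive pieces each >= min_piece.
rmultinom_lengths <- function(total, n, min_piece) {
  if (n == 1L) return(total)
  free <- total - n * min_piece
  if (free < 0) stop("pieces do not fit")
  cuts <- sort(sample.int(free + 1L, n - 1L, replace = TRUE) - 1L)
  extra <- diff(c(0L, cuts, free))
  as.integer(min_piece + extra)
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %s, %d exons\n",
              nrow(x$genes), paste(unique(x$genes$chrom), collapse = ","),
              nrow(x$exons)))
  invisible(x)
}
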