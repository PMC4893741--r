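#' Simulate reads with planted QC violations
#'
#' Draws reads uniformly from the genome (random strand) with baseline
#' PHRED qualities of 30-40, then independently plants three kinds of QC
#' violations: an embedded adapter substring, an N fraction above 10%,
#' and >= 50% of bases at PHRED <= 5. Ground-truth per-rule removal
#' counts are computed from the finished reads with the same precedence
#' the QC filter uses (adapter, then N fraction, then low quality), so a
#' read violating several rules is attributed to the first.
#'
#' @param genome named character vector / DNAStringSet.
#' @param n_reads number of reads (0 allowed).
#' @param read_len read length in bp (<= genome length).
#' @param adapter_rate,n_rate,lowq_rate per-read violation
#'   probabilities, each in [0, 1].
#' @param adapter adapter literal to embed.
#' @param seed integer seed.
#' @return list with `reads` (data.table id, seq, qual) and `truth`
#'   (list: adapter, n, lowq, clean counts).
#' @export
simulate_reads <- function(genome, n_reads, read_len = 100L,
                           adapter_rate = 0, n_rate = 0, lowq_rate = 0,
                           adapter = "AGATCGGAAGAGC", seed = 1L) {
  genome <- as_genome(genome)
  stopifnot_prob(c(adapter_rate, n_rate, lowq_rate), "violation rates")
  L <- nchar(genome[[1]])
  if (read_len > L) stop("read_len exceeds genome length")
  if (n_reads == 0) {
    reads <- data.table(id = character(), seq = character(), qual = character())
    return(list(reads = reads,
                truth = list(adapter = 0L, n = 0L, lowq = 0L, clean = 0L)))
  }
  with_seed(seed, {
    starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
    seqs <- substring(genome[[1]], starts, starts + read_len - 1L)
    rc <- runif(n_reads) < 0.5
    seqs[rc] <- revcomp(seqs[rc])
    quals <- vapply(seq_len(n_reads), function(i) {
      intToUtf8(sample(30:40, read_len, replace = TRUE) + 33L)
    }, character(1))

    plant_adapter <- runif(n_reads) < adapter_rate
    alen <- nchar(adapter)
    for (i in which(plant_adapter)) {
      at <- sample.int(read_len - alen + 1L, 1L)
      seqs[i] <- paste0(substr(seqs[i], 1, at - 1L), adapter,
                        substr(seqs[i], at + alen, read_len))
    }
    plant_n <- runif(n_reads) < n_rate
    n_n <- as.integer(ceiling(0.15 * read_len))   # 15% N > 10% threshold
    for (i in which(plant_n)) {
      at <- sample.int(read_len, n_n)
      s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      s[at] <- "N"
      seqs[i] <- paste(s, collapse = "")
    }
    plant_lowq <- runif(n_reads) < lowq_rate
    n_lq <- as.integer(ceiling(0.6 * read_len))   # 60% >= 50% threshold
    for (i in which(plant_lowq)) {
      at <- sample.int(read_len, n_lq)
      q <- utf8ToInt(quals[i]) - 33L
      q[at] <- sample(0:5, n_lq, replace = TRUE)
      quals[i] <- intToUtf8(q + 33L)
    }
    reads <- data.table(id = sprintf("read%06d", seq_len(n_reads)),
                        seq = seqs, qual = quals)

    # ground truth from the finished reads, with filter precedence
    has_adapter <- grepl(adapter, seqs, fixed = TRUE)
    n_frac <- (nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))) /
      nchar(seqs)
    lowq_frac <- vapply(quals, function(q) mean(utf8ToInt(q) - 33L <= 5L),
                        numeric(1), USE.NAMES = FALSE)
    rule <- rep("clean", n_reads)
    rule[has_adapter] <- "adapter"
    rule[rule == "clean" & n_frac > 0.10] <- "n"
    rule[rule == "clean" & lowq_frac >= 0.50] <- "lowq"
    truth <- list(adapter = sum(rule == "adapter"), n = sum(rule == "n"),
                  lowq = sum(rule == "lowq"), clean = sum(rule == "clean"))
    list(reads = reads, truth = truth)
  })
}

#' Simulate a per-gene expression table with optional linked DEGs
#'
#' Gene lengths are taken from the exon model; read counts are Poisson
#' around a log-normal per-gene mean. Genes named in `linkage` are
#' flagged as differentially expressed with the requested sign of the
#' log2 fold change; all other genes get small noise and deg = FALSE.
#'
#' @param gene_models a `gene_models` object.
#' @param linkage named character vector mapping gene_id to "up" or
#'   "down" (NULL or empty for a null table).
#' @param seed integer seed.
#' @param effect_log2fc mean |log2FC| of linked genes.
#' @return data.table: gene_id, length_bp (exon-model length),
#'   read_count, log2fc, deg.
#' @export
simulate_expression <- function(gene_models, linkage = NULL, seed = 1L,
                                effect_log2fc = 2) {
  g <- gene_models$genes
  exlen <- gene_models$exons[, .(length_bp = sum(end - start)), by = gene_id]
  if (length(linkage)) {
    if (is.null(names(linkage)) || !all(names(linkage) %in% g$gene_id))
      stop("linkage references unknown gene ids")
    if (!all(linkage %in% c("up", "down")))
      stop("linkage values must be 'up' or 'down'")
  }
  with_seed(seed, {
    n <- nrow(g)
    mu <- exp(rnorm(n, log(500), 1))
    out <- data.table(gene_id = g$gene_id)
    out <- merge(out, exlen, by = "gene_id", sort = FALSE)
    out[, read_count := rpois(n, mu)]
    out[, log2fc := rnorm(n, 0, 0.1)]
    out[, deg := FALSE]
    if (length(linkage)) {
      idx <- match(names(linkage), out$gene_id)
      sign <- ifelse(linkage == "up", 1, -1)
      out$log2fc[idx] <- sign * abs(rnorm(length(idx), effect_log2fc, 0.5))
      out$deg[idx] <- TRUE
    }
    setorder(out, gene_id)
    out[]
  })
}
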