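#' Classify cytosine contexts on both strands of a genome
#'
#' Every cytosine is assigned one of the three bisulfite sequence contexts,
#' read 5'->3' on the cytosine's own strand: the next base G gives CG,
#' otherwise a G two bases downstream gives CHG, otherwise CHH (H = A, C
#' or T). A plus-strand G marks a cytosine on the minus strand, classified
#' from the reverse complement. Sites lacking two downstream bases on
#' their strand, or with an N in the defining dinucleotide (CG) or
#' trinucleotide (CHG/CHH), are skipped and tallied.
#'
#' @param genome named character vector of chromosome sequences (or a
#'   `DNAStringSet`), alphabet A/C/G/T/N.
#' @return A `data.table` with columns `chrom`, `pos0` (0-based position
#'   of the cytosine on the plus-strand coordinate system), `strand`,
#'   `context` (CG/CHG/CHH) and `trinuc` (the 3 bases 5'->3' on the
#'   cytosine's strand), sorted by (chrom, pos0). The number of skipped
#'   sites is attached as attribute `n_skipped`.
#' @examples
#' call_contexts(c(chr1 = "TACGTAACTGA"))
#' @export
call_contexts <- function(genome) {
  genome <- as_genome(genome)
  skipped <- 0L
  res <- lapply(names(genome), function(chr) {
    s <- strsplit(genome[[chr]], "", fixed = TRUE)[[1]]
    L <- length(s)
    out <- list()

    # plus strand: C at i (1-based); defining bases at i+1, i+2
    i <- which(s == "C")
    n_edge <- sum(i > L - 2L)
    i <- i[i <= L - 2L]
    b1 <- s[i + 1L]; b2 <- s[i + 2L]
    drop <- b1 == "N" | (b1 != "G" & b2 == "N")
    skipped <<- skipped + n_edge + sum(drop)
    i <- i[!drop]; b1 <- b1[!drop]; b2 <- b2[!drop]
    if (length(i)) {
      out$plus <- data.table(
        chrom = chr, pos0 = i - 1L, strand = "+",
        context = fifelse(b1 == "G", "CG", fifelse(b2 == "G", "CHG", "CHH")),
        trinuc = paste0("C", b1, b2))
    }

    # minus strand: plus-strand G at i; defining bases at i-1, i-2
    j <- which(s == "G")
    n_edge <- sum(j < 3L)
    j <- j[j >= 3L]
    c1 <- COMPLEMENT[s[j - 1L]]; c2 <- COMPLEMENT[s[j - 2L]]
    drop <- c1 == "N" | (c1 != "G" & c2 == "N")
    skipped <<- skipped + n_edge + sum(drop)
    j <- j[!drop]; c1 <- c1[!drop]; c2 <- c2[!drop]
    if (length(j)) {
      out$minus <- data.table(
        chrom = chr, pos0 = j - 1L, strand = "-",
        context = fifelse(c1 == "G", "CG", fifelse(c2 == "G", "CHG", "CHH")),
        trinuc = paste0("C", c1, c2))
    }
    rbindlist(out)
  })
  ctx <- rbindlist(res)
  if (!nrow(ctx)) {
    ctx <- data.table(chrom = character(), pos0 = integer(),
                      strand = character(), context = character(),
                      trinuc = character())
  } else {
    setorder(ctx, chrom, pos0, strand)
  }
  setattr(ctx, "n_skipped", skipped)
  ctx[]
}
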