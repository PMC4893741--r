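## Readers and writers. External conventions: CX report and GFF3 are
## 1-based inclusive; BED is 0-based half-open; internal coordinates are
## 0-based half-open throughout.

#' Write a genome to FASTA
#' @param genome named character vector / DNAStringSet.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome(x)
}

#' Read a FASTQ file into a read table
#'
#' Minimal four-line-record FASTQ reader (plain or gzip). A record whose
#' sequence and quality strings differ in length aborts with the
#' offending record id.
#'
#' @param path FASTQ path (`.gz` handled transparently).
#' @return data.table with columns id, seq, qual.
#' @export
read_fastq <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ: ", length(lines), " lines")
  if (!length(lines))
    return(data.table(id = character(), seq = character(), qual = character()))
  ids <- lines[seq(1, length(lines), 4)]
  if (any(substr(ids, 1, 1) != "@")) stop("malformed FASTQ header line")
  reads <- data.table(id = sub("^@", "", sub("\\s.*$", "", ids)),
                      seq = toupper(lines[seq(2, length(lines), 4)]),
                      qual = lines[seq(4, length(lines), 4)])
  validate_reads(reads)
  reads
}

#' Write a read table to FASTQ
#' @param reads data.table with id, seq, qual.
#' @param path output path (`.gz` writes gzip).
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

CX_CONTEXTS <- c("CG", "CHG", "CHH")

#' Read a cytosine-report (CX) table
#'
#' Seven tab-separated columns: chrom, 1-based position, strand (+/-),
#' methylated count, unmethylated count, context (CG/CHG/CHH),
#' trinucleotide. Positions are converted to the internal 0-based
#' convention.
#'
#' @param path TSV path.
#' @return site data.table (chrom, pos0, strand, context, trinuc, mC,
#'   umC) sorted by (chrom, pos0).
#' @export
read_cx_report <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(
    character = c(1, 3, 6, 7), integer = c(2, 4, 5)))
  if (ncol(dt) != 7)
    stop("CX report must have 7 columns, found ", ncol(dt))
  setnames(dt, c("chrom", "pos", "strand", "mC", "umC", "context", "trinuc"))
  bad <- which(!dt$context %in% CX_CONTEXTS)
  if (length(bad))
    stop("unknown context '", dt$context[bad[1]], "' at line ", bad[1])
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    stop("unknown strand '", dt$strand[bad[1]], "' at line ", bad[1])
  bad <- which(dt$mC < 0 | dt$umC < 0 | dt$pos < 1)
  if (length(bad))
    stop("negative count or position at line ", bad[1])
  dt[, pos0 := pos - 1L][, pos := NULL]
  setcolorder(dt, c("chrom", "pos0", "strand", "context", "trinuc", "mC", "umC"))
  setorder(dt, chrom, pos0)
  dt[]
}

#' Write a site table as a CX report
#' @param sites site data.table.
#' @param path output path.
#' @export
write_cx_report <- function(sites, path) {
  assert_site_table(sites)
  out <- data.table(chrom = sites$chrom, pos = sites$pos0 + 1L,
                    strand = sites$strand, mC = sites$mC, umC = sites$umC,
                    context = sites$context,
                    trinuc = if ("trinuc" %in% names(sites)) sites$trinuc else ".")
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene, exon, five_prime_UTR and three_prime_UTR features with
#' ID/Parent attributes, 1-based inclusive coordinates.
#'
#' @param gene_models a `gene_models` object.
#' @param path output path.
#' @export
write_gene_models <- function(gene_models, path) {
  g <- gene_models$genes
  rows <- list(
    data.table(chrom = g$chrom, type = "gene", start = g$start + 1L,
               end = g$end, strand = g$strand,
               attr = paste0("ID=", g$gene_id))
  )
  add <- function(dt, type) {
    if (is.null(dt) || !nrow(dt)) return(NULL)
    data.table(chrom = g$chrom[match(dt$gene_id, g$gene_id)], type = type,
               start = dt$start + 1L, end = dt$end,
               strand = g$strand[match(dt$gene_id, g$gene_id)],
               attr = paste0("Parent=", dt$gene_id))
  }
  rows$exon <- add(gene_models$exons, "exon")
  rows$utr5 <- add(gene_models$utr5, "five_prime_UTR")
  rows$utr3 <- add(gene_models$utr3, "three_prime_UTR")
  dt <- rbindlist(rows)
  setorder(dt, chrom, start)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tbsmeth\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     dt$chrom, dt$type, dt$start, dt$end, dt$strand, dt$attr),
             con)
  invisible(path)
}

#' Read gene models from a GFF3 subset
#'
#' Expects gene features with ID attributes and exon /
#' five_prime_UTR / three_prime_UTR features with Parent attributes.
#'
#' @param path GFF3 path.
#' @return a `gene_models` object (0-based half-open internally).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  parent <- if ("Parent" %in% names(md))
    vapply(md$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  else rep(NA_character_, length(gr))
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   type = type,
                   id = if ("ID" %in% names(md)) as.character(md$ID)
                        else NA_character_,
                   parent = parent)
  genes <- dt[type == "gene",
              .(gene_id = id, chrom, strand, start, end)]
  pick <- function(t) {
    x <- dt[type == t, .(gene_id = parent, start, end)]
    setorder(x, gene_id, start)
    x
  }
  out <- list(genes = genes[order(gene_id)], exons = pick("exon"),
              utr5 = pick("five_prime_UTR"), utr3 = pick("three_prime_UTR"))
  class(out) <- "gene_models"
  out
}

#' Write an expression table to TSV
#' @param expression data.table (gene_id, length_bp, read_count,
#'   log2fc, deg).
#' @param path output path.
#' @export
write_expression <- function(expression, path) {
  fwrite(as.data.table(expression), path, sep = "\t")
  invisible(path)
}

#' Read an expression table from TSV
#' @param path TSV with header gene_id, length_bp, read_count, log2fc,
#'   deg.
#' @return data.table.
#' @export
read_expression <- function(path) {
  e <- fread(path, sep = "\t")
  need <- c("gene_id", "length_bp", "read_count", "log2fc", "deg")
  if (!all(need %in% names(e)))
    stop("expression table needs columns: ", paste(need, collapse = ", "))
  e[, deg := as.logical(deg)]
  e[]
}

#' Write DMRs as BED6+ with name context:direction and score
#'   -10*log10(q_min)
#' @param dmrs DMR data.table.
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- ifelse(dmrs$q_min > 0,
                  pmin(round(-10 * log10(dmrs$q_min)), 1000L), 1000L)
  bed <- data.table(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    name = paste0(dmrs$context, ":", dmrs$direction),
                    score = score, strand = ".",
                    ml_a = signif(dmrs$ml_a, 6), ml_b = signif(dmrs$ml_b, 6),
                    fold_change = signif(dmrs$fold_change, 6))
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
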