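## Internal helpers: RNG scoping, sequence ops, validation.

# Run code with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("seed must be coercible to integer")
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Stable per-stage seed derivation from one top-level seed (kept < 2^31).
derive_seed <- function(seed, stage) {
  offsets <- c(genome = 11L, genes = 23L, methylome = 37L, counts_a = 41L,
               counts_b = 43L, spike = 53L, expression = 61L, reads = 71L,
               dmr_plan = 83L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 97L + off) %% 2147483587)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Accept a named character vector or a Biostrings::DNAStringSet.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    genome <- out
  }
  if (!is.character(genome) || is.null(names(genome)) || any(names(genome) == ""))
    stop("genome must be a named character vector or DNAStringSet")
  toupper(genome)
}

genome_lengths <- function(genome) {
  genome <- as_genome(genome)
  setNames(nchar(genome), names(genome))
}

stopifnot_prob <- function(x, what, open_right = FALSE) {
  ok <- is.numeric(x) & !is.na(x) & x >= 0 & (if (open_right) x < 1 else x <= 1)
  if (!all(ok)) stop(what, " must lie in [0,1", if (open_right) ")" else "]")
  invisible(x)
}

assert_site_table <- function(sites) {
  need <- c("chrom", "pos0", "strand", "context", "mC", "umC")
  if (!is.data.frame(sites) || !all(need %in% names(sites)))
    stop("site table must contain columns: ", paste(need, collapse = ", "))
  invisible(sites)
}
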