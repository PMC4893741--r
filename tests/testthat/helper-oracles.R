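## Independent oracles and small fixture builders shared by the suite.

# Brute-force two-strand context scan: walks every position of the
# sequence character-by-character, independent of call_contexts().
oracle_contexts <- function(seq_str, chrom = "chr1") {
  s <- strsplit(toupper(seq_str), "", fixed = TRUE)[[1]]
  L <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rows <- list()
  for (i in seq_len(L)) {
    if (s[i] == "C" && i + 2 <= L) {
      b1 <- s[i + 1]; b2 <- s[i + 2]
      ctx <- if (b1 == "N") NA
      else if (b1 == "G") "CG"
      else if (b2 == "N") NA
      else if (b2 == "G") "CHG" else "CHH"
      if (!is.na(ctx))
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, pos0 = i - 1L, strand = "+", context = ctx)
    }
    if (s[i] == "G" && i - 2 >= 1) {
      b1 <- comp[[s[i - 1]]]; b2 <- comp[[s[i - 2]]]
      ctx <- if (b1 == "N") NA
      else if (b1 == "G") "CG"
      else if (b2 == "N") NA
      else if (b2 == "G") "CHG" else "CHH"
      if (!is.na(ctx))
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, pos0 = i - 1L, strand = "-", context = ctx)
    }
  }
  do.call(rbind, rows)
}

# Exhaustive two-sided Fisher p via log-binomial coefficients (no
# dhyper), with the same 1e-7 tie slack as the contract.
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  sup <- max(0, k - n):min(k, m)
  lp <- lchoose(m, sup) + lchoose(n, k - sup) - lchoose(m + n, k)
  pr <- exp(lp)
  po <- pr[sup == a]
  min(1, sum(pr[pr <= po * (1 + 1e-7)]))
}

# Step-up BH computed from the definition (sort, scale, cummin, map back).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Pearson r from the definition.
oracle_pearson <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) / (sqrt(mean((x - mean(x))^2)) *
                                           sqrt(mean((y - mean(y))^2)))
}

# Type-7 quantile from the definition (order statistics + interpolation).
oracle_quantile <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

# A tiny deterministic site table.
make_sites <- function(pos0, mC, umC, context = "CG", strand = "+",
                       chrom = "chr1") {
  data.table::data.table(chrom = chrom, pos0 = as.integer(pos0),
                         strand = strand, context = context,
                         trinuc = "CGA", mC = as.integer(mC),
                         umC = as.integer(umC))
}
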