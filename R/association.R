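#' Reads per kilobase of exon model per million mapped reads
#'
#' @param read_count reads mapped to the gene.
#' @param gene_length_bp exon-model length in bp (> 0).
#' @param total_mapped_reads library size (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(read_count, gene_length_bp, total_mapped_reads) {
  if (any(gene_length_bp <= 0)) stop("gene length must be > 0")
  if (any(total_mapped_reads <= 0)) stop("total mapped reads must be > 0")
  read_count / ((gene_length_bp / 1000) * (total_mapped_reads / 1e6))
}

#' Split differentially expressed genes into high and low expression classes
#'
#' DEGs are split at the median RPKM of the DEG set: strictly above the
#' median is "high", at or below is "low"; non-DEGs get "none". Set
#' `split = "abs-log2fc"` to split on |log2FC| instead.
#'
#' @param expression data.table with gene_id, length_bp, read_count,
#'   log2fc, deg (see [simulate_expression()] / [read_expression()]).
#' @param split "median-rpkm" (default) or "abs-log2fc".
#' @return the table with added columns rpkm_value and expr_class.
#' @export
classify_degs <- function(expression, split = c("median-rpkm", "abs-log2fc")) {
  split <- match.arg(split)
  e <- as.data.table(expression)
  need <- c("gene_id", "length_bp", "read_count", "log2fc", "deg")
  if (!all(need %in% names(e)))
    stop("expression table needs columns: ", paste(need, collapse = ", "))
  e <- copy(e)
  e[, rpkm_value := rpkm(read_count, length_bp, sum(read_count))]
  e[, expr_class := "none"]
  if (!any(e$deg)) {
    warning("no DEGs in expression table; classes are empty")
    return(e[])
  }
  val <- if (split == "median-rpkm") e$rpkm_value else abs(e$log2fc)
  med <- median(val[e$deg])
  e[deg == TRUE, expr_class := fifelse(val[e$deg] > med, "high", "low")]
  e[]
}

#' Overlap between differentially methylated and differentially expressed genes
#'
#' @param dmg_ids,deg_ids character vectors of gene ids.
#' @return list: n_dmg_only, n_deg_only, n_overlap, overlap (sorted
#'   ids), n_union.
#' @export
overlap_dmg_deg <- function(dmg_ids, deg_ids) {
  dmg_ids <- unique(as.character(dmg_ids))
  deg_ids <- unique(as.character(deg_ids))
  ov <- sort(intersect(dmg_ids, deg_ids))
  list(n_dmg_only = length(setdiff(dmg_ids, deg_ids)),
       n_deg_only = length(setdiff(deg_ids, dmg_ids)),
       n_overlap = length(ov), overlap = ov,
       n_union = length(union(dmg_ids, deg_ids)))
}

#' Pearson correlation between methylation and expression quantities
#'
#' Thin, validated wrapper around the standard Pearson product-moment
#' correlation; the pipeline applies it to (promoter methylation
#' difference, log2 fold change) pairs over genes present in both the
#' DMG and expression sets.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  cor(x, y, method = "pearson")
}

#' Promoter methylation difference per gene between two groups
#'
#' Pools calls over each gene's promoter interval(s) per group and
#' returns the corrected-level difference (group B minus group A).
#'
#' @param sites_a,sites_b site tables.
#' @param features `feature_intervals`.
#' @param r_a,r_b non-conversion rates.
#' @return data.table: gene_id, ml_a, ml_b, delta.
#' @export
promoter_ml_diff <- function(sites_a, sites_b, features, r_a = 0, r_b = 0) {
  pool <- function(sites, r) {
    h <- site_feature_hits(sites, features)[region == "promoter"]
    h[, .(ml = correct_ml(sum(mC) / max(sum(mC) + sum(umC), 1L), r)),
      by = gene_id]
  }
  a <- pool(sites_a, r_a); b <- pool(sites_b, r_b)
  setnames(a, "ml", "ml_a"); setnames(b, "ml", "ml_b")
  m <- merge(a, b, by = "gene_id")
  m[, delta := ml_b - ml_a]
  m[]
}

#' Metagene profiles stratified by DEG expression class
#'
#' Computes [metagene_profile()] separately for the genes of each
#' expression class ("high", "low") and each group's site table.
#'
#' @param sites_a,sites_b site tables for groups A and B.
#' @param features `feature_intervals`.
#' @param classified expression table with expr_class
#'   ([classify_degs()]).
#' @param r_a,r_b non-conversion rates.
#' @param n_bins bins per element (default 20).
#' @return data.table: expr_class, group, region, context, bin, mC,
#'   umC, n_sites, ml. Classes with no genes contribute no rows.
#' @export
class_profiles <- function(sites_a, sites_b, features, classified,
                           r_a = 0, r_b = 0, n_bins = 20L) {
  out <- list()
  for (cl in c("high", "low")) {
    ids <- classified$gene_id[classified$expr_class == cl]
    if (!length(ids)) next
    sub <- features
    sub$intervals <- features$intervals[gene_id %in% ids]
    for (grp in c("A", "B")) {
      sites <- if (grp == "A") sites_a else sites_b
      r <- if (grp == "A") r_a else r_b
      prof <- metagene_profile(sites, sub, r = r, n_bins = n_bins)
      if (nrow(prof)) {
        prof[, `:=`(expr_class = cl, group = grp)]
        out[[paste(cl, grp)]] <- prof
      }
    }
  }
  res <- rbindlist(out)
  if (nrow(res))
    setcolorder(res, c("expr_class", "group", "region", "context", "bin"))
  res
}
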