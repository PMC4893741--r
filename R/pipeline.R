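#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate
#' the study conditions: high CG methylation with very low non-CG
#' methylation (control-group regime), a small non-conversion rate, and
#' moderate shotgun depth.
#'
#' @param genome_length_bp genome length (default 500000).
#' @param gc_fraction genome GC content (default 0.4).
#' @param n_genes number of genes (default 20).
#' @param mean_depth mean per-site read depth (default 20).
#' @param r true bisulfite non-conversion rate (default 0.005).
#' @param baselines per-context baseline rates, shared or per group
#'   (see [plant_methylomes()]); default Table-2-style control regime
#'   c(CG = 0.6762, CHG = 0.0059, CHH = 0.0058) for both groups.
#' @param n_dmrs,dmr_width,dmr_rate_a,dmr_rate_b,dmr_context planted
#'   DMR plan (n_dmrs = 0 for a null simulation).
#' @param n_spike_positions spike-in cytosine positions (default 5000).
#' @param spike_depth spike-in mean depth (default 20).
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length_bp = 500000L, gc_fraction = 0.4,
                       n_genes = 20L, mean_depth = 20, r = 0.005,
                       baselines = c(CG = 0.6762, CHG = 0.0059, CHH = 0.0058),
                       n_dmrs = 0L, dmr_width = 2000L, dmr_rate_a = 0.6,
                       dmr_rate_b = 0.1, dmr_context = "CG",
                       n_spike_positions = 5000L, spike_depth = 20,
                       seed = 1L) {
  stopifnot_prob(r, "r", open_right = TRUE)
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  cfg <- list(genome_length_bp = as.integer(genome_length_bp),
              gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
              mean_depth = mean_depth, r = r, baselines = baselines,
              n_dmrs = as.integer(n_dmrs), dmr_width = as.integer(dmr_width),
              dmr_rate_a = dmr_rate_a, dmr_rate_b = dmr_rate_b,
              dmr_context = dmr_context,
              n_spike_positions = as.integer(n_spike_positions),
              spike_depth = spike_depth, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a complete synthetic dataset
#'
#' Runs every generator with seeds derived from the master seed:
#' genome, gene models, true methylomes with planted DMRs, per-group
#' site tables, spike-in table, and expression table.
#'
#' @param config a [sim_config()].
#' @param linkage optional DEG linkage passed to
#'   [simulate_expression()].
#' @return list: genome, gene_models, truth (plant_methylomes output),
#'   sites_a, sites_b, spike_in, expression, config.
#' @export
simulate_dataset <- function(config = sim_config(), linkage = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- generate_genome(config$genome_length_bp, config$gc_fraction,
                            seed = derive_seed(config$seed, "genome"))
  gm <- generate_gene_models(genome, config$n_genes,
                             seed = derive_seed(config$seed, "genes"))
  plan <- if (config$n_dmrs > 0)
    plan_dmrs(genome, config$n_dmrs, config$dmr_width, config$dmr_rate_a,
              config$dmr_rate_b, config$dmr_context,
              seed = derive_seed(config$seed, "dmr_plan"))
  else NULL
  truth <- plant_methylomes(genome, config$baselines, plan)
  sites_a <- simulate_site_counts(truth$truth_a, config$mean_depth, config$r,
                                  seed = derive_seed(config$seed, "counts_a"))
  sites_b <- simulate_site_counts(truth$truth_b, config$mean_depth, config$r,
                                  seed = derive_seed(config$seed, "counts_b"))
  spike <- simulate_spike_in(config$n_spike_positions, config$spike_depth,
                             config$r, seed = derive_seed(config$seed, "spike"))
  expression <- simulate_expression(gm, linkage,
                                    seed = derive_seed(config$seed, "expression"))
  list(genome = genome, gene_models = gm, truth = truth,
       sites_a = sites_a, sites_b = sites_b, spike_in = spike,
       expression = expression, config = config)
}

#' Write a simulated dataset to disk in standard formats
#'
#' FASTA genome, GFF3 gene models, CX-report site tables, spike-in CX
#' report, expression TSV, and the planted truth as BED + JSON.
#'
#' @param ds output of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return named vector of file paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.gff3"),
             sites_a = file.path(dir, "sites_A.cx.tsv"),
             sites_b = file.path(dir, "sites_B.cx.tsv"),
             spike = file.path(dir, "spike_in.cx.tsv"),
             expression = file.path(dir, "expression.tsv"),
             truth_bed = file.path(dir, "planted_dmrs.bed"),
             truth_json = file.path(dir, "truth.json"))
  write_fasta(ds$genome, paths["genome"])
  write_gene_models(ds$gene_models, paths["genes"])
  write_cx_report(ds$sites_a, paths["sites_a"])
  write_cx_report(ds$sites_b, paths["sites_b"])
  write_cx_report(ds$spike_in, paths["spike"])
  write_expression(ds$expression, paths["expression"])
  plan <- ds$truth$dmrs
  if (!is.null(plan) && nrow(plan)) {
    fwrite(data.table(plan$chrom, plan$start, plan$end,
                      paste0(plan$context, ":", plan$direction), 0L, "."),
           paths["truth_bed"], sep = "\t", col.names = FALSE)
  } else {
    file.create(paths["truth_bed"])
  }
  jsonlite::write_json(list(config = unclass(ds$config),
                            planted_dmrs = if (is.null(plan)) list() else plan),
                       paths["truth_json"], auto_unbox = TRUE, digits = NA)
  paths
}

#' Run the full comparative methylome pipeline on files
#'
#' Stages: read inputs, estimate the non-conversion rate from the
#' spike-in, genome summaries per group, 3000/600 window methylation,
#' functional regions and 20-bin metagene profiles, 1000/100 window
#' Fisher tests with BH FDR and filters, DMR merging, DMG assignment,
#' DEG classification and DMG x DEG association. All outputs plus a run
#' manifest (config snapshot, file checksums, skipped-site tallies) are
#' written under `out_dir`.
#'
#' @param genome_fa,genes_gff3,cx_a,cx_b,cx_spike,expression_tsv input
#'   paths.
#' @param out_dir output directory.
#' @param ml_window,ml_step estimation window geometry (3000/600).
#' @param dmr_window,dmr_step DMR window geometry (1000/100).
#' @param q_max,min_depth,min_fc DMR thresholds.
#' @param promoter_len promoter length (2000).
#' @param n_bins metagene bins (20).
#' @return the manifest (invisibly also written as manifest.json).
#' @export
run_pipeline <- function(genome_fa, genes_gff3, cx_a, cx_b, cx_spike,
                         expression_tsv, out_dir,
                         ml_window = 3000L, ml_step = 600L,
                         dmr_window = 1000L, dmr_step = 100L,
                         q_max = 0.05, min_depth = 5, min_fc = 2,
                         promoter_len = 2000L, n_bins = 20L) {
  ins <- c(genome_fa, genes_gff3, cx_a, cx_b, cx_spike, expression_tsv)
  missing <- ins[!file.exists(ins)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  genome <- read_fasta(genome_fa)
  gm <- read_gene_models(genes_gff3)
  sites_a <- read_cx_report(cx_a)
  sites_b <- read_cx_report(cx_b)
  spike <- read_cx_report(cx_spike)
  expression <- read_expression(expression_tsv)

  nc <- estimate_nonconversion(spike)
  r <- nc$r

  summ_a <- genome_summary(sites_a, r = r)
  summ_b <- genome_summary(sites_b, r = r)

  wml_a <- window_ml(sites_a, genome, ml_window, ml_step, r = r)
  wml_b <- window_ml(sites_b, genome, ml_window, ml_step, r = r)

  features <- derive_regions(gm, genome, promoter_len)
  reg_a <- region_levels(sites_a, features, r = r)
  reg_b <- region_levels(sites_b, features, r = r)
  prof_a <- metagene_profile(sites_a, features, r = r, n_bins = n_bins)
  prof_b <- metagene_profile(sites_b, features, r = r, n_bins = n_bins)

  wt <- window_tests(sites_a, sites_b, genome, dmr_window, dmr_step,
                     r_a = r, r_b = r)
  dmrs <- filter_and_merge(wt, sites_a, sites_b, q_max, min_depth, min_fc,
                           r_a = r, r_b = r)
  dmg <- assign_dmgs(dmrs, features)

  classified <- suppressWarnings(classify_degs(expression))
  deg_ids <- classified$gene_id[classified$deg]
  ov <- overlap_dmg_deg(dmg$dmgs$gene_id, deg_ids)
  pdiff <- promoter_ml_diff(sites_a, sites_b, features, r, r)
  assoc <- merge(pdiff, classified[, .(gene_id, log2fc)], by = "gene_id")
  assoc_r <- if (nrow(assoc) >= 3 && stats::sd(assoc$delta) > 0 &&
                 stats::sd(assoc$log2fc) > 0)
    pearson_assoc(assoc$delta, assoc$log2fc) else NA_real_
  cprof <- class_profiles(sites_a, sites_b, features, classified, r, r, n_bins)

  out <- c(nonconversion = "nonconversion.json",
           summary_a = "genome_summary_A.json",
           summary_b = "genome_summary_B.json",
           window_ml_a = "window_ml_A.tsv", window_ml_b = "window_ml_B.tsv",
           region_levels_a = "region_levels_A.tsv",
           region_levels_b = "region_levels_B.tsv",
           profiles_a = "metagene_A.tsv", profiles_b = "metagene_B.tsv",
           window_tests = "dmr_window_tests.tsv", dmrs = "dmrs.bed",
           dmgs = "dmgs.tsv", region_distribution = "dmr_region_distribution.tsv",
           overlap = "dmg_deg_overlap.json", class_profiles = "class_profiles.tsv")
  p <- function(k) file.path(out_dir, out[[k]])
  jsonlite::write_json(nc, p("nonconversion"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(summ_a, p("summary_a"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(summ_b, p("summary_b"), auto_unbox = TRUE, digits = NA)
  fwrite(wml_a, p("window_ml_a"), sep = "\t")
  fwrite(wml_b, p("window_ml_b"), sep = "\t")
  fwrite(reg_a, p("region_levels_a"), sep = "\t")
  fwrite(reg_b, p("region_levels_b"), sep = "\t")
  fwrite(prof_a, p("profiles_a"), sep = "\t")
  fwrite(prof_b, p("profiles_b"), sep = "\t")
  fwrite(wt, p("window_tests"), sep = "\t")
  write_dmr_bed(dmrs, p("dmrs"))
  fwrite(dmg$dmgs, p("dmgs"), sep = "\t")
  fwrite(dmg$region_distribution, p("region_distribution"), sep = "\t")
  jsonlite::write_json(c(ov[names(ov) != "overlap"],
                         list(overlap = ov$overlap,
                              pearson_r = assoc_r)),
                       p("overlap"), auto_unbox = TRUE, digits = NA)
  fwrite(cprof, p("class_profiles"), sep = "\t")

  files <- vapply(names(out), p, character(1))
  manifest <- list(
    inputs = as.list(setNames(unname(tools::md5sum(ins)), basename(ins))),
    outputs = as.list(setNames(unname(tools::md5sum(files)), basename(files))),
    parameters = list(ml_window = ml_window, ml_step = ml_step,
                      dmr_window = dmr_window, dmr_step = dmr_step,
                      q_max = q_max, min_depth = min_depth, min_fc = min_fc,
                      promoter_len = promoter_len, n_bins = n_bins,
                      r_estimate = r),
    tallies = list(windows_skipped = attr(wt, "n_skipped"),
                   n_dmrs = nrow(dmrs), n_dmgs = nrow(dmg$dmgs),
                   n_degs = length(deg_ids), n_overlap = ov$n_overlap))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
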