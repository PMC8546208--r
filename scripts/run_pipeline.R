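#!/usr/bin/env Rscript

# Thin command-line wrapper over the package: simulates a study (or loads
# existing tables) and runs the complete per-region and cross-region
# analysis chain, writing every result table as TSV.
#
#   Rscript scripts/run_pipeline.R --out results/pipeline [--seed 1]
#     [--proteins path --phospho path --acetyl path --samples path
#      --phospho-annotation path --acetyl-annotation path]
#     [--gmt sets.gmt] [--accessions list.txt]

suppressPackageStartupMessages({
  library(adproteo)
  library(optparse)
})

opt <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "pipeline_out"),
  make_option("--n-proteins", type = "integer", default = 2000L,
              dest = "n_proteins"),
  make_option("--n-phospho", type = "integer", default = 2000L,
              dest = "n_phospho"),
  make_option("--n-acetyl", type = "integer", default = 221L,
              dest = "n_acetyl"),
  make_option("--proteins", type = "character", default = NULL),
  make_option("--phospho", type = "character", default = NULL),
  make_option("--acetyl", type = "character", default = NULL),
  make_option("--samples", type = "character", default = NULL),
  make_option("--phospho-samples", type = "character", default = NULL,
              dest = "phospho_samples",
              help = "replicate-expanded sample table for the phospho layer"),
  make_option("--phospho-annotation", type = "character", default = NULL,
              dest = "phospho_annotation"),
  make_option("--acetyl-annotation", type = "character", default = NULL,
              dest = "acetyl_annotation"),
  make_option("--gmt", type = "character", default = NULL),
  make_option("--accessions", type = "character", default = NULL),
  make_option("--n-perm", type = "integer", default = 500L, dest = "n_perm")
)))

gene_sets <- if (!is.null(opt$gmt)) read_gmt(opt$gmt) else NULL

if (is.null(opt$proteins)) {
  cfg <- sim_config(n_proteins = opt$n_proteins, n_phospho = opt$n_phospho,
                    n_acetyl_sites = opt$n_acetyl, seed = opt$seed)
  res <- run_pipeline(cfg, out_dir = opt$out, gene_sets = gene_sets,
                      annotation_list = opt$accessions, n_perm = opt$n_perm)
  cat("simulated study written and analysed under", opt$out, "\n")
} else {
  # analysis of user-supplied tables: per-region preprocessing +
  # differential for each layer, trajectories and enrichment when all four
  # regions are present
  samples <- read_sample_table(opt$samples)
  protein <- read_intensity_matrix(opt$proteins, "protein", samples = samples)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  regions <- intersect(brain_regions(), unique(samples$region))
  prot <- list()
  for (r in regions) {
    pp <- preprocess_region(protein, samples, r, seed = opt$seed)
    prot[[r]] <- pp
    d <- run_differential(pp$imputed, pp$samples)
    write.table(d, file.path(opt$out, sprintf("differential_protein_%s.tsv", r)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(pp$qualitative,
                file.path(opt$out, sprintf("qualitative_protein_%s.tsv", r)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(test_group_balance(samples, r),
                file.path(opt$out, sprintf("balance_%s.tsv", r)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(opt$phospho)) {
    ann <- read.delim(opt$phospho_annotation, stringsAsFactors = FALSE)
    ph_samples <- if (!is.null(opt$phospho_samples))
      read_sample_table(opt$phospho_samples) else samples
    phospho <- read_intensity_matrix(opt$phospho, "phosphopeptide",
                                     samples = ph_samples)
    for (r in regions) {
      ph <- preprocess_region(phospho, ph_samples, r, seed = opt$seed + 1L)
      write.table(run_differential(ph$imputed, ph$samples),
                  file.path(opt$out, sprintf("differential_phospho_%s.tsv", r)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      st <- suppressWarnings(
        compute_phospho_state(ph$normalized, prot[[r]]$normalized, ann))
      v <- compute_validity(st, prot[[r]]$samples)
      keep <- filter_quantitative(v)
      imp <- impute_downshifted_normal(
        st[keep$feature_id[keep$status != "excluded"], , drop = FALSE],
        seed = opt$seed + 2L)
      write.table(run_differential(imp, prot[[r]]$samples),
                  file.path(opt$out,
                            sprintf("differential_phospho_state_%s.tsv", r)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(opt$acetyl)) {
    ann <- read.delim(opt$acetyl_annotation, stringsAsFactors = FALSE)
    acetyl <- read_intensity_matrix(opt$acetyl, "acetyl", samples = samples)
    for (r in regions) {
      cols <- intersect(colnames(acetyl),
                        samples$sample_id[samples$region == r])
      ratios <- compute_stoichiometry(acetyl[, cols, drop = FALSE], ann)
      write.table(compare_stoichiometry(ratios, samples),
                  file.path(opt$out, sprintf("stoichiometry_tests_%s.tsv", r)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (length(regions) == 4L) {
    traj <- run_trajectory(lapply(prot, `[[`, "imputed"), samples)
    write.table(traj$records, file.path(opt$out, "trajectory.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(gene_sets)) {
      metric <- traj$medians[, "PRC"] - traj$medians[, "HP"]
      write.table(prerank_gsea(metric, gene_sets, n_perm = opt$n_perm,
                               seed = opt$seed),
                  file.path(opt$out, "gsea.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(opt$accessions)) {
    ann_rep <- annotate_against_list(
      lapply(prot, function(p) rownames(p$imputed)), opt$accessions)
    write.table(ann_rep$status, file.path(opt$out, "annotation_status.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cat("analysis written under", opt$out, "\n")
}
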