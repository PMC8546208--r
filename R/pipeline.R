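#' Run the complete analysis pipeline on a synthetic study
#'
#' End-to-end chain over all three omic layers and all regions: simulation,
#' per-region pre-processing (replicate merging, normalisation, validity
#' filtering, imputation), cohort-balance tests, differential abundance with
#' covariate screening, phosphorylation-state quantification and its own
#' differential chain, acetylation stoichiometry with group comparison,
#' cross-region trajectory analysis of the protein layer, pre-ranked GSEA
#' on a cross-region fold-change difference, and accession-list annotation.
#'
#' When no gene sets or annotation list are supplied, small synthetic ones
#' are constructed from the simulated features (one set per spike direction
#' plus random sets) so the enrichment and annotation steps are always
#' exercised; supply real GMT/accession inputs to override.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV.
#' @param gene_sets Optional named list of gene sets (see [read_gmt()]).
#' @param annotation_list Optional accession vector or file path.
#' @param gsea_regions Length-2 region pair; the GSEA ranking metric is the
#'   median fold-change difference `first - second`.
#' @param n_perm GSEA permutations.
#' @return Nested list with `sim`, per-region `protein`, `phospho`,
#'   `phospho_state` (each: preprocessing + differential), `balance`,
#'   `stoichiometry`, `trajectory`, `gsea`, `annotation`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         gene_sets = NULL, annotation_list = NULL,
                         gsea_regions = c("PRC", "HP"), n_perm = 500L) {
  sim <- simulate_study(config)
  regions <- config$regions
  seed <- config$seed

  protein <- list()
  phospho <- list()
  state <- list()
  balance <- list()
  stoich <- list()
  for (r in regions) {
    pp <- preprocess_region(sim$protein$matrix, sim$cohort, r,
                            seed = seed + 11L)
    protein[[r]] <- c(pp, list(
      differential = run_differential(pp$imputed, pp$samples)))

    ph <- preprocess_region(sim$phospho$matrix, sim$phospho$samples, r,
                            seed = seed + 12L)
    phospho[[r]] <- c(ph, list(
      differential = run_differential(ph$imputed, ph$samples)))

    st_mat <- suppressWarnings(
      compute_phospho_state(ph$normalized, pp$normalized,
                            sim$phospho$annotation))
    st <- .filter_impute(st_mat, pp$samples,
                         on_threshold = 0.70, off_threshold = 0.10,
                         min_valid = 0.66, absent_max = 0.33,
                         width = 0.3, downshift = 1.8, seed = seed + 13L)
    state[[r]] <- c(list(state = st_mat), st, list(
      differential = run_differential(st$imputed, pp$samples)))

    balance[[r]] <- test_group_balance(sim$cohort, r)

    ac_cols <- sim$cohort$sample_id[sim$cohort$region == r]
    ratios <- compute_stoichiometry(sim$acetyl$matrix[, ac_cols, drop = FALSE],
                                    sim$acetyl$annotation)
    stoich[[r]] <- list(ratios = ratios,
                        tests = compare_stoichiometry(ratios, sim$cohort))
  }
  balance <- do.call(rbind, balance)

  trajectory <- NULL
  gsea <- NULL
  annotation <- NULL
  if (length(regions) == 4L) {
    imputed <- lapply(protein, `[[`, "imputed")
    trajectory <- run_trajectory(imputed, sim$cohort)

    stopifnot(all(gsea_regions %in% regions))
    metric <- trajectory$medians[, gsea_regions[1]] -
      trajectory$medians[, gsea_regions[2]]
    if (is.null(gene_sets))
      gene_sets <- .demo_gene_sets(names(metric), sim$protein$truth, seed)
    gsea <- prerank_gsea(metric, gene_sets, n_perm = n_perm,
                         seed = seed + 21L)

    if (is.null(annotation_list))
      annotation_list <- withr::with_seed(
        seed + 22L, sample(rownames(sim$protein$matrix),
                           min(40L, nrow(sim$protein$matrix))))
    annotation <- annotate_against_list(
      lapply(protein, function(p) rownames(p$imputed)),
      annotation_list,
      results = lapply(protein, `[[`, "differential"),
      list_name = "demo")
  }

  out <- list(sim = sim, protein = protein, phospho = phospho,
              phospho_state = state, balance = balance,
              stoichiometry = stoich, trajectory = trajectory,
              gsea = gsea, annotation = annotation)
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

## Demonstration gene sets built from the simulated features: the up- and
## down-spiked features form two coherent sets, padded with random sets.
.demo_gene_sets <- function(universe, truth, seed) {
  withr::with_seed(seed + 20L, {
    up <- intersect(truth$de$feature_id[truth$de$log2fc > 0], universe)
    dn <- intersect(truth$de$feature_id[truth$de$log2fc < 0], universe)
    sets <- list(spiked_up = up, spiked_down = dn)
    for (i in 1:8)
      sets[[sprintf("random_%02d", i)]] <-
        sample(universe, min(50L, length(universe)))
    sets[lengths(sets) > 0]
  })
}

.write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_sample_table(out$sim$cohort, file.path(out_dir, "samples.tsv"))
  wt(out$balance, "balance.tsv")
  for (r in names(out$protein)) {
    wt(out$protein[[r]]$differential, sprintf("differential_protein_%s.tsv", r))
    wt(out$protein[[r]]$qualitative, sprintf("qualitative_protein_%s.tsv", r))
    wt(out$protein[[r]]$quantitative, sprintf("filter_protein_%s.tsv", r))
    wt(out$phospho[[r]]$differential, sprintf("differential_phospho_%s.tsv", r))
    wt(out$phospho_state[[r]]$differential,
       sprintf("differential_phospho_state_%s.tsv", r))
    wt(out$stoichiometry[[r]]$tests, sprintf("stoichiometry_tests_%s.tsv", r))
    ratios <- out$stoichiometry[[r]]$ratios
    wt(data.frame(site_key = rownames(ratios), ratios, check.names = FALSE),
       sprintf("stoichiometry_ratios_%s.tsv", r))
  }
  if (!is.null(out$trajectory)) wt(out$trajectory$records, "trajectory.tsv")
  if (!is.null(out$gsea)) wt(out$gsea, "gsea.tsv")
  if (!is.null(out$annotation)) {
    wt(out$annotation$status, "annotation_status.tsv")
    wt(data.frame(region = names(out$annotation$n_detected),
                  n_detected = as.integer(out$annotation$n_detected),
                  n_all_regions = out$annotation$n_all_regions),
       "annotation_counts.tsv")
  }
  invisible(out_dir)
}
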