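#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the generator. The defaults reproduce the study
#' design the pipeline targets: 11 AD and 12 control brains sampled in four
#' regions, log-normal intensities, group effects attenuating along the
#' anatomical progression, abundance-dependent (MNAR) dropout, and paired
#' endogenous/heavy acetylation channels with known occupancy.
#'
#' @param n_ad_brains,n_control_brains Number of brains per disease group.
#' @param regions Regions sampled per brain (subset of [brain_regions()]).
#' @param n_proteins,n_phospho,n_acetyl_sites Feature counts per layer.
#' @param frac_de Fraction of protein (and, via `phospho_frac_de`,
#'   phosphopeptide and acetyl) features carrying a true group effect.
#' @param effect_log2fc True absolute log2 fold change of spiked features in
#'   the reference region (HP); attenuated by `region_effects` elsewhere.
#' @param sd_noise Residual log2-scale standard deviation.
#' @param region_effects Named multipliers applied to the group effect per
#'   region, creating monotone cross-region trajectories.
#' @param covariate_effects Named slopes (per unit of the centred covariate)
#'   applied to confounded features; `sex` is coded 0/1, `age` in years,
#'   `pmi` in hours.
#' @param frac_confounded Fraction of features receiving the covariate
#'   slopes (disjoint from the spiked set).
#' @param mnar_strength Steepness (>= 0) of the logistic dependence of
#'   dropout on standardised latent abundance; 0 gives missing completely at
#'   random, large values approach left-censoring at a detection limit. The
#'   marginal missing fraction stays at `missing_rate` for any steepness.
#' @param missing_rate Baseline missing fraction for protein/phospho layers.
#' @param baseline_mean,baseline_sd Normal distribution of per-feature
#'   baseline log2 abundance.
#' @param age_mean,age_sd,age_shift_ad Age model (years); a nonzero
#'   `age_shift_ad` is added to AD brains to emulate the age imbalance seen
#'   in real cohorts (default 0: balanced).
#' @param pmi_mean,pmi_sd Postmortem interval model (hours).
#' @param n_phospho_reps Technical replicates generated for the
#'   phosphopeptide layer.
#' @param rep_sd Log2-scale SD of replicate noise.
#' @param site_offset_mean,site_offset_sd Phosphosite offset relative to the
#'   parent protein (log2).
#' @param phospho_frac_de Fraction of phosphosites with a site-level group
#'   effect (independent of the parent protein's effect).
#' @param stoich_effect Absolute occupancy difference given to spiked acetyl
#'   sites (AD vs control).
#' @param acetyl_cv SD of the multiplicative (log-normal) channel noise.
#' @param acetyl_missing_rate Random per-channel dropout in the acetyl layer.
#' @param seed Integer seed; fully determines the generated data.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_ad_brains = 11L, n_control_brains = 12L,
                       regions = brain_regions(),
                       n_proteins = 2000L, n_phospho = 2000L,
                       n_acetyl_sites = 221L,
                       frac_de = 0.05, effect_log2fc = 1.5, sd_noise = 0.5,
                       region_effects = c(HP = 1, CA1 = 0.66, EC = 0.5, PRC = 0.25),
                       covariate_effects = c(sex = 0, age = 0, pmi = 0),
                       frac_confounded = 0,
                       mnar_strength = 3, missing_rate = 0.1,
                       baseline_mean = 20, baseline_sd = 2,
                       age_mean = 75, age_sd = 8, age_shift_ad = 0,
                       pmi_mean = 4, pmi_sd = 1.5,
                       n_phospho_reps = 2L, rep_sd = 0.2,
                       site_offset_mean = -2, site_offset_sd = 1,
                       phospho_frac_de = frac_de,
                       stoich_effect = 0.3, acetyl_cv = 0.1,
                       acetyl_missing_rate = 0.2,
                       seed = 1L) {
  cfg <- list(n_ad_brains = as.integer(n_ad_brains),
              n_control_brains = as.integer(n_control_brains),
              regions = match.arg(regions, brain_regions(), several.ok = TRUE),
              n_proteins = as.integer(n_proteins),
              n_phospho = as.integer(n_phospho),
              n_acetyl_sites = as.integer(n_acetyl_sites),
              frac_de = frac_de, effect_log2fc = effect_log2fc,
              sd_noise = sd_noise, region_effects = region_effects,
              covariate_effects = covariate_effects,
              frac_confounded = frac_confounded,
              mnar_strength = mnar_strength, missing_rate = missing_rate,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              age_mean = age_mean, age_sd = age_sd, age_shift_ad = age_shift_ad,
              pmi_mean = pmi_mean, pmi_sd = pmi_sd,
              n_phospho_reps = as.integer(n_phospho_reps), rep_sd = rep_sd,
              site_offset_mean = site_offset_mean,
              site_offset_sd = site_offset_sd,
              phospho_frac_de = phospho_frac_de,
              stoich_effect = stoich_effect, acetyl_cv = acetyl_cv,
              acetyl_missing_rate = acetyl_missing_rate,
              seed = as.integer(seed))
  for (f in c("frac_de", "frac_confounded", "missing_rate",
              "phospho_frac_de", "acetyl_missing_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must lie in [0, 1]")
  for (f in c("n_proteins", "n_phospho", "n_acetyl_sites", "n_phospho_reps"))
    if (cfg[[f]] < 1L) stop("'", f, "' must be a positive count")
  if (cfg$mnar_strength < 0) stop("'mnar_strength' must be >= 0")
  if (cfg$sd_noise < 0 || cfg$rep_sd < 0 || cfg$acetyl_cv < 0)
    stop("noise standard deviations must be >= 0")
  if (is.null(names(cfg$region_effects)) ||
      !all(cfg$regions %in% names(cfg$region_effects)))
    stop("'region_effects' must be named and cover every simulated region")
  structure(cfg, class = "sim_config")
}

#' Simulate a study cohort
#'
#' Draws per-brain covariates (sex Bernoulli(0.5), age and PMI from normal
#' models, with an optional AD age shift) and lays out one sample per brain
#' per region with `tech_rep = 1`.
#'
#' @param config A [sim_config()].
#' @return A validated sample table (one row per brain x region).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_ad_brains < 1L || config$n_control_brains < 1L)
    stop("both disease groups need at least one brain")
  withr::with_seed(config$seed, {
    brains <- data.frame(
      brain_id = c(sprintf("AD%02d", seq_len(config$n_ad_brains)),
                   sprintf("C%02d", seq_len(config$n_control_brains))),
      group = rep(c("AD", "control"),
                  c(config$n_ad_brains, config$n_control_brains)),
      stringsAsFactors = FALSE)
    n <- nrow(brains)
    brains$sex <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "F", "M")
    brains$age <- pmax(stats::rnorm(n, config$age_mean, config$age_sd) +
                         ifelse(brains$group == "AD", config$age_shift_ad, 0), 40)
    brains$pmi <- pmax(stats::rnorm(n, config$pmi_mean, config$pmi_sd), 0.5)
    samples <- merge(brains,
                     expand.grid(brain_id = brains$brain_id,
                                 region = config$regions,
                                 stringsAsFactors = FALSE),
                     by = "brain_id", sort = FALSE)
    samples <- samples[order(match(samples$brain_id, brains$brain_id),
                             match(samples$region, brain_regions())), ]
    samples$tech_rep <- 1L
    samples$sample_id <- paste(samples$brain_id, samples$region, sep = ".")
    validate_sample_table(samples)
  })
}

## Logistic MNAR dropout in standardised latent log2 abundance. The
## intercept is solved so that the marginal missing fraction stays at
## missing_rate for any steepness: strength 0 reduces to missing completely
## at random, large strength approaches left-censoring at the detection
## limit (the classical MNAR model motivating downshifted imputation).
.mnar_dropout <- function(z, missing_rate, mnar_strength) {
  if (missing_rate <= 0) return(matrix(FALSE, nrow(z), ncol(z)))
  if (missing_rate >= 1) return(matrix(TRUE, nrow(z), ncol(z)))
  zs <- (z - mean(z)) / stats::sd(z)
  if (mnar_strength == 0) {
    p <- missing_rate
  } else {
    a <- stats::uniroot(
      function(a) mean(stats::plogis(a - mnar_strength * zs)) - missing_rate,
      interval = c(stats::qlogis(missing_rate) - 10 * mnar_strength - 10,
                   stats::qlogis(missing_rate) + 10 * mnar_strength + 10),
      tol = 1e-10)$root
    p <- stats::plogis(a - mnar_strength * zs)
  }
  matrix(stats::runif(length(z)) < p, nrow(z), ncol(z))
}

#' Simulate a protein intensity matrix with ground truth
#'
#' Latent log2 abundance is feature baseline + group effect (spiked features
#' only, attenuated per region) + covariate terms (confounded features only)
#' + Gaussian noise. Dropout probability rises logistically as latent
#' abundance falls. Returned intensities are raw scale (2^log2) with `NA`
#' for missing cells.
#'
#' @param cohort Sample table from [simulate_cohort()].
#' @param config A [sim_config()].
#' @return List with `matrix` (raw-scale [intensity_matrix()]) and `truth`
#'   (spiked features with signed log2FC, confounded features, the complete
#'   latent log2 matrix, and the region multipliers).
#' @export
simulate_protein_matrix <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    n <- config$n_proteins
    features <- sprintf("PROT%05d", seq_len(n))
    base <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)

    n_de <- round(config$frac_de * n)
    de_idx <- if (n_de) sample.int(n, n_de) else integer(0)
    de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
    effect <- numeric(n)
    effect[de_idx] <- de_sign * config$effect_log2fc

    n_conf <- round(config$frac_confounded * n)
    pool <- setdiff(seq_len(n), de_idx)
    conf_idx <- if (n_conf) sample(pool, min(n_conf, length(pool))) else integer(0)

    S <- nrow(cohort)
    ad <- as.numeric(cohort$group == "AD")
    mult <- unname(config$region_effects[cohort$region])
    sex01 <- as.numeric(cohort$sex == "F")
    covs <- cbind(sex = sex01 - mean(sex01),
                  age = cohort$age - mean(cohort$age),
                  pmi = cohort$pmi - mean(cohort$pmi))
    cov_shift <- as.vector(covs %*% config$covariate_effects[colnames(covs)])

    z <- outer(base, rep(1, S)) + outer(effect, ad * mult)
    if (length(conf_idx))
      z[conf_idx, ] <- z[conf_idx, ] + rep(cov_shift, each = length(conf_idx))
    z <- z + matrix(stats::rnorm(n * S, 0, config$sd_noise), n, S)
    dimnames(z) <- list(features, cohort$sample_id)

    miss <- .mnar_dropout(z, config$missing_rate, config$mnar_strength)
    raw <- 2^z
    raw[miss] <- NA_real_

    truth <- list(
      de = data.frame(feature_id = features[de_idx],
                      log2fc = effect[de_idx],
                      stringsAsFactors = FALSE),
      confounded = features[conf_idx],
      latent = z,
      region_effects = config$region_effects)
    list(matrix = intensity_matrix(raw, "protein", "raw"), truth = truth)
  })
}

#' Simulate a phosphopeptide layer on top of a protein matrix
#'
#' Each phosphopeptide inherits the complete latent log2 trajectory of a
#' randomly assigned parent protein, plus a site offset, an optional
#' site-level group effect (so phospho-level change can differ from
#' protein-level change), replicate noise per technical replicate, and MNAR
#' dropout.
#'
#' @param protein Result of [simulate_protein_matrix()] (its `truth$latent`
#'   supplies the parent trajectories).
#' @param cohort Sample table from [simulate_cohort()].
#' @param config A [sim_config()].
#' @return List with `matrix` (raw scale, replicate columns), `annotation`
#'   (phosphopeptide to parent-protein map), `samples` (replicate-expanded
#'   sample table) and `truth` (site-level spiked effects).
#' @export
simulate_phospho_layer <- function(protein, cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_phospho < 1L) stop("'n_phospho' must be >= 1")
  latent <- protein$truth$latent
  withr::with_seed(config$seed + 2L, {
    n <- config$n_phospho
    features <- sprintf("PP%05d", seq_len(n))
    parent <- sample(rownames(latent), n, replace = TRUE)
    offset <- stats::rnorm(n, config$site_offset_mean, config$site_offset_sd)

    n_de <- round(config$phospho_frac_de * n)
    de_idx <- if (n_de) sample.int(n, n_de) else integer(0)
    effect <- numeric(n)
    effect[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * config$effect_log2fc

    ad <- as.numeric(cohort$group == "AD")
    mult <- unname(config$region_effects[cohort$region])
    z_site <- latent[parent, , drop = FALSE] + offset + outer(effect, ad * mult)

    R <- config$n_phospho_reps
    reps <- vector("list", R)
    rep_samples <- vector("list", R)
    for (r in seq_len(R)) {
      zr <- z_site + matrix(stats::rnorm(length(z_site), 0, config$rep_sd),
                            nrow(z_site), ncol(z_site))
      sr <- cohort
      sr$tech_rep <- r
      if (R > 1L) sr$sample_id <- paste0(cohort$sample_id, ".r", r)
      colnames(zr) <- sr$sample_id
      reps[[r]] <- zr
      rep_samples[[r]] <- sr
    }
    z <- do.call(cbind, reps)
    rownames(z) <- features
    samples <- validate_sample_table(do.call(rbind, rep_samples))

    miss <- .mnar_dropout(z, config$missing_rate, config$mnar_strength)
    raw <- 2^z
    raw[miss] <- NA_real_

    annotation <- data.frame(
      feature_id = features,
      protein_accession = parent,
      peptide_sequence = NA_character_,
      ptm_sites = sprintf("S%d", sample.int(900L, n, replace = TRUE)),
      site_key = features,
      stringsAsFactors = FALSE)
    truth <- list(de = data.frame(feature_id = features[de_idx],
                                  log2fc = effect[de_idx],
                                  stringsAsFactors = FALSE),
                  parent = stats::setNames(parent, features))
    list(matrix = intensity_matrix(raw, "phosphopeptide", "raw"),
         annotation = annotation, samples = samples, truth = truth)
  })
}

#' Simulate paired d0/d3 acetylation channels with known occupancy
#'
#' Per site and sample a total peptide intensity is drawn; the endogenous
#' (d0) channel receives `occupancy * total` and the chemically labelled
#' (d3) channel `(1 - occupancy) * total`, each under independent
#' multiplicative log-normal noise. A zero channel (occupancy 0 or 1) is
#' encoded as missing, as raw intensities are strictly positive.
#'
#' @param cohort Sample table from [simulate_cohort()].
#' @param config A [sim_config()].
#' @return List with `matrix` (raw-scale acetyl layer; rows `<site>.d0` /
#'   `<site>.d3`), `annotation` (channel and site keys) and `truth`
#'   (per-site occupancy per group).
#' @export
simulate_acetyl_layer <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 3L, {
    n <- config$n_acetyl_sites
    sites <- sprintf("ACK%04d", seq_len(n))
    occ_ctrl <- stats::runif(n, 0.1, 0.9)
    n_de <- round(config$frac_de * n)
    de_idx <- if (n_de) sample.int(n, n_de) else integer(0)
    occ_ad <- occ_ctrl
    if (n_de) {
      dir <- sample(c(-1, 1), n_de, replace = TRUE)
      occ_ad[de_idx] <- pmin(pmax(occ_ctrl[de_idx] + dir * config$stoich_effect,
                                  0.02), 0.98)
    }
    S <- nrow(cohort)
    occ <- outer(occ_ctrl, rep(1, S))
    is_ad <- cohort$group == "AD"
    occ[, is_ad] <- outer(occ_ad, rep(1, sum(is_ad)))

    site_base <- stats::rnorm(n, 20, 2)
    total <- 2^(outer(site_base, rep(1, S)) +
                  matrix(stats::rnorm(n * S, 0, 0.5), n, S))
    e0 <- exp(matrix(stats::rnorm(n * S, 0, config$acetyl_cv), n, S))
    e3 <- exp(matrix(stats::rnorm(n * S, 0, config$acetyl_cv), n, S))
    d0 <- occ * total * e0
    d3 <- (1 - occ) * total * e3
    d0[d0 == 0] <- NA_real_
    d3[d3 == 0] <- NA_real_
    if (config$acetyl_missing_rate > 0) {
      d0[matrix(stats::runif(n * S) < config$acetyl_missing_rate, n, S)] <- NA_real_
      d3[matrix(stats::runif(n * S) < config$acetyl_missing_rate, n, S)] <- NA_real_
    }
    raw <- rbind(d0, d3)
    rownames(raw) <- c(paste0(sites, ".d0"), paste0(sites, ".d3"))
    colnames(raw) <- cohort$sample_id
    ord <- order(rep(seq_len(n), 2L))  # interleave d0/d3 per site
    raw <- raw[ord, , drop = FALSE]

    annotation <- data.frame(
      feature_id = rownames(raw),
      protein_accession = rep(sites, each = 2L),
      peptide_sequence = NA_character_,
      ptm_sites = rep(sprintf("K%d", seq_len(n)), each = 2L),
      acetyl_channel = rep(c("d0", "d3"), n),
      site_key = rep(sites, each = 2L),
      stringsAsFactors = FALSE)
    truth <- data.frame(site_key = sites, occ_control = occ_ctrl,
                        occ_ad = occ_ad, spiked = seq_len(n) %in% de_idx,
                        stringsAsFactors = FALSE)
    list(matrix = intensity_matrix(raw, "acetyl", "raw"),
         annotation = annotation, truth = truth)
  })
}

#' Simulate a complete three-layer study
#'
#' Convenience wrapper generating the cohort and all three omic layers, and
#' optionally writing every table (plus ground truth) as TSV.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory for TSV output.
#' @return List with `cohort`, `protein`, `phospho`, `acetyl` components.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  cohort <- simulate_cohort(config)
  protein <- simulate_protein_matrix(cohort, config)
  phospho <- simulate_phospho_layer(protein, cohort, config)
  acetyl <- simulate_acetyl_layer(cohort, config)
  out <- list(cohort = cohort, protein = protein, phospho = phospho,
              acetyl = acetyl, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sample_table(cohort, file.path(out_dir, "samples.tsv"))
    write_sample_table(phospho$samples, file.path(out_dir, "samples_phospho.tsv"))
    write_intensity_matrix(protein$matrix, file.path(out_dir, "protein_intensities.tsv"))
    write_intensity_matrix(phospho$matrix, file.path(out_dir, "phospho_intensities.tsv"))
    write_intensity_matrix(acetyl$matrix, file.path(out_dir, "acetyl_intensities.tsv"))
    utils::write.table(phospho$annotation, file.path(out_dir, "phospho_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(acetyl$annotation, file.path(out_dir, "acetyl_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(protein$truth$de, file.path(out_dir, "truth_protein_de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(acetyl$truth, file.path(out_dir, "truth_acetyl_occupancy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
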