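#' Phosphorylation state corrected for protein abundance
#'
#' Subtracts, per sample, the parent protein's normalised log2 abundance
#' from each phosphopeptide's normalised log2 abundance (a ratio on the raw
#' scale). This isolates site-level regulation from changes in total protein
#' amount. Phosphopeptides without an annotation entry or without a
#' quantified parent protein are dropped with a warning; a cell is missing
#' whenever either input is missing.
#'
#' @param phospho Log2-scale phosphopeptide [intensity_matrix()] (replicates
#'   already merged).
#' @param protein Log2-scale protein [intensity_matrix()] for the same
#'   samples; row names are protein accessions.
#' @param annotation Feature annotation with `feature_id` and
#'   `protein_accession`.
#' @return Log2-scale [intensity_matrix()] of layer `phospho_state`, with
#'   attribute `n_dropped` counting removed phosphopeptides.
#' @export
compute_phospho_state <- function(phospho, protein, annotation) {
  if (im_scale(phospho) != "log2" || im_scale(protein) != "log2")
    stop("both matrices must be log2-normalised")
  if (!setequal(colnames(phospho), colnames(protein)))
    stop("phospho and protein matrices must cover the same samples")
  protein <- protein[, colnames(phospho), drop = FALSE]
  acc <- annotation$protein_accession[match(rownames(phospho),
                                            annotation$feature_id)]
  mapped <- !is.na(acc) & acc %in% rownames(protein)
  n_dropped <- sum(!mapped)
  if (n_dropped)
    warning(n_dropped, " phosphopeptide(s) without a quantified parent ",
            "protein were dropped")
  if (!any(mapped)) stop("no phosphopeptide maps to a quantified protein")
  state <- unclass(phospho)[mapped, , drop = FALSE] -
    unclass(protein)[acc[mapped], , drop = FALSE]
  rownames(state) <- rownames(phospho)[mapped]
  out <- intensity_matrix(state, layer = "phospho_state", scale = "log2")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Acetylation stoichiometry from paired d0/d3 channels
#'
#' Per site and sample, occupancy is the summed intensity of endogenously
#' acetylated (d0) peptides divided by the summed intensity of all peptides
#' (d0 + chemically acetylated d3). By default a site observed in only one
#' channel takes the algebraically forced value (d0 only: 1; d3 only: 0);
#' with `strict_pairs = TRUE` both channels are required and such cells stay
#' missing. Both channels missing always yields a missing ratio.
#'
#' @param acetyl Raw-scale acetyl [intensity_matrix()].
#' @param annotation Feature annotation with `feature_id`, `acetyl_channel`
#'   (`d0` endogenous / `d3` chemical) and `site_key`.
#' @param strict_pairs Require both channels to be present (default FALSE).
#' @return Sites x samples matrix of occupancy ratios in \[0, 1\] (`NA`
#'   where undefined).
#' @export
compute_stoichiometry <- function(acetyl, annotation, strict_pairs = FALSE) {
  if (im_scale(acetyl) != "raw")
    stop("stoichiometry is computed on raw-scale channel intensities")
  if (any(acetyl < 0, na.rm = TRUE)) stop("negative intensity encountered")
  ann <- annotation[annotation$feature_id %in% rownames(acetyl), , drop = FALSE]
  if (!nrow(ann)) stop("annotation matches no row of the acetyl matrix")
  sites <- unique(ann$site_key)
  S <- ncol(acetyl)
  ratios <- matrix(NA_real_, length(sites), S,
                   dimnames = list(sites, colnames(acetyl)))
  sum_rows <- function(ids) {
    if (!length(ids)) return(rep(NA_real_, S))
    sub <- unclass(acetyl)[ids, , drop = FALSE]
    out <- colSums(sub, na.rm = TRUE)
    out[colSums(!is.na(sub)) == 0L] <- NA_real_
    out
  }
  for (i in seq_along(sites)) {
    rows <- ann[ann$site_key == sites[i], , drop = FALSE]
    d0 <- sum_rows(rows$feature_id[rows$acetyl_channel == "d0"])
    d3 <- sum_rows(rows$feature_id[rows$acetyl_channel == "d3"])
    both <- !is.na(d0) & !is.na(d3)
    r <- rep(NA_real_, S)
    r[both] <- d0[both] / (d0[both] + d3[both])
    if (!strict_pairs) {
      r[!is.na(d0) & is.na(d3)] <- 1
      r[is.na(d0) & !is.na(d3)] <- 0
    }
    ratios[i, ] <- r
  }
  ratios
}

#' Group comparison of acetylation stoichiometry
#'
#' Sites with at least `min_valid` (default 40%) valid occupancy ratios in
#' each disease group are compared with a two-sided Wilcoxon rank-sum test
#' on the raw ratios (no imputation); other sites are reported untested.
#'
#' @param ratios Sites x samples ratio matrix from
#'   [compute_stoichiometry()].
#' @param samples Sample table (one region).
#' @param min_valid Minimum valid fraction required in each group.
#' @return Data frame with per-group valid fractions, medians, `p_value`,
#'   `direction` and a `tested` flag per site.
#' @export
compare_stoichiometry <- function(ratios, samples, min_valid = 0.40) {
  idx <- match(colnames(ratios), samples$sample_id)
  if (anyNA(idx))
    stop("ratio column(s) absent from sample table: ",
         paste(colnames(ratios)[is.na(idx)], collapse = ", "))
  grp <- samples$group[idx]
  ad_cols <- which(grp == "AD")
  ctrl_cols <- which(grp == "control")
  if (!length(ad_cols) || !length(ctrl_cols))
    stop("both disease groups must have at least one sample")
  out <- data.frame(
    site_key = rownames(ratios),
    frac_valid_ad = rowMeans(!is.na(ratios[, ad_cols, drop = FALSE])),
    frac_valid_control = rowMeans(!is.na(ratios[, ctrl_cols, drop = FALSE])),
    median_ratio_ad = NA_real_, median_ratio_control = NA_real_,
    p_value = NA_real_, direction = NA_character_, tested = FALSE,
    row.names = NULL, stringsAsFactors = FALSE)
  eligible <- out$frac_valid_ad >= min_valid &
    out$frac_valid_control >= min_valid
  for (i in which(eligible)) {
    a <- ratios[i, ad_cols]
    b <- ratios[i, ctrl_cols]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    out$median_ratio_ad[i] <- stats::median(a)
    out$median_ratio_control[i] <- stats::median(b)
    out$p_value[i] <- wilcox_ranksum_p(a, b)
    d <- out$median_ratio_ad[i] - out$median_ratio_control[i]
    out$direction[i] <- if (d > 0) "up" else if (d < 0) "down" else "none"
    out$tested[i] <- TRUE
  }
  out
}
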