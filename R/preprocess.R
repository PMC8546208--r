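#' Merge technical replicates by per-feature median
#'
#' Collapses replicate columns of the same (brain, region) sample to one
#' column holding the median over present values; a cell missing in every
#' replicate stays missing. With a single replicate throughout, the matrix
#' is returned unchanged.
#'
#' @param mat An [intensity_matrix()].
#' @param samples Sample table describing the replicate structure; every
#'   matrix column must be a known `sample_id`.
#' @return An [intensity_matrix()] with one column per (brain, region),
#'   named `<brain_id>.<region>`.
#' @export
merge_technical_replicates <- function(mat, samples) {
  idx <- match(colnames(mat), samples$sample_id)
  if (anyNA(idx))
    stop("matrix column(s) absent from sample table: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "))
  key <- paste(samples$brain_id[idx], samples$region[idx], sep = ".")
  if (!anyDuplicated(key)) return(mat)
  groups <- split(seq_len(ncol(mat)), factor(key, levels = unique(key)))
  merged <- vapply(groups, function(j) {
    if (length(j) == 1L) return(mat[, j])
    if (length(j) == 2L) {
      # median of two values is their mean; present-only when one is missing
      v <- rowMeans(mat[, j, drop = FALSE], na.rm = TRUE)
      v[is.nan(v)] <- NA_real_
      return(v)
    }
    apply(mat[, j, drop = FALSE], 1L, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else stats::median(v)
    })
  }, numeric(nrow(mat)))
  rownames(merged) <- rownames(mat)
  intensity_matrix(merged, layer = im_layer(mat), scale = im_scale(mat))
}

#' Collapse a sample table to one row per (brain, region)
#'
#' Companion to [merge_technical_replicates()]: keeps one row per biological
#' sample, with `sample_id = <brain_id>.<region>` and `tech_rep = 1`.
#'
#' @param samples Sample table.
#' @return Collapsed sample table.
#' @export
collapse_sample_table <- function(samples) {
  key <- paste(samples$brain_id, samples$region, sep = ".")
  if (!anyDuplicated(key)) return(validate_sample_table(samples))
  out <- samples[!duplicated(key), , drop = FALSE]
  out$sample_id <- key[!duplicated(key)]
  out$tech_rep <- 1L
  validate_sample_table(out)
}

#' Log2 transform and median normalisation
#'
#' Transforms raw intensities to log2 and subtracts each sample's median of
#' present values, so every post-normalisation column median is exactly 0.
#'
#' @param mat Raw-scale [intensity_matrix()].
#' @return Log2-scale [intensity_matrix()].
#' @export
log2_median_normalize <- function(mat) {
  if (im_scale(mat) != "raw")
    stop("log2_median_normalize() expects a raw-scale matrix")
  n_present <- colSums(!is.na(mat))
  if (any(n_present == 0L))
    stop("sample ", colnames(mat)[n_present == 0L][1],
         " has no present values")
  l <- log2(unclass(mat))
  med <- apply(l, 2L, stats::median, na.rm = TRUE)
  intensity_matrix(sweep(l, 2L, med), layer = im_layer(mat), scale = "log2")
}

#' Per-group valid-value fractions
#'
#' For each feature, the exact fraction of non-missing values among AD and
#' among control samples. The matrix should be restricted to one region (one
#' column per biological sample).
#'
#' @param mat An [intensity_matrix()].
#' @param samples Sample table covering the matrix columns.
#' @return Data frame with `feature_id`, `frac_valid_ad`,
#'   `frac_valid_control`, `n_ad`, `n_control`.
#' @export
compute_validity <- function(mat, samples) {
  idx <- match(colnames(mat), samples$sample_id)
  if (anyNA(idx))
    stop("matrix column(s) absent from sample table: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "))
  grp <- samples$group[idx]
  ad_cols <- which(grp == "AD")
  ctrl_cols <- which(grp == "control")
  if (!length(ad_cols) || !length(ctrl_cols))
    stop("both disease groups must have at least one sample")
  data.frame(
    feature_id = rownames(mat),
    frac_valid_ad = rowMeans(!is.na(mat[, ad_cols, drop = FALSE])),
    frac_valid_control = rowMeans(!is.na(mat[, ctrl_cols, drop = FALSE])),
    n_ad = length(ad_cols),
    n_control = length(ctrl_cols),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Qualitative (ON/OFF) presence classification
#'
#' A feature is ON in AD when it is valid in at least 70% of AD samples and
#' in less than 10% of controls; OFF in AD is the mirror rule. Thresholds
#' are compared exactly: a fraction equal to 0.70 satisfies ">= 0.70", one
#' equal to 0.10 fails "< 0.10".
#'
#' @param validity Output of [compute_validity()].
#' @param on_threshold Minimum valid fraction in the "present" group.
#' @param off_threshold Strict upper bound in the "absent" group.
#' @return Data frame with `feature_id` and `status` in
#'   `qualitative_on_AD` / `qualitative_off_AD` / `not_qualitative`.
#' @export
classify_on_off <- function(validity, on_threshold = 0.70, off_threshold = 0.10) {
  a <- validity$frac_valid_ad
  c_ <- validity$frac_valid_control
  status <- rep("not_qualitative", nrow(validity))
  status[a >= on_threshold & c_ < off_threshold] <- "qualitative_on_AD"
  status[c_ >= on_threshold & a < off_threshold] <- "qualitative_off_AD"
  data.frame(feature_id = validity$feature_id, status = status,
             stringsAsFactors = FALSE)
}

#' Quantitative validity filter
#'
#' Keeps features with at least 66% valid values in both groups
#' (`quantitative`), plus "on-off-like" features with less than 33% valid
#' values in one group and at least 66% in the other; everything else is
#' excluded from quantitative testing. Boundary handling mirrors
#' [classify_on_off()].
#'
#' @param validity Output of [compute_validity()].
#' @param min_valid Minimum valid fraction required in a group.
#' @param absent_max Strict upper bound defining near-absence.
#' @return Data frame with `feature_id` and `status` in
#'   `quantitative` / `on_off_like` / `excluded`.
#' @export
filter_quantitative <- function(validity, min_valid = 0.66, absent_max = 0.33) {
  a <- validity$frac_valid_ad
  c_ <- validity$frac_valid_control
  status <- rep("excluded", nrow(validity))
  status[(a >= min_valid & c_ < absent_max) |
           (c_ >= min_valid & a < absent_max)] <- "on_off_like"
  status[a >= min_valid & c_ >= min_valid] <- "quantitative"
  data.frame(feature_id = validity$feature_id, status = status,
             stringsAsFactors = FALSE)
}

## Deterministic per-column random substream: the draw a column receives
## depends on its sample id and the global seed, never on column order.
.column_seed <- function(seed, colname) {
  h <- 0
  for (k in utf8ToInt(colname)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

#' Impute missing values from a downshifted normal distribution
#'
#' For each sample (column) the mean `m` and standard deviation `s` of the
#' present values are computed, and every missing cell is replaced by a draw
#' from Normal(m - downshift * s, (width * s)^2). This models
#' missing-not-at-random dropout of low-abundance features by placing
#' imputed values in the left tail of the sample's observed distribution.
#'
#' @param mat Log2-scale [intensity_matrix()]; typically restricted to
#'   features passing [filter_quantitative()].
#' @param width Width of the imputation distribution, as a fraction of the
#'   per-sample SD (default 0.3).
#' @param downshift Downshift of its mean, in per-sample SDs (default 1.8).
#' @param seed Integer seed; draws are reproducible and independent of
#'   column order.
#' @return The matrix with all missing cells imputed; present values are
#'   untouched.
#' @export
impute_downshifted_normal <- function(mat, width = 0.3, downshift = 1.8,
                                      seed = 1L) {
  if (im_scale(mat) != "log2")
    stop("impute_downshifted_normal() expects a log2-scale matrix")
  if (width <= 0) stop("'width' must be > 0")
  out <- unclass(mat)
  for (j in seq_len(ncol(out))) {
    v <- out[, j]
    present <- !is.na(v)
    if (sum(present) < 2L)
      stop("sample ", colnames(out)[j],
           " has fewer than 2 present values; per-sample SD is undefined")
    miss <- which(!present)
    if (!length(miss)) next
    m <- mean(v[present])
    s <- stats::sd(v[present])
    draws <- withr::with_seed(
      .column_seed(seed, colnames(out)[j]),
      stats::rnorm(length(miss), m - downshift * s, width * s))
    out[miss, j] <- draws
  }
  intensity_matrix(out, layer = im_layer(mat), scale = "log2")
}

## Shared tail of the per-region chain: validity -> filters -> imputation.
.filter_impute <- function(norm, samples, on_threshold, off_threshold,
                           min_valid, absent_max, width, downshift, seed) {
  validity <- compute_validity(norm, samples)
  qualitative <- classify_on_off(validity, on_threshold, off_threshold)
  quantitative <- filter_quantitative(validity, min_valid, absent_max)
  keep <- quantitative$feature_id[quantitative$status != "excluded"]
  imputed <- if (length(keep))
    impute_downshifted_normal(norm[keep, , drop = FALSE],
                              width = width, downshift = downshift,
                              seed = seed)
  else norm[keep, , drop = FALSE]
  list(validity = validity, qualitative = qualitative,
       quantitative = quantitative, imputed = imputed)
}

#' Run the full pre-processing chain for one region
#'
#' Subsets the matrix to one region's samples, merges technical replicates,
#' log2-transforms and median-normalises, computes validity profiles and
#' both filter decisions, and imputes the retained (quantitative +
#' on-off-like) features. Pre-processing is performed for each brain region
#' individually.
#'
#' @param mat Raw-scale [intensity_matrix()] covering one or more regions.
#' @param samples Sample table for the matrix columns.
#' @param region Region to process (one of [brain_regions()]).
#' @param on_threshold,off_threshold Qualitative-rule thresholds.
#' @param min_valid,absent_max Quantitative-rule thresholds.
#' @param width,downshift,seed Imputation parameters, see
#'   [impute_downshifted_normal()].
#' @return List with `normalized` (all features, unimputed), `imputed`
#'   (retained features, complete), `validity`, `qualitative`,
#'   `quantitative` and the collapsed per-region `samples`.
#' @export
preprocess_region <- function(mat, samples, region,
                              on_threshold = 0.70, off_threshold = 0.10,
                              min_valid = 0.66, absent_max = 0.33,
                              width = 0.3, downshift = 1.8, seed = 1L) {
  region <- match.arg(region, brain_regions())
  keep_samples <- samples[samples$region == region, , drop = FALSE]
  if (!nrow(keep_samples)) stop("no samples for region ", region)
  cols <- intersect(colnames(mat), keep_samples$sample_id)
  if (!length(cols)) stop("matrix has no columns for region ", region)
  sub <- mat[, cols, drop = FALSE]
  merged <- merge_technical_replicates(sub, keep_samples)
  collapsed <- collapse_sample_table(keep_samples)
  collapsed <- collapsed[match(colnames(merged), collapsed$sample_id), , drop = FALSE]
  norm <- log2_median_normalize(merged)
  res <- .filter_impute(norm, collapsed, on_threshold, off_threshold,
                        min_valid, absent_max, width, downshift, seed)
  c(list(normalized = norm, samples = collapsed), res)
}
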