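#' Two-sided Wilcoxon rank-sum p-value, exact for small groups
#'
#' For groups of at most `exact_limit` observations each, the permutation
#' distribution of the rank sum (midranks, so ties are handled exactly) is
#' enumerated by dynamic programming and the two-sided p is twice the
#' smaller tail, capped at 1 — the convention of [stats::wilcox.test()].
#' Larger samples use the normal approximation with tie correction.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest per-group size enumerated exactly.
#' @return Two-sided p-value.
#' @export
wilcox_ranksum_p <- function(x, y, exact_limit = 25L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) return(1)
  if (length(x) > exact_limit || length(y) > exact_limit)
    return(suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value))
  r2 <- as.integer(round(2 * rank(c(x, y))))  # doubled midranks: integers
  m <- length(x)
  w_obs <- sum(r2[seq_len(m)])
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(m)])
  # counts[k + 1, s + 1] = number of size-k subsets with doubled-rank sum s
  counts <- matrix(0, m + 1L, smax + 1L)
  counts[1L, 1L] <- 1
  for (v in r2) {
    kmax <- min(m, nrow(counts) - 1L)
    for (k in kmax:1) {
      shifted <- c(rep(0, v), counts[k, seq_len(smax + 1L - v)])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  dist <- counts[m + 1L, ]
  total <- sum(dist)
  p_le <- sum(dist[seq_len(w_obs + 1L)]) / total
  p_ge <- sum(dist[(w_obs + 1L):(smax + 1L)]) / total
  min(1, 2 * min(p_le, p_ge))
}

## Closed-form simple OLS of each matrix row on a single regressor.
## For a binary 0/1 regressor the slope is the difference of group means and
## the slope t-test is the equal-variance two-sample t-test; the testthat
## suite checks agreement with t.test()/lm() to 1e-10.
.ols_fit <- function(Y, x) {
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L)
  n <- length(x)
  if (ncol(Y) != n) stop("regressor length does not match the number of samples")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0)
    return(list(slope = rep(NA_real_, nrow(Y)), p = rep(NA_real_, nrow(Y)),
                constant = TRUE))
  slope <- as.vector(Y %*% xc) / sxx
  tss <- rowSums((Y - rowMeans(Y))^2)
  rss <- pmax(tss - slope^2 * sxx, 0)
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate rows: constant response -> no association (p = 1);
  # an exact non-trivial linear fit -> p = 0
  degenerate <- se == 0
  const_y <- tss <= .Machine$double.eps * n * (rowMeans(Y)^2 + 1)
  p[degenerate] <- ifelse(const_y[degenerate], 1, 0)
  slope[degenerate & const_y] <- 0
  list(slope = slope, p = p, constant = FALSE)
}

.group_indicator <- function(mat_cols, samples) {
  idx <- match(mat_cols, samples$sample_id)
  if (anyNA(idx))
    stop("sample id(s) absent from sample table: ",
         paste(mat_cols[is.na(idx)], collapse = ", "))
  list(idx = idx, x = as.numeric(samples$group[idx] == "AD"))
}

#' Cohort balance tests for one region
#'
#' Compares the disease groups with respect to sex (two-sided Fisher's exact
#' test on the 2x2 table), and age and postmortem interval (two-sided
#' Wilcoxon rank-sum tests), one brain contributing once. A variable
#' constant across both groups yields p = 1 with a warning.
#'
#' @param samples Sample table.
#' @param region Region to test.
#' @return Data frame with `region`, `variable`, `test`, `p_value`.
#' @export
test_group_balance <- function(samples, region) {
  region <- match.arg(region, brain_regions())
  sub <- samples[samples$region == region, , drop = FALSE]
  sub <- sub[!duplicated(sub$brain_id), , drop = FALSE]
  if (!any(sub$group == "AD") || !any(sub$group == "control"))
    stop("region ", region, " lacks samples in one disease group")
  grp <- factor(sub$group, levels = c("AD", "control"))

  sex <- factor(sub$sex, levels = c("M", "F"))
  tab <- table(grp, sex)
  p_sex <- if (any(colSums(tab) == 0)) {
    warning("sex is constant across both groups in ", region, "; p set to 1")
    1
  } else stats::fisher.test(tab)$p.value

  wilcox_p <- function(v, label) {
    a <- v[grp == "AD"]
    b <- v[grp == "control"]
    if (length(unique(c(a, b))) == 1L) {
      warning(label, " is constant across both groups in ", region,
              "; p set to 1")
      return(1)
    }
    wilcox_ranksum_p(a, b)
  }
  data.frame(region = region,
             variable = c("sex", "age", "pmi"),
             test = c("fisher_exact", "wilcoxon_rank_sum",
                      "wilcoxon_rank_sum"),
             p_value = c(p_sex, wilcox_p(sub$age, "age"),
                         wilcox_p(sub$pmi, "pmi")),
             stringsAsFactors = FALSE)
}

#' Differential abundance regression for one feature
#'
#' Ordinary least squares of log2 abundance on the disease-group indicator
#' (control = 0, AD = 1). The slope is the AD - control log2 fold change and
#' its two-sided t-test supplies the p-value; a feature is significant when
#' p < `p_threshold` and |log2FC| >= `fc_threshold`.
#'
#' @param values Named (by sample id) or column-aligned numeric vector of
#'   complete log2 abundances for one region.
#' @param samples Sample table.
#' @param p_threshold,fc_threshold Significance rule (defaults 0.05 / 0.7).
#' @return One-row data frame with `log2fc`, `p_value`, `significant`.
#' @export
fit_group_regression <- function(values, samples, p_threshold = 0.05,
                                 fc_threshold = 0.7) {
  ids <- if (!is.null(names(values))) names(values) else samples$sample_id
  g <- .group_indicator(ids, samples)
  if (sum(g$x == 1) < 2L || sum(g$x == 0) < 2L)
    stop("each disease group needs at least 2 samples")
  fit <- .ols_fit(matrix(values, nrow = 1L), g$x)
  data.frame(log2fc = fit$slope, p_value = fit$p,
             significant = fit$p < p_threshold &
               abs(fit$slope) >= fc_threshold)
}

#' Screen one feature against the study covariates
#'
#' Fits, independently for each covariate, a simple regression of abundance
#' on that covariate alone (sex coded 0/1, age and PMI numeric) and flags
#' the covariate when its slope is significant at `alpha`. Flagged features
#' are excluded from biological interpretation downstream. A constant
#' covariate is never flagged and raises a warning.
#'
#' @param values Named or column-aligned numeric vector of complete log2
#'   abundances.
#' @param samples Sample table.
#' @param covariates Covariates to screen.
#' @param alpha Per-covariate significance level.
#' @return Character vector of flagged covariate names (possibly empty).
#' @export
screen_covariates <- function(values, samples,
                              covariates = c("sex", "age", "pmi"),
                              alpha = 0.05) {
  ids <- if (!is.null(names(values))) names(values) else samples$sample_id
  idx <- match(ids, samples$sample_id)
  if (anyNA(idx)) stop("sample id(s) absent from sample table")
  flags <- character(0)
  for (cv in covariates) {
    x <- switch(cv,
                sex = as.numeric(samples$sex[idx] == "F"),
                age = samples$age[idx],
                pmi = samples$pmi[idx],
                stop("unknown covariate: ", cv))
    fit <- .ols_fit(matrix(values, nrow = 1L), x)
    if (fit$constant) {
      warning("covariate ", cv, " is constant; not flagged")
      next
    }
    if (!is.na(fit$p) && fit$p < alpha) flags <- c(flags, cv)
  }
  flags
}

#' Differential abundance analysis for one region and layer
#'
#' Applies [fit_group_regression()] and [screen_covariates()] (both
#' vectorised internally) to every retained feature of an imputed matrix. A
#' feature is `retained` when it is significant under the p/fold-change rule
#' and no covariate is flagged. No multiple-testing correction is applied by
#' default (raw p < 0.05 with a fold-change floor); set `adjust = "BH"` for
#' an optional Benjamini-Hochberg corrected decision.
#'
#' @param mat Complete (imputed) log2 [intensity_matrix()] for one region.
#' @param samples Sample table.
#' @param decisions Optional output of [filter_quantitative()]; when given,
#'   only `quantitative` / `on_off_like` features are tested.
#' @param p_threshold,fc_threshold Significance rule.
#' @param screen Logical; run the covariate screen (default `TRUE`).
#' @param alpha Covariate-screen significance level.
#' @param adjust `"none"` (default, faithful to the headline rule) or
#'   `"BH"`.
#' @return Data frame with one row per tested feature: `feature_id`,
#'   `region`, `log2fc`, `p_value`, `significant`, per-covariate flag
#'   columns, `covariate_flags`, `retained`, `direction`.
#' @export
run_differential <- function(mat, samples, decisions = NULL,
                             p_threshold = 0.05, fc_threshold = 0.7,
                             screen = TRUE, alpha = 0.05,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.null(decisions)) {
    keep <- decisions$feature_id[decisions$status %in%
                                   c("quantitative", "on_off_like")]
    mat <- mat[intersect(rownames(mat), keep), , drop = FALSE]
  }
  if (!nrow(mat)) stop("no features to test")
  if (anyNA(mat)) stop("run_differential() expects a complete (imputed) matrix")
  g <- .group_indicator(colnames(mat), samples)
  if (sum(g$x == 1) < 2L || sum(g$x == 0) < 2L)
    stop("each disease group needs at least 2 samples")
  sub <- samples[g$idx, , drop = FALSE]
  region <- if (length(unique(sub$region)) == 1L) sub$region[1] else NA_character_

  fit <- .ols_fit(unclass(mat), g$x)
  p_used <- if (adjust == "BH") stats::p.adjust(fit$p, "BH") else fit$p
  significant <- p_used < p_threshold & abs(fit$slope) >= fc_threshold

  flag <- matrix(FALSE, nrow(mat), 3L,
                 dimnames = list(NULL, c("sex", "age", "pmi")))
  if (screen) {
    covs <- list(sex = as.numeric(sub$sex == "F"), age = sub$age,
                 pmi = sub$pmi)
    for (cv in names(covs)) {
      cfit <- .ols_fit(unclass(mat), covs[[cv]])
      if (cfit$constant) {
        warning("covariate ", cv, " is constant; not flagged")
        next
      }
      flag[, cv] <- !is.na(cfit$p) & cfit$p < alpha
    }
  }
  covariate_flags <- apply(flag, 1L, function(f)
    paste(colnames(flag)[f], collapse = ","))
  data.frame(
    feature_id = rownames(mat), region = region,
    log2fc = fit$slope, p_value = fit$p,
    significant = significant,
    flag_sex = flag[, "sex"], flag_age = flag[, "age"],
    flag_pmi = flag[, "pmi"],
    covariate_flags = covariate_flags,
    retained = significant & covariate_flags == "",
    direction = ifelse(fit$slope > 0, "up", ifelse(fit$slope < 0, "down", "none")),
    row.names = NULL, stringsAsFactors = FALSE)
}
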