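test_that("technical replicates collapse to present-only medians", {
  brains <- c("AD01", "C01")
  samples <- validate_sample_table(data.frame(
    sample_id = c("a.r1", "a.r2", "a.r3", "b.r1"),
    brain_id = c("AD01", "AD01", "AD01", "C01"),
    region = "HP", group = c("AD", "AD", "AD", "control"),
    sex = "M", age = 70, pmi = 5, tech_rep = c(1L, 2L, 3L, 1L)))
  m <- intensity_matrix(
    matrix(c(4, 4, NA,
             6, NA, NA,
             NA, NA, NA,
             1, 1, 1), nrow = 3, ncol = 4,
           dimnames = list(c("F1", "F2", "F3"),
                           c("a.r1", "a.r2", "a.r3", "b.r1"))),
    "phosphopeptide", "log2")
  merged <- merge_technical_replicates(m, samples)
  expect_equal(colnames(merged), c("AD01.HP", "C01.HP"))
  expect_equal(unname(merged["F1", "AD01.HP"]), 5)   # median {4, 6}
  expect_equal(unname(merged["F2", "AD01.HP"]), 4)   # median over present {4}
  expect_true(is.na(merged["F3", "AD01.HP"]))        # all replicates missing

  # single replicate: identity
  single <- tiny_matrix(tiny_samples(), scale = "log2")
  expect_identical(merge_technical_replicates(single, tiny_samples()), single)
})

test_that("log2 median normalisation zeroes every sample median", {
  m <- intensity_matrix(
    matrix(c(2, 8), 2, 1, dimnames = list(c("F1", "F2"), "S1")),
    "protein", "raw")
  norm <- log2_median_normalize(m)
  expect_equal(unname(unclass(norm)[, 1]), c(-1, 1))
  expect_identical(im_scale(norm), "log2")

  # all-identical column -> all zeros
  m2 <- intensity_matrix(
    matrix(16, 3, 2, dimnames = list(paste0("F", 1:3), c("S1", "S2"))),
    "protein", "raw")
  expect_true(all(unclass(log2_median_normalize(m2)) == 0))

  # property: random matrices with missingness
  withr::local_seed(7)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    p <- sample(3:10, 1)
    m <- matrix(2^stats::rnorm(n * p, 20, 2), n, p,
                dimnames = list(sprintf("F%02d", 1:n), sprintf("S%02d", 1:p)))
    m[stats::runif(n * p) < 0.2] <- NA
    m[1, ] <- 1  # guarantee a present value per column
    norm <- log2_median_normalize(intensity_matrix(m, "protein", "raw"))
    meds <- apply(unclass(norm), 2, stats::median, na.rm = TRUE)
    expect_equal(unname(meds), rep(0, p), tolerance = 1e-12)
  }

  # a fully-missing sample is a hard error
  m3 <- matrix(c(1, NA), 1, 2, dimnames = list("F1", c("S1", "S2")))
  expect_error(log2_median_normalize(intensity_matrix(m3, "protein", "raw")),
               "no present values")
})

test_that("validity fractions are exact per-group ratios", {
  samples <- tiny_samples(n_ad = 11, n_control = 12)
  m <- matrix(1, 3, 23, dimnames = list(c("F1", "F2", "F3"), samples$sample_id))
  m[1, samples$sample_id[samples$group == "AD"][1:3]] <- NA  # 8/11 valid
  m[3, ] <- NA
  v <- compute_validity(intensity_matrix(m, "protein", "log2"), samples)
  expect_equal(v$frac_valid_ad, c(8 / 11, 1, 0))
  expect_equal(v$frac_valid_control, c(1, 1, 0))
  expect_equal(v$n_ad[1], 11L)
})

test_that("ON/OFF and quantitative rules reproduce hand-computed boundary decisions", {
  # 30 profiles covering the exact 0.70 / 0.10 / 0.66 / 0.33 boundaries;
  # expected labels assigned by hand from the rules:
  #   ON in AD:  ad >= 0.70 & control < 0.10 (OFF mirrored)
  #   quantitative: both >= 0.66; on-off-like: one >= 0.66 & other < 0.33
  fixture <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
    ad     ctrl   qual               quant
    1.00   0.00   qualitative_on_AD  on_off_like
    0.00   1.00   qualitative_off_AD on_off_like
    0.70   0.09   qualitative_on_AD  on_off_like
    0.70   0.10   not_qualitative    on_off_like
    0.69   0.05   not_qualitative    on_off_like
    0.66   0.32   not_qualitative    on_off_like
    0.66   0.33   not_qualitative    excluded
    0.66   0.66   not_qualitative    quantitative
    0.65   0.65   not_qualitative    excluded
    0.66   0.65   not_qualitative    excluded
    0.09   0.70   qualitative_off_AD on_off_like
    0.10   0.70   not_qualitative    on_off_like
    0.32   0.66   not_qualitative    on_off_like
    0.33   0.66   not_qualitative    excluded
    1.00   1.00   not_qualitative    quantitative
    0.00   0.00   not_qualitative    excluded
    0.75   0.727  not_qualitative    quantitative
    0.818  0.083  qualitative_on_AD  on_off_like
    0.727  0.167  not_qualitative    on_off_like
    0.27   0.75   not_qualitative    on_off_like
    0.45   0.41   not_qualitative    excluded
    0.70   0.00   qualitative_on_AD  on_off_like
    0.00   0.70   qualitative_off_AD on_off_like
    1.00   0.09   qualitative_on_AD  on_off_like
    0.09   1.00   qualitative_off_AD on_off_like
    0.69   0.09   not_qualitative    on_off_like
    0.09   0.69   not_qualitative    on_off_like
    0.34   0.34   not_qualitative    excluded
    1.00   0.33   not_qualitative    excluded
    0.33   1.00   not_qualitative    excluded")
  expect_equal(nrow(fixture), 30L)
  v <- make_validity(fixture$ad, fixture$ctrl)
  expect_equal(classify_on_off(v)$status, fixture$qual)
  expect_equal(filter_quantitative(v)$status, fixture$quant)
})

test_that("imputation draws the downshifted normal per column, reproducibly", {
  samples <- tiny_samples(n_ad = 2, n_control = 2)
  m <- tiny_matrix(samples, n_features = 30, scale = "log2")
  m[cbind(sample(30, 10), sample(4, 10, replace = TRUE))] <- NA
  imp1 <- impute_downshifted_normal(m, seed = 99)
  imp2 <- impute_downshifted_normal(m, seed = 99)
  expect_identical(imp1, imp2)
  expect_false(anyNA(imp1))
  # present values untouched
  ok <- !is.na(m)
  expect_identical(unclass(imp1)[ok], unclass(m)[ok])
  # no missing values -> identity
  full <- tiny_matrix(samples, scale = "log2")
  expect_identical(impute_downshifted_normal(full, seed = 1), full)
  # column with < 2 present values is an error
  bad <- unclass(m)
  bad[-1, 1] <- NA
  expect_error(impute_downshifted_normal(
    intensity_matrix(bad, "protein", "log2"), seed = 1), "fewer than 2")
})

test_that("imputation statistics are column-wise, not global", {
  # two columns with very different means: imputed values must follow each
  # column's own mean - 1.8 * sd
  withr::local_seed(3)
  n <- 4000
  col1 <- stats::rnorm(n, 10, 1)
  col2 <- stats::rnorm(n, 30, 2)
  m <- cbind(S1 = col1, S2 = col2)
  rownames(m) <- sprintf("F%04d", 1:n)
  m[1:1500, "S1"] <- NA
  m[2501:4000, "S2"] <- NA
  stats1 <- c(mean(m[-(1:1500), "S1"]), stats::sd(m[-(1:1500), "S1"]))
  stats2 <- c(mean(m[1:2500, "S2"]), stats::sd(m[1:2500, "S2"]))
  imp <- unclass(impute_downshifted_normal(
    intensity_matrix(m, "protein", "log2"), seed = 4))
  i1 <- imp[1:1500, "S1"]
  i2 <- imp[2501:4000, "S2"]
  expect_lt(abs(mean(i1) - (stats1[1] - 1.8 * stats1[2])), 0.05)
  expect_lt(abs(mean(i2) - (stats2[1] - 1.8 * stats2[2])), 0.1)
  expect_lt(abs(stats::sd(i1) - 0.3 * stats1[2]), 0.02)
  expect_lt(abs(stats::sd(i2) - 0.3 * stats2[2]), 0.04)
})

test_that("column order does not change the imputed draws", {
  samples <- tiny_samples(n_ad = 2, n_control = 2)
  m <- tiny_matrix(samples, n_features = 50, scale = "log2")
  m[cbind(sample(50, 20), sample(4, 20, replace = TRUE))] <- NA
  imp <- impute_downshifted_normal(m, seed = 5)
  perm <- rev(colnames(m))
  imp_perm <- impute_downshifted_normal(m[, perm], seed = 5)
  expect_identical(imp_perm, imp[, perm])
})

test_that("per-region preprocessing chains merge, normalise, filter and impute", {
  cfg <- sim_config(n_proteins = 300, seed = 17)
  sim <- simulate_study(cfg)
  pp <- preprocess_region(sim$protein$matrix, sim$cohort, "CA1", seed = 2)
  expect_equal(ncol(pp$imputed), 23L)
  expect_false(anyNA(pp$imputed))
  expect_true(all(rownames(pp$imputed) %in%
                    pp$quantitative$feature_id[pp$quantitative$status != "excluded"]))
  meds <- apply(unclass(pp$normalized), 2, stats::median, na.rm = TRUE)
  expect_equal(unname(meds), rep(0, 23), tolerance = 1e-12)
  # phospho layer: replicate columns collapse to one per brain
  ph <- preprocess_region(sim$phospho$matrix, sim$phospho$samples, "CA1", seed = 2)
  expect_equal(ncol(ph$imputed), 23L)
})
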