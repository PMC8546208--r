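# Small in-code fixtures shared across test files.

# A balanced two-group, one-region sample table.
tiny_samples <- function(n_ad = 3, n_control = 3, region = "HP") {
  brains <- c(sprintf("AD%02d", seq_len(n_ad)),
              sprintf("C%02d", seq_len(n_control)))
  validate_sample_table(data.frame(
    sample_id = paste(brains, region, sep = "."),
    brain_id = brains,
    region = region,
    group = rep(c("AD", "control"), c(n_ad, n_control)),
    sex = rep(c("M", "F"), length.out = n_ad + n_control),
    # covariates cycle so that neither correlates with the group blocks
    age = 70 + rep_len(c(0, 5, 2, 7, 4, 1, 6, 3), n_ad + n_control),
    pmi = 3 + rep_len(c(0.5, 2, 1, 3, 0, 2.5, 1.5, 3.5), n_ad + n_control),
    tech_rep = 1L,
    stringsAsFactors = FALSE))
}

# A small intensity matrix whose columns match tiny_samples().
tiny_matrix <- function(samples, n_features = 4, scale = "log2",
                        layer = "protein", seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_features * nrow(samples), 20, 1),
                n_features, nrow(samples),
                dimnames = list(sprintf("F%03d", seq_len(n_features)),
                                samples$sample_id))
    if (scale == "raw") m <- 2^(m / 4)
    intensity_matrix(m, layer = layer, scale = scale)
  })
}

# Validity profiles with exact fractions (denominator 1000 reproduces
# two-decimal fractions exactly as doubles).
make_validity <- function(frac_ad, frac_control) {
  data.frame(feature_id = sprintf("V%03d", seq_along(frac_ad)),
             frac_valid_ad = round(frac_ad * 1000) / 1000,
             frac_valid_control = round(frac_control * 1000) / 1000,
             n_ad = 1000L, n_control = 1000L,
             stringsAsFactors = FALSE)
}
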