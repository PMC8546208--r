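region_matrices <- function(cfg) {
  sim <- simulate_study(cfg)
  mats <- lapply(brain_regions(), function(r)
    preprocess_region(sim$protein$matrix, sim$cohort, r, seed = 1)$imputed)
  names(mats) <- brain_regions()
  list(mats = mats, sim = sim)
}

test_that("fold changes are anchored on the per-region control median", {
  samples <- tiny_samples(n_ad = 2, n_control = 3)
  m <- matrix(0, 1, 5, dimnames = list("F1", samples$sample_id))
  ctrl <- samples$sample_id[samples$group == "control"]
  m["F1", ctrl] <- c(1, 2, 3)
  m["F1", samples$sample_id[samples$group == "AD"]] <- c(5, 4)
  mats <- lapply(brain_regions(), function(r) intensity_matrix(m, "protein", "log2"))
  names(mats) <- brain_regions()
  # reuse the same column ids across regions via a single-region table
  prof <- compute_fold_change_profiles(mats["HP"], samples)
  expect_equal(unname(prof$fc$HP["F1", ]), c(3, 2))  # 5 - median{1,2,3}
  # subtracting the anchor from the controls themselves re-centres them at 0
  expect_equal(stats::median(m["F1", ctrl] - stats::median(m["F1", ctrl])), 0)
})

test_that("features absent from any region are dropped and counted", {
  samples <- tiny_samples(n_ad = 2, n_control = 2)
  base <- matrix(stats::rnorm(8), 2, 4,
                 dimnames = list(c("F1", "F2"), samples$sample_id))
  mats <- list(
    HP = intensity_matrix(base, "protein", "log2"),
    CA1 = intensity_matrix(base, "protein", "log2"),
    EC = intensity_matrix(base, "protein", "log2"),
    PRC = intensity_matrix(base["F1", , drop = FALSE], "protein", "log2"))
  prof <- compute_fold_change_profiles(mats, samples)
  expect_equal(rownames(prof$medians), "F1")
  expect_equal(prof$n_dropped, 1L)
})

test_that("ANOVA F and p match the closed-form decomposition oracle", {
  # four identical groups -> F = 0, p = 1
  same <- list(HP = c(1, 2), CA1 = c(1, 2), EC = c(1, 2), PRC = c(1, 2))
  res <- anova_tukey(same)
  expect_equal(res$f, 0, tolerance = 1e-12)
  expect_equal(res$anova_p, 1, tolerance = 1e-12)

  oracle_f <- function(groups) {
    k <- length(groups)
    n <- lengths(groups)
    N <- sum(n)
    gm <- mean(unlist(groups))
    ssb <- sum(n * (vapply(groups, mean, 0) - gm)^2)
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
    f <- (ssb / (k - 1)) / (ssw / (N - k))
    list(f = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
  }
  shifted <- list(HP = c(1, 2), CA1 = c(1, 2), EC = c(1, 2), PRC = c(5, 6))
  res2 <- anova_tukey(shifted)
  orc <- oracle_f(shifted)
  expect_lt(abs(res2$f - orc$f), 1e-10)
  expect_lt(abs(res2$anova_p - orc$p), 1e-10)

  withr::local_seed(91)
  for (i in 1:200) {
    groups <- lapply(stats::setNames(nm = brain_regions()), function(r)
      stats::rnorm(sample(2:8, 1), mean = stats::rnorm(1)))
    res <- anova_tukey(groups)
    orc <- oracle_f(groups)
    expect_lt(abs(res$f - orc$f) / max(orc$f, 1), 1e-8)
    expect_lt(abs(res$anova_p - orc$p), 1e-8)
  }
})

test_that("Tukey adjusted p-values dominate the pooled pairwise t-test p", {
  withr::local_seed(101)
  for (i in 1:50) {
    groups <- lapply(stats::setNames(nm = brain_regions()), function(r)
      stats::rnorm(sample(3:9, 1), mean = stats::rnorm(1, sd = 0.5)))
    res <- anova_tukey(groups)
    # unadjusted pooled-variance pairwise p from the same decomposition
    n <- lengths(groups)
    N <- sum(n)
    mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / (N - 4)
    pairs <- utils::combn(names(groups), 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      tstat <- abs(mean(groups[[b]]) - mean(groups[[a]])) /
        sqrt(mse * (1 / n[[a]] + 1 / n[[b]]))
      p_un <- 2 * stats::pt(-tstat, N - 4)
      p_adj <- res$tukey$p_adj[res$tukey$pair %in%
                                 c(paste0(b, "-", a), paste0(a, "-", b))]
      expect_gte(p_adj + 1e-9, p_un)
    }
  }
})

test_that("trajectory shapes classify monotone and non-monotone profiles", {
  expect_equal(label_trajectory_shape(c(0.1, 0.4, 0.4, 0.9)), "increasing")
  expect_equal(label_trajectory_shape(c(0.9, 0.5, 0.2, 0.1)), "decreasing")
  expect_equal(label_trajectory_shape(c(0.1, 0.9, 0.2, 0.8)), "other")
  expect_equal(label_trajectory_shape(c(0, 0, 0, 0)), "other")
  m <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  expect_equal(unname(label_trajectory_shape(m)), c("increasing", "decreasing"))
})

test_that("well-separated blobs are recovered exactly by the dynamic cut", {
  withr::local_seed(111)
  for (rep in 1:5) {
    centers <- c(0, 15, 40)
    sizes <- c(150, 150, 120)
    x <- do.call(rbind, lapply(1:3, function(k)
      cbind(stats::rnorm(sizes[k], centers[k]),
            matrix(stats::rnorm(sizes[k] * 3), ncol = 3))))
    rownames(x) <- sprintf("f%03d", seq_len(nrow(x)))
    cl <- cluster_profiles(x, min_cluster_size = 100)
    truth <- rep(1:3, sizes)
    expect_equal(length(unique(cl)), 3L)
    # purity: every cluster maps to exactly one blob
    expect_true(all(apply(table(cl, truth) > 0, 1, sum) == 1))
  }
})

test_that("the size floor and degenerate inputs are handled", {
  withr::local_seed(121)
  # one homogeneous blob -> a single cluster
  z <- matrix(stats::rnorm(300 * 4), ncol = 4,
              dimnames = list(sprintf("h%03d", 1:300), NULL))
  expect_equal(unname(unique(cluster_profiles(z, min_cluster_size = 100))), 1L)
  # 50-point blob next to a 200-point blob: never its own cluster
  y <- rbind(matrix(stats::rnorm(50 * 4), ncol = 4),
             sweep(matrix(stats::rnorm(200 * 4), ncol = 4), 2,
                   c(20, 0, 0, 0), `+`))
  rownames(y) <- sprintf("g%03d", 1:250)
  cl <- cluster_profiles(y, min_cluster_size = 100)
  expect_true(all(table(cl) >= 100))
  # fewer features than the floor -> single cluster with warning
  expect_warning(cl2 <- cluster_profiles(z[1:30, ], min_cluster_size = 100),
                 "single cluster")
  expect_equal(unname(unique(cl2)), 1L)
})

test_that("spiked monotone features are labelled and clustered by spike direction", {
  ari <- function(a, b) {
    tab <- table(a, b)
    c2 <- function(x) sum(choose(x, 2))
    idx <- c2(as.vector(tab))
    er <- c2(rowSums(tab)) * c2(colSums(tab)) / choose(sum(tab), 2)
    mx <- (c2(rowSums(tab)) + c2(colSums(tab))) / 2
    (idx - er) / (mx - er)
  }
  for (seed in 131:133) {
    cfg <- sim_config(n_proteins = 800, frac_de = 0.15, effect_log2fc = 2,
                      sd_noise = 0.1, missing_rate = 0.05, seed = seed)
    rm <- region_matrices(cfg)
    tr <- run_trajectory(rm$mats, rm$sim$cohort, min_cluster_size = 20)
    truth <- rm$sim$protein$truth$de
    rec <- tr$records[match(truth$feature_id, tr$records$feature_id), ]
    ok <- !is.na(rec$anova_p)
    expect_gt(mean(ok), 0.7)
    # region multipliers decay HP -> PRC, so positive spikes decrease
    expected <- ifelse(truth$log2fc > 0, "decreasing", "increasing")
    expect_gt(mean(rec$shape[ok] == expected[ok]), 0.9)
    # spiked features cluster by spike direction
    keep <- ok & !is.na(rec$cluster)
    expect_gte(ari(rec$cluster[keep], sign(truth$log2fc[keep])), 0.8)
  }
})
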