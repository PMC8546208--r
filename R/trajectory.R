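#' Control-median-anchored fold-change profiles across regions
#'
#' For every feature quantified in all regions, subtracts the per-region
#' control median log2 intensity from each AD sample's log2 intensity,
#' giving per-AD-sample log2 fold changes and per-region median fold
#' changes in the anatomical order HP, CA1, EC, PRC.
#'
#' @param matrices Named list (by region) of complete log2
#'   [intensity_matrix()] objects, e.g. the `imputed` output of
#'   [preprocess_region()].
#' @param samples Sample table covering all regions.
#' @return List with `fc` (per-region features x AD-samples fold-change
#'   matrices), `medians` (features x regions median fold changes),
#'   `regions`, and `n_dropped` (features absent from at least one region).
#' @export
compute_fold_change_profiles <- function(matrices, samples) {
  regions <- intersect(brain_regions(), names(matrices))
  if (!length(regions)) stop("'matrices' must be named by region")
  matrices <- matrices[regions]
  common <- Reduce(intersect, lapply(matrices, rownames))
  n_dropped <- length(unique(unlist(lapply(matrices, rownames)))) -
    length(common)
  if (!length(common))
    stop("no feature is quantified in every region")
  fc <- vector("list", length(regions))
  names(fc) <- regions
  medians <- matrix(NA_real_, length(common), length(regions),
                    dimnames = list(common, regions))
  for (r in regions) {
    m <- matrices[[r]][common, , drop = FALSE]
    idx <- match(colnames(m), samples$sample_id)
    if (anyNA(idx))
      stop("sample id(s) in region ", r, " absent from sample table")
    grp <- samples$group[idx]
    ctrl <- which(grp == "control")
    ad <- which(grp == "AD")
    if (!length(ctrl)) stop("region ", r, " has no control samples")
    ctrl_med <- apply(unclass(m)[, ctrl, drop = FALSE], 1L, stats::median)
    fc[[r]] <- unclass(m)[, ad, drop = FALSE] - ctrl_med
    medians[, r] <- apply(fc[[r]], 1L, stats::median)
  }
  list(fc = fc, medians = medians, regions = regions, n_dropped = n_dropped)
}

#' One-way ANOVA with Tukey HSD across regions for one feature
#'
#' Fixed-effects one-way ANOVA of the per-AD-sample fold changes on region,
#' followed by Tukey's honestly-significant-difference post-hoc test for all
#' region pairs (the Tukey-Kramer form handles unequal group sizes).
#'
#' @param values_by_region Named list of numeric fold-change vectors, one
#'   per region, each of length >= 2.
#' @return List with `f`, `anova_p` and `tukey` (data frame of pairwise
#'   differences and adjusted p-values).
#' @export
anova_tukey <- function(values_by_region) {
  if (any(lengths(values_by_region) < 2L))
    stop("each region needs at least 2 fold-change values")
  df <- data.frame(
    value = unlist(values_by_region, use.names = FALSE),
    region = factor(rep(names(values_by_region), lengths(values_by_region)),
                    levels = names(values_by_region)))
  fit <- stats::aov(value ~ region, data = df)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$region
  list(f = tab[["F value"]][1], anova_p = tab[["Pr(>F)"]][1],
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

## deepSplit 0..4 mapped to the published hybrid-cut sensitivity scale;
## the minimum merge-gap a split must exhibit is (1 - core)*3/4 of the
## dendrogram height range.
.deep_split_gap <- function(deep_split) {
  core <- c(0.64, 0.73, 0.82, 0.91, 0.95)
  if (deep_split < 0 || deep_split > 4)
    stop("'deep_split' must lie in 0..4")
  (1 - core[deep_split + 1L]) * 3 / 4
}

#' Complete-linkage clustering with a dynamic hybrid tree cut
#'
#' Hierarchical clustering (complete linkage, Euclidean distance) of
#' per-region median fold-change vectors, with an adaptive dendrogram cut:
#' starting from the root, a branch is split into its two children only
#' when both children would contain at least `min_cluster_size` features
#' and the merge height exceeds the children's internal heights by a
#' deep-split-controlled gap. Branches smaller than the size floor are
#' therefore never reported as their own cluster; they remain merged with
#' their nearest (complete-linkage) neighbour branch. Cluster ids are
#' ordered by decreasing size.
#'
#' @param x Numeric matrix (features x dimensions, e.g. the `medians` of
#'   [compute_fold_change_profiles()] restricted to ANOVA-significant
#'   features).
#' @param min_cluster_size Minimum cluster size (default 100).
#' @param deep_split Split sensitivity 0 (coarse) to 4 (fine); default 1.
#' @param method Cut variant; only `"hybrid"` is implemented.
#' @return Integer cluster labels (named by feature), 1..K.
#' @export
cluster_profiles <- function(x, min_cluster_size = 100L, deep_split = 1L,
                             method = "hybrid") {
  method <- match.arg(method, "hybrid")
  if (min_cluster_size < 2L) stop("'min_cluster_size' must be >= 2")
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("f", seq_len(n))
  if (n < min_cluster_size) {
    warning("fewer features (", n, ") than min_cluster_size (",
            min_cluster_size, "); returning a single cluster")
    return(stats::setNames(rep(1L, n), rownames(x)))
  }
  hc <- stats::hclust(stats::dist(x), method = "complete")
  h <- hc$height
  href <- stats::quantile(h, 0.05, names = FALSE)
  hrange <- max(h) - href
  if (hrange <= 0)
    return(stats::setNames(rep(1L, n), rownames(x)))
  min_gap <- .deep_split_gap(deep_split) * hrange

  nm <- n - 1L
  size <- integer(nm)
  members <- vector("list", nm)
  node_h <- numeric(nm)
  for (k in seq_len(nm)) {
    kids <- hc$merge[k, ]
    get_members <- function(id) if (id < 0) -id else members[[id]]
    members[[k]] <- c(get_members(kids[1]), get_members(kids[2]))
    size[k] <- length(members[[k]])
    node_h[k] <- h[k]
  }
  child_size <- function(id) if (id < 0) 1L else size[id]
  child_height <- function(id) if (id < 0) 0 else node_h[id]

  labels <- integer(n)
  next_id <- 0L
  assign_cluster <- function(node) {
    next_id <<- next_id + 1L
    labels[members[[node]]] <<- next_id
  }
  recurse <- function(node) {
    kids <- hc$merge[node, ]
    ok_size <- child_size(kids[1]) >= min_cluster_size &&
      child_size(kids[2]) >= min_cluster_size
    gap <- node_h[node] - max(child_height(kids[1]), child_height(kids[2]))
    if (ok_size && gap > 0 && gap >= min_gap) {
      for (id in kids)
        if (id > 0) recurse(id) else assign_cluster(node)  # unreachable leaf guard
    } else {
      assign_cluster(node)
    }
  }
  recurse(nm)
  # relabel by decreasing size
  sizes <- sort(table(labels), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relabel[as.character(labels)])
  stats::setNames(out, hc$labels)
}

#' Monotonicity label of a cross-region trajectory
#'
#' Classifies the four per-region median fold changes (order HP, CA1, EC,
#' PRC) as `increasing` (non-strictly monotone up with at least one strict
#' increase), `decreasing` (mirror rule), or `other`.
#'
#' @param medians Numeric vector of 4 region medians, or a features x 4
#'   matrix.
#' @return Character label(s).
#' @export
label_trajectory_shape <- function(medians) {
  shape1 <- function(v) {
    d <- diff(v)
    if (all(d >= 0) && any(d > 0)) "increasing"
    else if (all(d <= 0) && any(d < 0)) "decreasing"
    else "other"
  }
  if (is.matrix(medians)) apply(medians, 1L, shape1) else shape1(medians)
}

#' Cross-region trajectory analysis
#'
#' Full spatial-progression chain: control-median fold-change profiles,
#' per-feature ANOVA across regions with Tukey HSD, dynamic-tree-cut
#' clustering of the ANOVA-significant features' median profiles, and
#' monotonicity labels.
#'
#' @param matrices Named per-region list of complete log2 matrices (see
#'   [compute_fold_change_profiles()]).
#' @param samples Sample table.
#' @param alpha ANOVA significance level gating cluster assignment.
#' @param min_cluster_size,deep_split Tree-cut parameters.
#' @return List with `records` (per-feature data frame: ANOVA p, Tukey pair
#'   p-values, shape, cluster id — `NA` when not significant), `medians`,
#'   `profiles` and `cluster_profiles` (per-cluster mean median-FC
#'   trajectory).
#' @export
run_trajectory <- function(matrices, samples, alpha = 0.05,
                           min_cluster_size = 100L, deep_split = 1L) {
  prof <- compute_fold_change_profiles(matrices, samples)
  features <- rownames(prof$medians)
  n <- length(features)
  anova_p <- numeric(n)
  fstat <- numeric(n)
  pair_names <- NULL
  tukey_p <- NULL
  for (i in seq_len(n)) {
    vals <- lapply(prof$fc, function(m) m[i, ])
    at <- anova_tukey(vals)
    anova_p[i] <- at$anova_p
    fstat[i] <- at$f
    if (is.null(pair_names)) {
      pair_names <- at$tukey$pair
      tukey_p <- matrix(NA_real_, n, length(pair_names),
                        dimnames = list(features, paste0("tukey_", pair_names)))
    }
    tukey_p[i, ] <- at$tukey$p_adj
  }
  shape <- label_trajectory_shape(prof$medians)
  sig <- !is.na(anova_p) & anova_p < alpha
  cluster <- rep(NA_integer_, n)
  if (sum(sig) >= 2L)
    cluster[sig] <- cluster_profiles(prof$medians[sig, , drop = FALSE],
                                     min_cluster_size = min_cluster_size,
                                     deep_split = deep_split)
  records <- data.frame(feature_id = features, f = fstat, anova_p = anova_p,
                        shape = shape, cluster = cluster,
                        row.names = NULL, stringsAsFactors = FALSE)
  records <- cbind(records, as.data.frame(tukey_p, row.names = NULL))
  cl_prof <- NULL
  if (any(!is.na(cluster))) {
    cl_prof <- t(vapply(sort(unique(stats::na.omit(cluster))), function(k)
      colMeans(prof$medians[which(cluster == k), , drop = FALSE]),
      numeric(ncol(prof$medians))))
    rownames(cl_prof) <- sort(unique(stats::na.omit(cluster)))
  }
  list(records = records, medians = prof$medians, profiles = prof,
       cluster_profiles = cl_prof)
}
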