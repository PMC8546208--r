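## ES of a gene set given sorted hit positions, computed in O(|S|):
## between hits the running sum decays linearly, so its extrema occur
## immediately after a hit (maximum candidates) or immediately before one
## (minimum candidates).
.es_from_hits <- function(idx, w, N) {
  k <- length(idx)
  sw <- sum(w)
  wn <- if (sw > 0) w / sw else rep(1 / k, k)
  m <- 1 / (N - k)
  cum <- cumsum(wn)
  after <- cum - m * (idx - seq_len(k))
  before <- c(0, cum[-k]) - m * (idx - seq_len(k))
  es_pos <- max(after)
  es_neg <- min(c(0, before))
  if (es_pos >= -es_neg) es_pos else es_neg
}

#' Weighted enrichment score of one gene set
#'
#' Classic pre-ranked GSEA running-sum statistic: walking down the ranked
#' list, hits increment the sum proportionally to |metric|^weight
#' (normalised to total 1) and misses decrement it by 1/(N - N_hits); the
#' score is the maximum deviation from zero (signed). Ties in the metric
#' are broken by feature id so the ranking is fully reproducible.
#'
#' @param stats Named numeric ranking metric (any order; sorted internally,
#'   decreasing).
#' @param set Character vector of member ids.
#' @param weight Exponent on |metric| (default 1, the classic weighted
#'   form).
#' @return Enrichment score in \[-1, 1\].
#' @export
enrichment_score <- function(stats, set, weight = 1) {
  ord <- order(-stats, names(stats))
  s <- stats[ord]
  idx <- which(names(s) %in% set)
  if (!length(idx)) stop("set has no members in the ranked list")
  if (length(idx) == length(s)) stop("set covers the entire ranked list")
  .es_from_hits(idx, abs(s[idx])^weight, length(s))
}

#' Pre-ranked gene set enrichment analysis
#'
#' Computes the weighted enrichment score of each set against the ranked
#' list, with significance from gene-label permutations (random sets of the
#' same size drawn from the list; pre-ranked input carries no phenotype
#' labels to permute). NES is ES divided by the mean |permuted ES| of the
#' same sign, the p-value is the same-sign permutation tail with add-one
#' smoothing, and FDR q-values are Benjamini-Hochberg across tested sets.
#'
#' @param stats Named numeric ranking metric (e.g. a log2 fold-change
#'   difference between two regions).
#' @param sets Named list of member-id vectors (see [read_gmt()]).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed for reproducible permutations.
#' @param min_size,max_size Set-size bounds after restriction to the list
#'   (defaults 15 / 500).
#' @param weight ES weight exponent.
#' @return Data frame with `set_name`, `n_hits`, `es`, `nes`, `p_value`,
#'   `fdr_q`; sets outside the size bounds are recorded in the `skipped`
#'   attribute.
#' @export
prerank_gsea <- function(stats, sets, n_perm = 1000L, seed = NULL,
                         min_size = 15L, max_size = 500L, weight = 1) {
  if (n_perm < 100L) stop("'n_perm' must be >= 100")
  if (is.null(names(stats)) || anyDuplicated(names(stats)))
    stop("'stats' must be named with unique feature ids")
  if (!is.null(seed)) set.seed(seed)
  ord <- order(-stats, names(stats))
  s <- stats[ord]
  N <- length(s)
  w_all <- abs(s)^weight

  hit_idx <- lapply(sets, function(members) which(names(s) %in% members))
  k <- lengths(hit_idx)
  tested <- k >= min_size & k <= max_size & k < N
  skipped <- names(sets)[!tested]

  res <- data.frame(set_name = names(sets)[tested],
                    n_hits = k[tested], es = NA_real_, nes = NA_real_,
                    p_value = NA_real_, fdr_q = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    idx <- hit_idx[[res$set_name[i]]]
    ki <- length(idx)
    es <- .es_from_hits(idx, w_all[idx], N)
    perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      pi <- sort.int(sample.int(N, ki))
      perm[b] <- .es_from_hits(pi, w_all[pi], N)
    }
    same <- perm[sign(perm) == sign(es)]
    res$es[i] <- es
    res$p_value[i] <- (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1)
    res$nes[i] <- if (length(same)) es / mean(abs(same)) else NA_real_
  }
  res$fdr_q <- stats::p.adjust(res$p_value, "BH")
  attr(res, "skipped") <- skipped
  res
}

#' Annotate quantified features against an accession list
#'
#' Intersects each region's quantified feature set with an external list
#' (antimicrobial peptides, kinases, or any custom accession list), reports
#' per-region and all-region overlap counts, and joins per-feature
#' dysregulation status from differential results when supplied.
#'
#' @param quantified Named list (by region) of quantified feature-id
#'   vectors.
#' @param accessions Character vector of list members, or the path of a
#'   plain one-id-per-line file.
#' @param results Optional named list (by region) of [run_differential()]
#'   outputs used to flag detected ids as up/down-regulated.
#' @param list_name Label for the list (`"AMP"`, `"kinase"`, or custom).
#' @return List with `list_name`, per-region `detected` sets, `n_detected`,
#'   `all_regions` (ids found in every region), `n_all_regions`,
#'   `n_total_detected`, and a long `status` data frame.
#' @export
annotate_against_list <- function(quantified, accessions, results = NULL,
                                  list_name = "custom") {
  if (length(accessions) == 1L && file.exists(accessions))
    accessions <- read_accession_list(accessions)
  accessions <- unique(accessions)
  if (!length(accessions)) stop("accession list is empty")
  if (is.null(names(quantified)))
    stop("'quantified' must be a named per-region list")
  detected <- lapply(quantified, function(ids) intersect(unique(ids), accessions))
  all_regions <- Reduce(intersect, detected)
  total <- unique(unlist(detected))
  status <- do.call(rbind, lapply(names(detected), function(r) {
    ids <- detected[[r]]
    if (!length(ids)) return(NULL)
    st <- rep("detected", length(ids))
    if (!is.null(results) && r %in% names(results)) {
      dr <- results[[r]]
      hit <- match(ids, dr$feature_id)
      up <- !is.na(hit) & dr$retained[hit] & dr$log2fc[hit] > 0
      dn <- !is.na(hit) & dr$retained[hit] & dr$log2fc[hit] < 0
      st[up] <- "up"
      st[dn] <- "down"
    }
    data.frame(region = r, feature_id = ids, status = st,
               stringsAsFactors = FALSE)
  }))
  list(list_name = list_name, detected = detected,
       n_detected = lengths(detected),
       all_regions = all_regions, n_all_regions = length(all_regions),
       n_total_detected = length(total), status = status)
}
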