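# Per-RP differential expression between clusters: median-based log2 fold
# changes against a reference cluster and two-sided Wilcoxon rank-sum tests,
# with Benjamini-Hochberg adjustment reported alongside the raw p-values.

cluster_samples <- function(clusters, label) {
  clusters$sample[clusters$cluster == label]
}

largest_cluster <- function(clusters) {
  tab <- table(clusters$cluster[clusters$cluster != "unassigned"])
  if (!length(tab)) abort("no assigned clusters")
  names(tab)[order(-tab, names(tab))][1]
}

#' Per-group log2 fold-change profile against a reference cluster
#'
#' For every group g and RP r computes
#' `log2((median_g + c) / (median_ref + c))` of the normalized values, the
#' profile used to display how each group's RP signature deviates from the
#' reference. The reference defaults to the largest cluster, whose own
#' profile is identically zero.
#'
#' @param m An `rp_norm` tibble.
#' @param clusters An `rp_clusters` tibble (`"unassigned"` samples are
#'   ignored).
#' @param reference Reference cluster label; default the largest cluster.
#' @param pseudocount Added to the medians before the ratio; default
#'   `target_sum * 1e-6`.
#' @return A tibble `rp`, `group`, `reference`, `log2_fc`.
#' @export
log2_fc_profile <- function(m, clusters, reference = NULL, pseudocount = NULL) {
  stopifnot(inherits(m, "rp_expr"))
  mat <- expr_matrix(m)
  if (is.null(pseudocount)) {
    s <- attr(m, "target_sum", exact = TRUE)
    pseudocount <- if (is.null(s)) 0 else s * 1e-6
  }
  reference <- reference %||% largest_cluster(clusters)
  groups <- setdiff(unique(clusters$cluster), "unassigned")
  if (!reference %in% groups) abort(paste0("reference cluster '", reference, "' not found"))
  med <- function(g) {
    s <- intersect(cluster_samples(clusters, g), colnames(mat))
    if (!length(s)) abort(paste0("cluster '", g, "' has no samples in the matrix"))
    apply(mat[, s, drop = FALSE], 1, median)
  }
  ref_med <- med(reference)
  purrr::map_dfr(groups, function(g) {
    tibble(
      rp = rownames(mat), group = g, reference = reference,
      log2_fc = unname(log2((med(g) + pseudocount) / (ref_med + pseudocount)))
    )
  })
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value (full enumeration of rank assignments) when the pooled size
#' is at most 20 and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A one-row tibble `statistic` (the rank-sum U of `x`), `p_value`,
#'   `exact`, `n_x`, `n_y`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact, correct = TRUE))
  tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    exact = use_exact, n_x = length(x), n_y = length(y)
  )
}

#' Per-RP differential expression between clusters
#'
#' For every non-reference group and every RP: the median-based log2 fold
#' change versus the reference, a two-sided Wilcoxon rank-sum test of the
#' normalized values, and Benjamini-Hochberg adjusted p-values (adjusted
#' across RPs within each group-vs-reference comparison).
#'
#' @inheritParams log2_fc_profile
#' @return A tibble of class `rp_differential`: `rp`, `group`, `reference`,
#'   `log2_fc`, `p_raw`, `p_bh`, `n_group`, `n_ref`.
#' @export
rp_differential <- function(m, clusters, reference = NULL, pseudocount = NULL) {
  stopifnot(inherits(m, "rp_expr"))
  mat <- expr_matrix(m)
  reference <- reference %||% largest_cluster(clusters)
  fc <- log2_fc_profile(m, clusters, reference, pseudocount)
  ref_s <- intersect(cluster_samples(clusters, reference), colnames(mat))
  groups <- setdiff(unique(clusters$cluster), c("unassigned", reference))
  empty <- tibble(
    rp = character(), group = character(), reference = character(),
    p_raw = numeric(), p_bh = numeric(), n_group = integer(), n_ref = integer()
  )
  res <- purrr::map_dfr(groups, function(g) {
    gs <- intersect(cluster_samples(clusters, g), colnames(mat))
    p <- vapply(rownames(mat), function(r) {
      wilcoxon_rank_sum(mat[r, gs], mat[r, ref_s])$p_value
    }, numeric(1))
    tibble(
      rp = rownames(mat), group = g, reference = reference,
      p_raw = unname(p), p_bh = p.adjust(p, method = "BH"),
      n_group = length(gs), n_ref = length(ref_s)
    )
  })
  out <- bind_rows(empty, res) |>
    left_join(fc, by = c("rp", "group", "reference")) |>
    select("rp", "group", "reference", "log2_fc", "p_raw", "p_bh", "n_group", "n_ref")
  structure(out, class = c("rp_differential", class(tibble())))
}

#' Rank the top differentially expressed RPs
#'
#' Orders by ascending raw p-value, breaking ties by descending absolute
#' log2 fold change and then alphabetically by RP symbol — a total order, so
#' the ranking is invariant to input row permutation.
#'
#' @param results An `rp_differential` tibble (one comparison, or pre-filtered
#'   to one group).
#' @param k Number of top RPs to return.
#' @return The top `k` rows with all statistics, in rank order.
#' @export
rank_top_rps <- function(results, k = 15L) {
  stopifnot(k >= 1)
  results |>
    arrange(.data$p_raw, desc(abs(.data$log2_fc)), .data$rp) |>
    head(k)
}
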