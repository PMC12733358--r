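# Programmatic cluster extraction. The embedding separates signature groups
# visually; extraction replaces visual identification with a reproducible
# rule: connected components of the radius graph on the 2D embedding
# ("density"), or an average-linkage cut on the precomputed distance
# ("hclust"). Groups smaller than min_size are labeled "unassigned".

#' Extract clusters from an embedding or a distance matrix
#'
#' The default `"density"` method links every pair of embedded points closer
#' than a radius `eps` and takes connected components; `eps` defaults to a
#' multiple of the median nearest-neighbor distance, so it adapts to the
#' embedding's scale. Components with fewer than `min_size` samples are
#' labeled `"unassigned"`. The `"hclust"` method cuts an average-linkage
#' dendrogram of the precomputed distance into `k` clusters.
#'
#' @param x An `rp_embedding` or an `rp_dist`. The `"density"` method accepts
#'   either (radius graph on the embedded points or on the given distances);
#'   `"hclust"` needs an `rp_dist`.
#' @param method `"density"` or `"hclust"`.
#' @param eps Neighborhood radius for `"density"`; default
#'   `eps_factor` times the median nearest-neighbor distance.
#' @param eps_factor Multiplier used when `eps` is `NULL` (default 3).
#' @param min_size Minimum cluster size (default 5); smaller components are
#'   `"unassigned"`.
#' @param k Number of clusters for `"hclust"`.
#' @return A tibble of class `rp_clusters` with columns `sample`, `cluster`
#'   (`cluster_1`, `cluster_2`, ... by decreasing size, or `"unassigned"`)
#'   and attributes `method` and `n_clusters`.
#' @export
extract_clusters <- function(x, method = c("density", "hclust"),
                             eps = NULL, eps_factor = 3, min_size = 5L, k = NULL) {
  method <- match.arg(method)
  if (method == "density") {
    if (inherits(x, "rp_embedding")) {
      if (nrow(x) == 0) abort("empty embedding")
      dm <- as.matrix(dist(cbind(x$x, x$y)))
      ids <- x$sample
    } else if (inherits(x, "rp_dist")) {
      dm <- x$matrix
      ids <- x$sample_ids
    } else {
      abort("density clustering needs an rp_embedding or rp_dist")
    }
    if (is.null(eps)) {
      diag(dm) <- Inf
      nn <- apply(dm, 1, min)
      diag(dm) <- 0
      eps <- eps_factor * median(nn) + sqrt(.Machine$double.eps)
    }
    adj <- dm <= eps
    comp <- graph_components(adj)
  } else {
    if (!inherits(x, "rp_dist")) abort("hclust clustering needs an rp_dist")
    if (is.null(k)) abort("method = 'hclust' requires k")
    hc <- hclust(as.dist(x$matrix), method = "average")
    comp <- cutree(hc, k = k)
    ids <- x$sample_ids
  }
  sizes <- table(comp)
  keep <- names(sizes)[sizes >= min_size]
  ord <- keep[order(-sizes[keep], as.numeric(keep))]
  lab <- rep("unassigned", length(comp))
  for (i in seq_along(ord)) lab[comp == ord[i]] <- paste0("cluster_", i)
  structure(
    tibble(sample = ids, cluster = lab),
    method = method, n_clusters = length(ord),
    class = c("rp_clusters", class(tibble()))
  )
}

# Connected components of a logical adjacency matrix (breadth-first).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      frontier <- i
      comp[i] <- cur
      while (length(frontier)) {
        nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
        comp[nb] <- cur
        frontier <- nb
      }
    }
  }
  comp
}

#' @export
print.rp_clusters <- function(x, ...) {
  cat(sprintf(
    "<rp_clusters> %d samples, %d clusters (method: %s)\n",
    nrow(x), attr(x, "n_clusters"), attr(x, "method")
  ))
  NextMethod()
}

#' Cross-tabulate clusters against a sample annotation
#'
#' Counts and within-cluster fractions of an annotation (e.g. cancer type or
#' cell of origin) per cluster. Samples without an annotation are tallied in
#' an `n_unannotated` column and excluded from the fraction denominators, so
#' fractions per cluster sum to 1 over the annotated samples.
#'
#' @param clusters An `rp_clusters` tibble (or any tibble with `sample` and
#'   `cluster` columns).
#' @param annotation Named character vector (names = sample ids), or a tibble
#'   with columns `sample` and `category`.
#' @return A tibble `cluster`, `category`, `n`, `n_annotated`, `fraction`,
#'   `n_unannotated`.
#' @examples
#' cl <- tibble::tibble(sample = c("a", "b", "c"), cluster = "cluster_1")
#' crosstab_clusters(cl, c(a = "T-ALL", b = "T-ALL", c = "B-ALL"))
#' @export
crosstab_clusters <- function(clusters, annotation) {
  if (is.data.frame(annotation)) {
    annotation <- setNames(as.character(annotation[[2]]), annotation[[1]])
  }
  df <- tibble(
    cluster = clusters$cluster,
    category = unname(annotation[clusters$sample])
  )
  totals <- df |>
    group_by(.data$cluster) |>
    summarise(
      n_annotated = sum(!is.na(.data$category)),
      n_unannotated = sum(is.na(.data$category)),
      .groups = "drop"
    )
  df |>
    filter(!is.na(.data$category)) |>
    count(.data$cluster, .data$category, name = "n") |>
    left_join(totals, by = "cluster") |>
    mutate(fraction = .data$n / .data$n_annotated) |>
    select("cluster", "category", "n", "n_annotated", "fraction", "n_unannotated")
}
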