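# Self-organizing map validation. Clusters found on the t-SNE embedding are
# checked with an independent method: samples are mapped to a hexagonal SOM
# grid trained on the log2 normalized RP values, nodes are colored by the
# majority (>50%) cluster among their samples, and spatial co-localization of
# same-colored nodes quantifies agreement between the two views.

# Hexagonal layout: odd rows are offset by half a unit, rows are sqrt(3)/2
# apart, so each interior node has 6 neighbors at distance 1.
hex_grid <- function(gx, gy) {
  g <- expand.grid(col = seq_len(gx), row = seq_len(gy))
  tibble(
    node = seq_len(gx * gy),
    col = g$col, row = g$row,
    x = g$col + ifelse(g$row %% 2 == 0, 0.5, 0),
    y = g$row * sqrt(3) / 2
  )
}

default_grid_dims <- function(n_samples) {
  side <- max(2L, round(sqrt(5 * sqrt(n_samples))))
  c(side, side)
}

#' Train a hexagonal self-organizing map on normalized RP values
#'
#' Classic online Kohonen training on `log2(value + pseudocount)` sample
#' vectors, so the SOM's Euclidean geometry matches the log-scale distance
#' used for the embedding. For each of `rlen` presentations a random sample is
#' drawn, its Euclidean-nearest codebook vector (best-matching unit, BMU) is
#' found, and every codebook vector w is moved by
#' `alpha(t) * h(t, node, bmu) * (x - w)` with a Gaussian neighborhood h on
#' the hex layout. The learning rate declines linearly 0.05 to 0.01 and the
#' neighborhood radius declines linearly from the 2/3 quantile of all
#' node-to-node distances to zero. Codebooks are initialized from randomly
#' sampled input vectors.
#'
#' @param m An `rp_norm` tibble (linear scale; log2 is taken internally).
#' @param gx,gy Grid dimensions; default a square-ish grid with about
#'   `5 * sqrt(n_samples)` nodes.
#' @param rlen Number of single-sample presentations (default 10000).
#' @param seed Integer seed.
#' @param pseudocount Added before log2; default `target_sum * 1e-6`.
#' @param alpha Length-2 learning-rate schedule (start, end).
#' @param train Set `FALSE` to skip training and return the initialized
#'   codebook (useful for before/after comparisons).
#' @return An object of class `rp_som`: list with `codebook` (nodes x RPs),
#'   `grid` (hex layout tibble), `gx`, `gy`, `rlen`, `seed`, `pseudocount`
#'   and `rp_genes`.
#' @export
train_som <- function(m, gx = NULL, gy = NULL, rlen = 10000L, seed = 1L,
                      pseudocount = NULL, alpha = c(0.05, 0.01), train = TRUE) {
  stopifnot(inherits(m, "rp_expr"))
  if (train && rlen <= 0) abort("rlen must be positive")
  mat <- expr_matrix(m)
  if (ncol(mat) < 2) abort("need at least 2 samples")
  if (is.null(pseudocount)) {
    s <- attr(m, "target_sum", exact = TRUE)
    pseudocount <- if (is.null(s)) 0 else s * 1e-6
  }
  X <- t(log2(mat + pseudocount)) # samples x RPs
  if (!all(is.finite(X))) abort("non-finite values after log2; check the pseudocount")
  if (is.null(gx) || is.null(gy)) {
    dims <- default_grid_dims(nrow(X))
    gx <- gx %||% dims[1]
    gy <- gy %||% dims[2]
  }
  grid <- hex_grid(gx, gy)
  nn <- nrow(grid)
  if (nn < 2) abort("grid must have at least 2 nodes")
  gd <- as.matrix(dist(cbind(grid$x, grid$y)))
  r0 <- unname(quantile(gd[upper.tri(gd)], 2 / 3))

  withr::with_seed(as.integer(seed), {
    init_idx <- sample.int(nrow(X), nn, replace = nrow(X) < nn)
    codebook <- X[init_idx, , drop = FALSE]
    rownames(codebook) <- NULL
    if (train) {
      pres <- sample.int(nrow(X), rlen, replace = TRUE)
      alphas <- seq(alpha[1], alpha[2], length.out = rlen)
      radii <- seq(r0, 0, length.out = rlen)
      for (t in seq_len(rlen)) {
        xv <- X[pres[t], ]
        delta <- sweep(codebook, 2, xv, `-`)
        bmu <- which.min(rowSums(delta^2))
        sigma <- max(radii[t], 1e-3)
        h <- exp(-gd[, bmu]^2 / (2 * sigma^2))
        codebook <- codebook - (alphas[t] * h) * delta
      }
    }
    structure(list(
      codebook = codebook, grid = grid, gx = gx, gy = gy,
      rlen = as.integer(rlen), seed = as.integer(seed),
      pseudocount = pseudocount, rp_genes = colnames(X)
    ), class = "rp_som")
  })
}

#' @export
print.rp_som <- function(x, ...) {
  cat(sprintf(
    "<rp_som> %dx%d hexagonal grid, %d RPs, rlen %d, seed %d\n",
    x$gx, x$gy, length(x$rp_genes), x$rlen, x$seed
  ))
  invisible(x)
}

#' Map samples to their best-matching SOM node
#'
#' Assigns every sample to the node with the Euclidean-nearest codebook
#' vector in the same log2 space used for training; ties go to the lowest
#' node index.
#'
#' @param som An `rp_som`.
#' @param m An `rp_norm`/`rp_expr` tibble with the same RP rows the SOM was
#'   trained on.
#' @return A tibble `sample`, `node`, `dist` (Euclidean distance to the BMU).
#' @export
map_samples <- function(som, m) {
  stopifnot(inherits(som, "rp_som"), inherits(m, "rp_expr"))
  mat <- expr_matrix(m)
  if (nrow(mat) != ncol(som$codebook)) {
    abort(sprintf(
      "dimension mismatch: SOM trained on %d RPs, data has %d genes",
      ncol(som$codebook), nrow(mat)
    ))
  }
  X <- t(log2(mat + som$pseudocount))
  # squared distances samples x nodes
  d2 <- outer(rowSums(X^2), rowSums(som$codebook^2), `+`) - 2 * tcrossprod(X, som$codebook)
  bmu <- max.col(-d2, ties.method = "first")
  tibble(
    sample = colnames(mat), node = bmu,
    dist = sqrt(pmax(d2[cbind(seq_len(nrow(X)), bmu)], 0))
  )
}

#' Quantization error of a mapping
#'
#' Mean Euclidean distance of samples to their best-matching unit; training
#' should not increase it relative to the initialized codebook.
#'
#' @param som An `rp_som`.
#' @param m The normalized tibble.
#' @return A single nonnegative number.
#' @export
quantization_error <- function(som, m) mean(map_samples(som, m)$dist)

#' Color SOM nodes by majority cluster
#'
#' A node takes a cluster's color iff strictly more than 50% of the samples
#' mapping to it belong to that cluster; an exact tie (or no majority) is
#' `"mixed"`, and a node with no samples is `"empty"`.
#'
#' @param mapping A tibble from [map_samples()].
#' @param clusters An `rp_clusters` tibble covering the mapped samples.
#' @param som The `rp_som` (supplies the full node list and layout).
#' @return A tibble of class `rp_som_coloring`: `node`, `color`, `n_samples`,
#'   plus the hex layout columns, with the per-node cluster counts in the
#'   `counts` attribute.
#' @export
color_nodes <- function(mapping, clusters, som) {
  lab <- setNames(clusters$cluster, clusters$sample)
  cl <- unname(lab[mapping$sample])
  if (anyNA(cl)) abort("clusters do not cover all mapped samples")
  counts <- table(factor(mapping$node, levels = som$grid$node), cl)
  totals <- rowSums(counts)
  color <- rep("empty", nrow(som$grid))
  has <- totals > 0
  if (any(has)) {
    frac <- counts[has, , drop = FALSE] / totals[has]
    best <- max.col(frac, ties.method = "first")
    maj <- frac[cbind(seq_len(nrow(frac)), best)] > 0.5
    color[has] <- ifelse(maj, colnames(counts)[best], "mixed")
  }
  structure(
    tibble(
      node = som$grid$node, color = color, n_samples = as.integer(totals),
      col = som$grid$col, row = som$grid$row, x = som$grid$x, y = som$grid$y
    ),
    counts = unclass(counts),
    class = c("rp_som_coloring", class(tibble()))
  )
}

#' Spatial co-localization score of a node coloring
#'
#' For every colored node (not `"mixed"`/`"empty"`) with at least one colored
#' hex-neighbor, the fraction of those colored neighbors sharing its color is
#' computed; the score is the mean over such nodes. 1 means same-colored
#' nodes form perfectly segregated territories — the signature of cluster
#' structure confirmed by the SOM — while interleaved colors drive the score
#' toward 0.
#'
#' @param coloring An `rp_som_coloring`.
#' @param som The `rp_som` that produced it.
#' @return A number in `[0, 1]`.
#' @export
colocalization_score <- function(coloring, som) {
  colored <- !(coloring$color %in% c("mixed", "empty"))
  if (!any(colored)) abort("no colored nodes; cannot score co-localization")
  gd <- as.matrix(dist(cbind(som$grid$x, som$grid$y)))
  nb <- gd <= 1.01 & gd > 0
  fracs <- vapply(which(colored), function(i) {
    j <- which(nb[i, ] & colored)
    if (!length(j)) return(NA_real_)
    mean(coloring$color[j] == coloring$color[i])
  }, numeric(1))
  if (all(is.na(fracs))) abort("no colored node has a colored neighbor")
  mean(fracs, na.rm = TRUE)
}

#' Validate clusters with a SOM in one call
#'
#' Trains a SOM, maps the samples, colors the nodes by the supplied clusters
#' and returns the coloring together with the co-localization score and the
#' score of a label-permuted control (same SOM, shuffled cluster labels),
#' which calibrates what "no spatial structure" looks like.
#'
#' @param m An `rp_norm` tibble.
#' @param clusters An `rp_clusters` tibble.
#' @param ... Passed to [train_som()].
#' @param permute_seed Seed for the label permutation control.
#' @return A list of class `rp_som_validation`: `som`, `mapping`, `coloring`,
#'   `score`, `score_permuted`.
#' @export
som_validate <- function(m, clusters, ..., permute_seed = 1L) {
  som <- train_som(m, ...)
  mapping <- map_samples(som, m)
  coloring <- color_nodes(mapping, clusters, som)
  perm <- clusters
  withr::with_seed(as.integer(permute_seed), {
    perm$cluster <- sample(perm$cluster)
  })
  structure(list(
    som = som, mapping = mapping, coloring = coloring,
    score = colocalization_score(coloring, som),
    score_permuted = colocalization_score(color_nodes(mapping, perm, som), som)
  ), class = "rp_som_validation")
}

#' @export
print.rp_som_validation <- function(x, ...) {
  cat(sprintf(
    "<rp_som_validation> colocalization %.3f (label-permuted control %.3f)\n",
    x$score, x$score_permuted
  ))
  invisible(x)
}
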