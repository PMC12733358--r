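# Exact-gradient t-SNE consuming a precomputed distance matrix.
#
# The standard formulation: input similarities P are Gaussian kernels on the
# (squared) precomputed distances, with per-point bandwidths calibrated by
# binary search so each point's conditional distribution has the requested
# perplexity; the 2D layout minimizes KL(P || Q) where Q uses the Student-t
# kernel. The O(n^2) exact gradient is used throughout — no tree
# approximation — with the usual early exaggeration, adaptive gains and
# momentum schedule.

#' Embed samples in 2D by exact t-SNE on a precomputed distance
#'
#' @param d An [rp_distance()] result, or a symmetric numeric distance matrix
#'   with zero diagonal.
#' @param perplexity Target perplexity (default 30). Must be below
#'   `(n - 1) / 3`; larger values are reduced automatically with a warning.
#' @param seed Integer seed controlling the random initialization; identical
#'   distance, parameters and seed give identical coordinates.
#' @param max_iter Gradient iterations (default 1000).
#' @param learning_rate Gradient step size (default 200).
#' @param exaggeration Early-exaggeration factor applied to P for the first
#'   quarter of the iterations (default 12).
#' @return A tibble of class `rp_embedding` with columns `sample`, `x`, `y`
#'   and attributes `seed` and `perplexity`.
#' @export
embed_tsne <- function(d, perplexity = 30, seed = 1L, max_iter = 1000L,
                       learning_rate = 200, exaggeration = 12) {
  dm <- if (inherits(d, "rp_dist")) d$matrix else as.matrix(d)
  n <- nrow(dm)
  if (n < 4) abort("t-SNE needs at least 4 samples")
  if (!all(is.finite(dm))) abort("non-finite entries in the distance matrix")
  if (perplexity >= (n - 1) / 3) {
    perplexity <- max(1, (n - 1) / 3 - 1e-8)
    warn(sprintf("perplexity too large for %d samples; reduced to %.2f", n, perplexity))
  }
  P <- joint_probabilities(dm^2, perplexity)

  withr::with_seed(as.integer(seed), {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    exag_iter <- max_iter %/% 4L
    P_run <- P * exaggeration
    momentum <- 0.5
    for (it in seq_len(max_iter)) {
      if (it == exag_iter + 1L) P_run <- P
      if (it == 251L) momentum <- 0.8
      # Student-t kernel on the current layout
      sq <- rowSums(Y^2)
      num <- 1 / (1 + outer(sq, sq, `+`) - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- num / sum(num)
      W <- (P_run - pmax(Q, 1e-12)) * num
      grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - learning_rate * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    ids <- if (inherits(d, "rp_dist")) d$sample_ids else rownames(dm) %||% paste0("S", seq_len(n))
    structure(
      tibble(sample = ids, x = Y[, 1], y = Y[, 2]),
      seed = as.integer(seed), perplexity = perplexity,
      class = c("rp_embedding", class(tibble()))
    )
  })
}

# Conditional Gaussian similarities with per-point bandwidth found by binary
# search on the precision so that the row entropy matches log(perplexity);
# then symmetrized and normalized to sum to 1.
joint_probabilities <- function(d2, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    beta_lo <- -Inf
    beta_hi <- Inf
    di <- d2[i, -i]
    for (k in seq_len(max_tries)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) {
        h <- 0
        p[] <- 0
      } else {
        h <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(h - target) < tol) break
      if (h > target) {
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    if (sum(p) == 0) p <- rep(1 / length(di), length(di)) # all distances equal/huge
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

#' @export
print.rp_embedding <- function(x, ...) {
  cat(sprintf(
    "<rp_embedding> %d samples (perplexity %.1f, seed %d)\n",
    nrow(x), attr(x, "perplexity"), attr(x, "seed")
  ))
  NextMethod()
}
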