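# Independent brute-force oracles. These deliberately share no code with the
# package: nested loops, full enumeration and closed forms only.

# L1-in-log2 pairwise distance by nested loops.
oracle_distance <- function(mat, pseudocount = 0) {
  ns <- ncol(mat)
  d <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      s <- 0
      for (r in seq_len(nrow(mat))) {
        s <- s + abs(log2((mat[r, i] + pseudocount) / (mat[r, j] + pseudocount)))
      }
      d[i, j] <- s
    }
  }
  d
}

# Two-sided Fisher p by full hypergeometric enumeration over the support,
# probability-mass convention with a relative tolerance for float ties.
oracle_fisher_p <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + rel_tol)])
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all C(m+n, m) rank
# assignments (no ties assumed).
oracle_wilcoxon_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2 # U statistic of x
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]) - m * (m + 1) / 2)
  mu <- m * length(y) / 2
  mean(abs(u_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Product-limit estimator by direct computation.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  est <- numeric(length(ut))
  for (k in seq_along(ut)) {
    n_risk <- sum(time >= ut[k])
    d_k <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d_k / n_risk)
    est[k] <- s
  }
  list(time = ut, surv = est)
}

# Brute-force best-matching unit search.
oracle_bmu <- function(X, codebook) {
  apply(X, 1, function(x) {
    d <- apply(codebook, 1, function(w) sum((x - w)^2))
    which(d == min(d))[1]
  })
}

# Colocalization by explicit neighbor loops over the hex layout.
oracle_colocalization <- function(colors, grid) {
  colored <- which(!(colors %in% c("mixed", "empty")))
  fr <- c()
  for (i in colored) {
    same <- 0
    tot <- 0
    for (j in colored) {
      if (i == j) next
      dd <- sqrt((grid$x[i] - grid$x[j])^2 + (grid$y[i] - grid$y[j])^2)
      if (dd <= 1.01) {
        tot <- tot + 1
        if (colors[i] == colors[j]) same <- same + 1
      }
    }
    if (tot > 0) fr <- c(fr, same / tot)
  }
  mean(fr)
}

# Mean silhouette width of a labeling on 2D points.
mean_silhouette <- function(pts, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), dist(pts))
  mean(sil[, "sil_width"])
}
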