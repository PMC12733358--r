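# The pairwise sample distance at the core of the method: for samples i, j the
# distance is the sum over RP genes of |log2 fold change|, i.e. the L1 distance
# between samples in log2 expression space. Because every sample's RP sum has
# been equalized, this measures differences in RP *ratios* only.

#' Pairwise L1-in-log2 RP distance
#'
#' Computes `d(i, j) = sum_r | log2((m[r, i] + c) / (m[r, j] + c)) |` over the
#' RP genes r of a normalized matrix. The pseudocount `c` guards zeros
#' (RNA-seq zeros do occur for low-expressed RPs); with `c = 0` any zero value
#' is an error. The result is a genuine metric (symmetric, zero diagonal,
#' triangle inequality) because it is an L1 distance in log2 space.
#'
#' @param m An `rp_norm` tibble from [equalize_rp_sum()] (or any `rp_expr` on
#'   a linear scale).
#' @param pseudocount Nonnegative pseudocount `c`; default `target_sum * 1e-6`
#'   (i.e. 1 in CPM-like units).
#' @return An object of class `rp_dist`: list with `sample_ids`, the distance
#'   `matrix`, `pseudocount` and `n_rp`.
#' @examples
#' x <- as_expr(data.frame(gene = c("A", "B"), s1 = c(0.5, 0.5), s2 = c(0.25, 0.75)), "fpkm")
#' rp_distance(x, pseudocount = 0)$matrix
#' @export
rp_distance <- function(m, pseudocount = NULL) {
  stopifnot(inherits(m, "rp_expr"))
  mat <- expr_matrix(m)
  if (ncol(mat) < 2) abort("need at least 2 samples for a pairwise distance")
  if (is.null(pseudocount)) {
    s <- attr(m, "target_sum", exact = TRUE)
    pseudocount <- if (is.null(s)) 0 else s * 1e-6
  }
  if (pseudocount < 0) abort("pseudocount must be nonnegative")
  if (pseudocount == 0 && any(mat == 0)) {
    abort("zero values present; supply a positive pseudocount")
  }
  lg <- log2(mat + pseudocount)
  d <- as.matrix(dist(t(lg), method = "manhattan"))
  diag(d) <- 0
  structure(
    list(
      sample_ids = colnames(mat), matrix = d,
      pseudocount = pseudocount, n_rp = nrow(mat)
    ),
    class = "rp_dist"
  )
}

#' @export
print.rp_dist <- function(x, ...) {
  cat(sprintf(
    "<rp_dist> %d samples, %d RPs, pseudocount %g\n",
    length(x$sample_ids), x$n_rp, x$pseudocount
  ))
  invisible(x)
}

#' Tidy a pairwise distance into a long tibble
#' @param x An `rp_dist`.
#' @param ... Unused.
#' @return A tibble with columns `sample_1`, `sample_2`, `distance`
#'   (unordered pairs, i < j).
#' @method tidy rp_dist
#' @export
tidy.rp_dist <- function(x, ...) {
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble(
    sample_1 = x$sample_ids[idx[, 1]],
    sample_2 = x$sample_ids[idx[, 2]],
    distance = x$matrix[idx]
  )
}

#' Write a distance matrix as a square TSV
#' @param d An `rp_dist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance <- function(d, path) {
  out <- tibble(sample = d$sample_ids, as_tibble(d$matrix))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
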