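# Small shared fixtures, built in code.

tiny_spec <- function(seed = 1L, ...) {
  cohort_spec(
    samples_per_subtype = 10L, n_decoy_genes = 10L, seed = seed, ...
  )
}

default_norm <- function(seed = 1L, ...) {
  co <- generate_cohort(cohort_spec(seed = seed, ...))
  list(cohort = co, norm = normalize_rp(co$expression, co$gene_lengths))
}

random_expr <- function(n_genes, n_samples, seed = 1L, genes = NULL) {
  withr::with_seed(seed, {
    m <- matrix(rexp(n_genes * n_samples, rate = 1e-3), n_genes, n_samples)
    rownames(m) <- if (is.null(genes)) paste0("G", seq_len(n_genes)) else genes
    colnames(m) <- paste0("S", seq_len(n_samples))
    as_expr(tibble::tibble(gene = rownames(m), tibble::as_tibble(m)), kind = "fpkm")
  })
}
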