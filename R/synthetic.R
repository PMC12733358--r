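# Seeded synthetic cohort generator: planted per-subtype RP signatures,
# library-size variation, log-normal noise, subtype-linked survival and
# binary clinical markers. Every downstream stage of the pipeline can be
# exercised on its output without access to patient data.

#' Specify a synthetic multi-subtype cohort
#'
#' Builds the parameter object consumed by [generate_cohort()]. The defaults
#' describe the package's reference operating point: three subtypes of 50
#' samples, 78 RP genes plus 100 non-RP decoy genes, and per-subtype
#' multiplicative signatures of +0.8 log2 units (about 1.7-fold, i.e. below
#' 2-fold, the magnitude regime typical of RP signatures) planted on disjoint
#' blocks of 15 RPs.
#'
#' @param n_subtypes Number of subtypes.
#' @param samples_per_subtype Samples per subtype (recycled to `n_subtypes`);
#'   each must be at least 2.
#' @param n_rp_genes Number of RP genes (default 78, the packaged panel size).
#' @param n_decoy_genes Number of non-RP decoy genes that RP restriction must
#'   remove.
#' @param signature_log2 Either a `n_subtypes` x `n_rp_genes` matrix of
#'   additive log2 offsets, or `NULL` for the default disjoint-block design
#'   controlled by `signature_size` and `signature_magnitude`.
#' @param signature_size Number of RPs in each subtype's block (default 15).
#' @param signature_magnitude Log2 offset applied on a subtype's block
#'   (default 0.8; magnitudes below 1 keep effects under 2-fold).
#' @param noise_sd Standard deviation of the per-cell Gaussian noise on the
#'   log2 scale (default 0.25).
#' @param libsize_log_sd Standard deviation of per-sample log library-size
#'   factors (natural log; default 0.5).
#' @param gene_length_range Range (bases) gene lengths are drawn from,
#'   uniformly (default 500-5000).
#' @param hazard_per_subtype Exponential event hazards per subtype, events per
#'   year (recycled; default `c(0.5, 0.15, 0.25)` truncated/recycled to
#'   `n_subtypes`).
#' @param censor_rate Exponential censoring rate, per year (default 0.15).
#' @param marker_prevalence Matrix (`n_subtypes` x n_markers) of Bernoulli
#'   prevalences of binary clinical markers per subtype; default one marker
#'   with prevalence `c(0.6, 0.1, 0.3)` recycled to `n_subtypes`.
#' @param seed Integer seed; identical spec and seed reproduce the cohort
#'   bit for bit.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subtypes = 3L,
                        samples_per_subtype = 50L,
                        n_rp_genes = 78L,
                        n_decoy_genes = 100L,
                        signature_log2 = NULL,
                        signature_size = 15L,
                        signature_magnitude = 0.8,
                        noise_sd = 0.25,
                        libsize_log_sd = 0.5,
                        gene_length_range = c(500L, 5000L),
                        hazard_per_subtype = c(0.5, 0.15, 0.25),
                        censor_rate = 0.15,
                        marker_prevalence = c(0.6, 0.1, 0.3),
                        seed = 1L) {
  stopifnot(n_subtypes >= 1, n_rp_genes >= 1, n_decoy_genes >= 0)
  if (noise_sd < 0) abort("noise_sd must be nonnegative")
  if (libsize_log_sd < 0) abort("libsize_log_sd must be nonnegative")
  samples_per_subtype <- rep_len(as.integer(samples_per_subtype), n_subtypes)
  if (any(samples_per_subtype < 2)) abort("each subtype needs at least 2 samples")
  if (is.null(signature_log2)) {
    signature_log2 <- matrix(0, n_subtypes, n_rp_genes)
    for (k in seq_len(n_subtypes)) {
      lo <- (k - 1L) * signature_size + 1L
      hi <- min(k * signature_size, n_rp_genes)
      if (lo <= hi) signature_log2[k, lo:hi] <- signature_magnitude
    }
  } else {
    signature_log2 <- as.matrix(signature_log2)
    stopifnot(nrow(signature_log2) == n_subtypes, ncol(signature_log2) == n_rp_genes)
  }
  hazard_per_subtype <- rep_len(hazard_per_subtype, n_subtypes)
  if (any(hazard_per_subtype <= 0)) abort("hazards must be positive")
  if (censor_rate <= 0) abort("censor_rate must be positive")
  if (!is.matrix(marker_prevalence)) {
    marker_prevalence <- matrix(rep_len(marker_prevalence, n_subtypes),
      ncol = 1, dimnames = list(NULL, "marker_1")
    )
  }
  stopifnot(nrow(marker_prevalence) == n_subtypes)
  if (any(marker_prevalence < 0 | marker_prevalence > 1)) {
    abort("marker prevalences must be in [0, 1]")
  }
  if (is.null(colnames(marker_prevalence))) {
    colnames(marker_prevalence) <- paste0("marker_", seq_len(ncol(marker_prevalence)))
  }
  structure(list(
    n_subtypes = as.integer(n_subtypes),
    samples_per_subtype = samples_per_subtype,
    n_rp_genes = as.integer(n_rp_genes),
    n_decoy_genes = as.integer(n_decoy_genes),
    signature_log2 = signature_log2,
    noise_sd = noise_sd,
    libsize_log_sd = libsize_log_sd,
    gene_length_range = as.integer(gene_length_range),
    hazard_per_subtype = hazard_per_subtype,
    censor_rate = censor_rate,
    marker_prevalence = marker_prevalence,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

synthetic_gene_ids <- function(n_rp, n_decoy) {
  panel <- rp_gene_set()
  rp <- if (n_rp <= length(panel)) {
    panel[seq_len(n_rp)]
  } else {
    c(panel, sprintf("RPX%03d", seq_len(n_rp - length(panel))))
  }
  decoy <- if (n_decoy > 0) sprintf("DECOY%04d", seq_len(n_decoy)) else character()
  list(rp = rp, decoy = decoy)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_spec()]. The expression value of gene g in
#' sample s of subtype k is
#' `L_s * len_g * b_g * 2^(sig_{k,g} + eps)` with `eps ~ N(0, noise_sd^2)`,
#' `L_s = exp(N(0, libsize_log_sd^2))` a per-sample library-size factor, and
#' `b_g` a per-gene baseline drawn once per cohort from a log-normal
#' (sdlog 1.5) to mimic the skewed abundance distribution of transcripts.
#' Decoy genes carry zero signature and identifiers outside the RP panel, so
#' RP restriction must remove them. For `kind = "counts"` the value is rounded
#' (and includes the gene-length factor, which [length_normalize()] undoes);
#' `"fpkm"` omits the length factor; `"log2_intensity"` returns the log2 of
#' the length-free value.
#'
#' @param spec A [cohort_spec()].
#' @param kind Output measurement kind.
#' @return A list of class `synthetic_cohort` with elements `expression`
#'   (an [as_expr()] tibble), `gene_lengths` (tibble `gene`, `length_bp`),
#'   `true_labels` (tibble `sample`, `subtype`), `survival` (tibble from
#'   [generate_survival()]), `markers` (tibble `sample`, one column per
#'   marker) and `spec`.
#' @examples
#' co <- generate_cohort(cohort_spec(samples_per_subtype = 5, seed = 7))
#' dim(co$expression)
#' @export
generate_cohort <- function(spec, kind = c("counts", "fpkm", "log2_intensity")) {
  stopifnot(inherits(spec, "cohort_spec"))
  kind <- match.arg(kind)
  withr::with_seed(spec$seed, {
    ids <- synthetic_gene_ids(spec$n_rp_genes, spec$n_decoy_genes)
    genes <- c(ids$rp, ids$decoy)
    if (anyDuplicated(genes)) abort("duplicate gene identifiers in synthetic design")
    n_genes <- length(genes)
    ns <- spec$samples_per_subtype
    n_samples <- sum(ns)
    samples <- sprintf("S%04d", seq_len(n_samples))
    subtype <- rep(paste0("subtype_", seq_len(spec$n_subtypes)), times = ns)

    baseline <- exp(rnorm(n_genes, 0, 1.5))          # b_g, heavy-tailed positive
    lengths <- round(runif(
      n_genes, spec$gene_length_range[1], spec$gene_length_range[2]
    ))
    libsize <- exp(rnorm(n_samples, 0, spec$libsize_log_sd))

    sig <- matrix(0, n_genes, n_samples)             # per-gene, per-sample log2 offset
    k_of_sample <- rep(seq_len(spec$n_subtypes), times = ns)
    sig[seq_len(spec$n_rp_genes), ] <- t(spec$signature_log2)[, k_of_sample]
    eps <- matrix(rnorm(n_genes * n_samples, 0, spec$noise_sd), n_genes, n_samples)

    linear <- baseline * 2^(sig + eps)               # length-free signal
    linear <- sweep(linear, 2, libsize, `*`)
    vals <- switch(kind,
      counts = round(linear * lengths),
      fpkm = linear,
      log2_intensity = log2(linear)
    )
    dimnames(vals) <- list(genes, samples)

    surv <- generate_survival(
      setNames(subtype, samples),
      hazards = setNames(spec$hazard_per_subtype, paste0("subtype_", seq_len(spec$n_subtypes))),
      censor_rate = spec$censor_rate,
      seed = sample.int(.Machine$integer.max, 1)
    )

    prev <- spec$marker_prevalence
    markers <- tibble(sample = samples)
    for (j in seq_len(ncol(prev))) {
      markers[[colnames(prev)[j]]] <- rbinom(n_samples, 1, prev[k_of_sample, j])
    }

    structure(list(
      expression = expr_from_matrix(vals, kind = kind),
      gene_lengths = tibble(gene = genes, length_bp = as.integer(lengths)),
      true_labels = tibble(sample = samples, subtype = subtype),
      survival = surv,
      markers = markers,
      spec = spec
    ), class = "synthetic_cohort")
  })
}

#' Generate subtype-linked survival data
#'
#' Event times are exponential with the subtype's hazard; censoring times are
#' independent exponential with rate `censor_rate`. The observed time is the
#' minimum of the two and the event flag is 1 when the event came first.
#'
#' @param labels Named character vector (names = sample ids, values =
#'   subtype), or a tibble with columns `sample` and `subtype`.
#' @param hazards Named positive vector of hazards (events per year), one per
#'   subtype appearing in `labels`.
#' @param censor_rate Positive exponential censoring rate (per year).
#' @param seed Integer seed.
#' @return A tibble `sample`, `subtype`, `time_years`, `event`.
#' @export
generate_survival <- function(labels, hazards, censor_rate, seed = 1L) {
  if (is.data.frame(labels)) labels <- setNames(labels$subtype, labels$sample)
  if (any(hazards <= 0)) abort("hazards must be positive")
  if (censor_rate <= 0) abort("censor_rate must be positive")
  h <- hazards[as.character(labels)]
  if (anyNA(h)) {
    abort(paste0(
      "no hazard given for subtype(s): ",
      paste(setdiff(unique(labels), names(hazards)), collapse = ", ")
    ))
  }
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    t_event <- rexp(length(h), rate = h)
    t_cens <- rexp(length(h), rate = censor_rate)
    tibble(
      sample = names(labels),
      subtype = as.character(labels),
      time_years = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
  })
}

#' Write a synthetic cohort to a directory
#'
#' Writes `expression.tsv` (genes x samples), `gene_lengths.tsv` and
#' `clinical.tsv` (sample_id, time_years, event, marker columns,
#' true_subtype).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$gene_lengths, file.path(dir, "gene_lengths.tsv"), progress = FALSE)
  clinical <- cohort$survival |>
    select("sample", "time_years", "event") |>
    left_join(cohort$markers, by = "sample") |>
    left_join(cohort$true_labels, by = "sample") |>
    rename(sample_id = "sample", true_subtype = "subtype")
  readr::write_tsv(clinical, file.path(dir, "clinical.tsv"), progress = FALSE)
  invisible(dir)
}
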