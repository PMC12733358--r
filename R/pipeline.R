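# Config-driven orchestration: normalize -> distance -> embed -> cluster ->
# SOM validation -> differential expression -> clinical/survival, with every
# parameter, seed and output checksum recorded in a JSON manifest so a run is
# self-describing and reproducible.

#' Default pipeline configuration
#'
#' Returns the full configuration list with defaults filled in; any element
#' can be overridden via `...` or by the YAML file passed to
#' [run_pipeline()].
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    expression = NULL,       # path to expression TSV/CSV (or rp_expr tibble)
    kind = "counts",         # counts | fpkm | log2_intensity
    gene_lengths = NULL,     # path or tibble; required for counts
    rp_list = NULL,          # path to one-symbol-per-line file; NULL = packaged panel
    clinical = NULL,         # path or tibble; survival stage skipped when NULL
    min_present = 50L,
    target_sum = 1e6,
    pseudocount = NULL,      # NULL = target_sum * 1e-6
    perplexity = 30,
    tsne_iter = 1000L,
    cluster_method = "density",
    cluster_min_size = 5L,
    cluster_eps_factor = 3,
    cluster_k = NULL,
    som_gx = NULL,
    som_gy = NULL,
    som_rlen = 10000L,
    time_col = "time_years",
    event_col = "event",
    out_dir = NULL,
    seed = 1L
  )
  utils::modifyList(defaults, list(...))
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  do.call(pipeline_config, config)
}

#' Run the full RP signature pipeline
#'
#' Executes normalization, pairwise distance, t-SNE embedding, cluster
#' extraction, SOM validation and per-RP differential expression, and — when
#' a clinical table is supplied — the cluster-versus-clinical battery. Each
#' stage's output is written as TSV/JSON under `out_dir`, and a
#' `manifest.json` records inputs, every parameter, the seed and an MD5
#' checksum per output file: identical config and seed reproduce identical
#' checksums. A missing clinical table skips the survival stage with a
#' manifest note; any stage error aborts with the stage name while earlier
#' outputs remain on disk.
#'
#' @param config A [pipeline_config()] list, a named list of overrides, or a
#'   path to a YAML file of overrides.
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- read_config(if (is.character(config)) config else as.list(config))
  if (is.null(cfg$out_dir)) abort("config$out_dir is required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  notes <- character()
  stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  emit <- function(name) outputs[[length(outputs) + 1]] <<- file.path(cfg$out_dir, name)

  rp_genes <- if (is.null(cfg$rp_list)) rp_gene_set() else read_rp_genes(cfg$rp_list)

  norm <- stage("normalize", function() {
    x <- if (inherits(cfg$expression, "rp_expr")) {
      cfg$expression
    } else {
      read_expression(cfg$expression, kind = cfg$kind)
    }
    lengths <- cfg$gene_lengths
    if (is.character(lengths)) {
      lengths <- readr::read_tsv(lengths, show_col_types = FALSE, progress = FALSE)
    }
    n <- normalize_rp(x, lengths,
      rp_genes = rp_genes,
      min_present = cfg$min_present, target_sum = cfg$target_sum
    )
    write_expression(n, file.path(cfg$out_dir, "normalized.tsv"))
    emit("normalized.tsv")
    n
  })

  d <- stage("distance", function() {
    d <- rp_distance(norm, pseudocount = cfg$pseudocount)
    write_distance(d, file.path(cfg$out_dir, "distance.tsv"))
    emit("distance.tsv")
    d
  })

  emb <- stage("embed", function() {
    e <- embed_tsne(d,
      perplexity = cfg$perplexity, seed = cfg$seed,
      max_iter = cfg$tsne_iter
    )
    readr::write_tsv(as_tibble(e), file.path(cfg$out_dir, "embedding.tsv"), progress = FALSE)
    emit("embedding.tsv")
    e
  })

  cl <- stage("cluster", function() {
    cl <- if (cfg$cluster_method == "density") {
      extract_clusters(emb,
        method = "density",
        eps_factor = cfg$cluster_eps_factor, min_size = cfg$cluster_min_size
      )
    } else {
      extract_clusters(d, method = "hclust", k = cfg$cluster_k, min_size = cfg$cluster_min_size)
    }
    readr::write_tsv(as_tibble(cl), file.path(cfg$out_dir, "clusters.tsv"), progress = FALSE)
    emit("clusters.tsv")
    cl
  })

  somv <- stage("som_validate", function() {
    v <- som_validate(norm, cl,
      gx = cfg$som_gx, gy = cfg$som_gy,
      rlen = cfg$som_rlen, seed = cfg$seed, permute_seed = cfg$seed
    )
    readr::write_tsv(
      tibble(node = seq_len(nrow(v$som$codebook)), as_tibble(v$som$codebook)),
      file.path(cfg$out_dir, "som_codebook.tsv"),
      progress = FALSE
    )
    emit("som_codebook.tsv")
    readr::write_tsv(v$mapping, file.path(cfg$out_dir, "som_nodes.tsv"), progress = FALSE)
    emit("som_nodes.tsv")
    readr::write_tsv(as_tibble(v$coloring), file.path(cfg$out_dir, "som_coloring.tsv"),
      progress = FALSE
    )
    emit("som_coloring.tsv")
    jsonlite::write_json(
      list(colocalization = v$score, colocalization_permuted = v$score_permuted),
      file.path(cfg$out_dir, "som_score.json"),
      auto_unbox = TRUE, digits = NA
    )
    emit("som_score.json")
    v
  })

  stage("differential", function() {
    de <- rp_differential(norm, cl, pseudocount = cfg$pseudocount)
    readr::write_tsv(as_tibble(de), file.path(cfg$out_dir, "differential.tsv"), progress = FALSE)
    emit("differential.tsv")
    de
  })

  if (is.null(cfg$clinical)) {
    notes <- c(notes, "clinical table absent; survival stage skipped")
  } else {
    stage("survival", function() {
      clin <- cfg$clinical
      if (is.character(clin)) {
        clin <- readr::read_tsv(clin, show_col_types = FALSE, progress = FALSE)
      }
      rep <- cluster_clinical_report(cl, clin,
        time = cfg$time_col, event = cfg$event_col
      )
      write_clinical_report(rep, cfg$out_dir)
      emit("clinical_tests.tsv")
      emit("clinical_report.json")
      rep
    })
  }

  input_paths <- Filter(is.character, cfg[c("expression", "gene_lengths", "clinical", "rp_list")])
  manifest <- list(
    package = "rpsig",
    version = as.character(utils::packageVersion("rpsig")),
    seed = cfg$seed,
    inputs = input_paths,
    parameters = cfg[setdiff(names(cfg), c("expression", "clinical", "gene_lengths"))],
    n_rp_panel = length(rp_genes),
    som_colocalization = somv$score,
    notes = notes,
    outputs = lapply(setNames(outputs, basename(outputs)), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(manifest)
}
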