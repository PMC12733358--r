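# Reading expression tables and the RP-restricted compositional normalization.
#
# An expression table is a tibble whose first column ("gene") holds unique gene
# identifiers and whose remaining columns are samples. The measurement kind
# travels with the tibble as the "kind" attribute: "counts", "fpkm",
# "log2_intensity", or the derived kinds "rpk" (reads per kilobase) and
# "intensity" (linearized microarray values).

VALID_KINDS <- c("counts", "fpkm", "log2_intensity", "rpk", "intensity")

#' Construct an expression table from a data frame
#'
#' @param x A data frame with gene identifiers in the first column and one
#'   numeric column per sample.
#' @param kind Measurement kind: `"counts"`, `"fpkm"` or `"log2_intensity"`
#'   (the three supported input dialects), or a derived kind produced by the
#'   normalization steps.
#' @return A tibble of class `rp_expr` with a `kind` attribute.
#' @export
as_expr <- function(x, kind) {
  kind <- match.arg(kind, VALID_KINDS)
  x <- as_tibble(x)
  if (ncol(x) < 2L) abort("an expression table needs a gene column and at least one sample")
  names(x)[1] <- "gene"
  x$gene <- as.character(x$gene)
  if (anyDuplicated(x$gene)) {
    abort(paste0(
      "duplicate gene identifiers: ",
      paste(unique(x$gene[duplicated(x$gene)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(names(x))) abort("duplicate sample identifiers in header")
  num_ok <- vapply(x[-1], is.numeric, logical(1))
  if (!all(num_ok)) {
    abort(paste0("non-numeric sample column(s): ", paste(names(x)[-1][!num_ok], collapse = ", ")))
  }
  if (kind %in% c("counts", "fpkm") && any(as.matrix(x[-1]) < 0, na.rm = TRUE)) {
    abort(paste0("negative values are not allowed for kind '", kind, "'"))
  }
  structure(x, kind = kind, class = c("rp_expr", class(x)))
}

#' Measurement kind of an expression table
#' @param x An `rp_expr` tibble.
#' @return A string.
#' @export
expr_kind <- function(x) attr(x, "kind", exact = TRUE)

#' Convert an expression table to a gene-by-sample matrix
#' @param x An `rp_expr` tibble.
#' @return A numeric matrix with gene identifiers as row names.
#' @export
expr_matrix <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene
  storage.mode(m) <- "double"
  m
}

expr_from_matrix <- function(m, kind) {
  as_expr(tibble(gene = rownames(m), as_tibble(m)), kind = kind)
}

#' Read a delimited expression table
#'
#' Reads a TSV or CSV file (delimiter auto-detected from the header line) with
#' gene identifiers in the first column and sample identifiers in the header.
#' Non-numeric cells and duplicated gene or sample identifiers are errors.
#'
#' @param path Path to the delimited file.
#' @param kind Declared measurement kind: `"counts"`, `"fpkm"` or
#'   `"log2_intensity"`.
#' @return An `rp_expr` tibble (see [as_expr()]).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "RPL3\t10\t20", "RPS6\t5\t2"), tf)
#' read_expression(tf, kind = "counts")
#' @export
read_expression <- function(path, kind = c("counts", "fpkm", "log2_intensity")) {
  kind <- match.arg(kind)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, name_repair = "minimal"
  )
  if (anyDuplicated(names(raw))) {
    abort(paste0(
      "duplicate sample identifiers in ", path, ": ",
      paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", ")
    ))
  }
  vals <- raw[-1]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad)) {
      abort(sprintf(
        "non-numeric value '%s' at row %d (gene %s), column '%s' of %s",
        vals[[j]][bad[1]], bad[1], raw[[1]][bad[1]], names(vals)[j], path
      ))
    }
    vals[[j]] <- v
  }
  as_expr(tibble(gene = raw[[1]], vals), kind = kind)
}

#' Restrict an expression table to a ribosomal protein panel
#'
#' Keeps only genes in the RP panel (matched by exact symbol after uppercasing)
#' in panel order. A warning reports panels found incomplete — microarray
#' platforms commonly lack probes for some RPs — and fewer than `min_present`
#' panel genes is an error.
#'
#' @param x An `rp_expr` tibble.
#' @param rp_genes Character vector of RP gene symbols (default [rp_gene_set()]).
#' @param min_present Minimum number of panel genes that must be present.
#' @return An `rp_expr` tibble with rows in panel order and an `n_rp_found`
#'   attribute.
#' @export
restrict_to_rp <- function(x, rp_genes = rp_gene_set(), min_present = 50L) {
  stopifnot(inherits(x, "rp_expr"))
  if (min_present > length(rp_genes)) {
    abort("min_present cannot exceed the panel size")
  }
  idx <- match(toupper(rp_genes), toupper(x$gene))
  found <- which(!is.na(idx))
  if (length(found) < min_present) {
    abort(sprintf(
      "only %d of %d RP panel genes found (need at least %d)",
      length(found), length(rp_genes), min_present
    ))
  }
  if (length(found) < length(rp_genes)) {
    warn(sprintf(
      "%d of %d RP panel genes absent; normalizing over the %d present",
      length(rp_genes) - length(found), length(rp_genes), length(found)
    ))
  }
  out <- x[idx[found], ]
  out$gene <- rp_genes[found]
  structure(out,
    kind = expr_kind(x), n_rp_found = length(found),
    class = class(x)
  )
}

#' Convert counts to reads per kilobase
#'
#' Divides each gene's counts by its length in kilobases, the first step of the
#' counts dialect of the normalization.
#'
#' @param x An `rp_expr` tibble of kind `"counts"`.
#' @param lengths A data frame with columns `gene` and `length_bp`, or a named
#'   numeric vector of lengths in bases.
#' @return An `rp_expr` tibble of kind `"rpk"`.
#' @export
length_normalize <- function(x, lengths) {
  stopifnot(inherits(x, "rp_expr"))
  if (expr_kind(x) != "counts") {
    abort(paste0("length_normalize applies to counts, not kind '", expr_kind(x), "'"))
  }
  if (is.data.frame(lengths)) {
    lengths <- setNames(as.numeric(lengths[[2]]), as.character(lengths[[1]]))
  }
  len <- lengths[match(toupper(x$gene), toupper(names(lengths)))]
  bad <- is.na(len) | len <= 0
  if (any(bad)) {
    abort(paste0(
      "missing or nonpositive gene length for: ",
      paste(x$gene[bad], collapse = ", ")
    ))
  }
  m <- expr_matrix(x) / (as.numeric(len) / 1000)
  expr_from_matrix(m, kind = "rpk")
}

#' Linearize log2 microarray intensities
#'
#' Applies `x -> 2^x` to a log2-intensity table, the first step of the
#' microarray dialect of the normalization.
#'
#' @param x An `rp_expr` tibble of kind `"log2_intensity"`.
#' @return An `rp_expr` tibble of kind `"intensity"`.
#' @export
linearize_log2 <- function(x) {
  stopifnot(inherits(x, "rp_expr"))
  if (expr_kind(x) != "log2_intensity") {
    abort(paste0("linearize_log2 applies to log2_intensity, not kind '", expr_kind(x), "'"))
  }
  expr_from_matrix(2^expr_matrix(x), kind = "intensity")
}

#' Equalize the per-sample RP sum
#'
#' Scales every sample (column) so that its sum over the retained RP genes
#' equals `target_sum`, removing inter-sample variation in total RP signal so
#' that only the ratios between RPs remain. This is the final, defining step of
#' the normalization: all downstream quantities are ratios and therefore
#' invariant to the choice of `target_sum`.
#'
#' @param x An `rp_expr` tibble on a linear scale (any kind except
#'   `"log2_intensity"`), typically already restricted to the RP panel.
#' @param target_sum Positive constant each sample column is scaled to sum to.
#'   Default `1e6`, giving CPM-like units.
#' @return A tibble of class `rp_norm` with attributes `target_sum` and
#'   `n_rp`.
#' @examples
#' x <- as_expr(data.frame(gene = c("A", "B", "C"), s1 = c(2, 3, 5)), "fpkm")
#' equalize_rp_sum(x, target_sum = 1)
#' @export
equalize_rp_sum <- function(x, target_sum = 1e6) {
  stopifnot(inherits(x, "rp_expr"), target_sum > 0)
  if (expr_kind(x) == "log2_intensity") {
    abort("equalize_rp_sum needs linear values; call linearize_log2() first")
  }
  m <- expr_matrix(x)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    abort(paste0("all-zero sample column(s): ", paste(colnames(m)[cs <= 0], collapse = ", ")))
  }
  m <- sweep(m, 2, target_sum / cs, `*`)
  out <- tibble(gene = rownames(m), as_tibble(m))
  structure(out,
    target_sum = target_sum, n_rp = nrow(m),
    class = c("rp_norm", "rp_expr", class(tibble())),
    kind = "normalized"
  )
}

#' One-call RP normalization
#'
#' Chains the dialect-appropriate steps: counts are restricted to the RP panel,
#' length-corrected and sum-equalized; FPKM values are restricted and
#' sum-equalized; log2 intensities are linearized, restricted and
#' sum-equalized.
#'
#' @param x An `rp_expr` tibble (kind `"counts"`, `"fpkm"` or
#'   `"log2_intensity"`).
#' @param lengths Gene lengths (see [length_normalize()]); required for counts.
#' @param rp_genes RP panel (default [rp_gene_set()]).
#' @param min_present Minimum panel genes required (see [restrict_to_rp()]).
#' @param target_sum Per-sample RP sum after normalization.
#' @return An `rp_norm` tibble.
#' @export
normalize_rp <- function(x, lengths = NULL, rp_genes = rp_gene_set(),
                         min_present = 50L, target_sum = 1e6) {
  stopifnot(inherits(x, "rp_expr"))
  kind <- expr_kind(x)
  if (kind == "log2_intensity") x <- linearize_log2(x)
  x <- restrict_to_rp(x, rp_genes, min_present)
  if (kind == "counts") {
    if (is.null(lengths)) abort("counts require gene lengths for length_normalize()")
    x <- length_normalize(x, lengths)
  }
  equalize_rp_sum(x, target_sum)
}

#' Write an expression or normalized table as TSV
#' @param x An `rp_expr` or `rp_norm` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
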