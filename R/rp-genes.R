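# Default panel of human cytoplasmic ribosomal protein genes.

#' Default ribosomal protein gene panel
#'
#' Returns the packaged panel of 78 human cytoplasmic ribosomal protein (RP)
#' gene symbols: the canonical `RPS*`/`RPL*` genes plus `RPSA`, the acidic stalk
#' proteins `RPLP0`/`RPLP1`/`RPLP2` and `FAU` (which encodes RPS30), excluding
#' the sex-chromosome-specific paralogs `RPS4Y1` and `RPS4Y2` and
#' tissue-restricted paralogs (e.g. `RPL3L`, `RPL10L`, `RPL39L`). The panel is a
#' reconstruction of the RP genes considered functional in human tissues and is
#' fully overridable: any character vector of symbols, or a one-symbol-per-line
#' file read with [read_rp_genes()], can be passed wherever a panel is expected.
#'
#' @return A character vector of 78 unique gene symbols.
#' @examples
#' length(rp_gene_set())
#' @export
rp_gene_set <- function() {
  c(
    # small (40S) subunit
    "RPSA", "RPS2", "RPS3", "RPS3A", "RPS4X", "RPS5", "RPS6", "RPS7",
    "RPS8", "RPS9", "RPS10", "RPS11", "RPS12", "RPS13", "RPS14", "RPS15",
    "RPS15A", "RPS16", "RPS17", "RPS18", "RPS19", "RPS20", "RPS21", "RPS23",
    "RPS24", "RPS25", "RPS26", "RPS27", "RPS27A", "RPS28", "RPS29", "FAU",
    # large (60S) subunit
    "RPL3", "RPL4", "RPL5", "RPL6", "RPL7", "RPL7A", "RPL8", "RPL9",
    "RPL10", "RPL10A", "RPL11", "RPL12", "RPL13", "RPL13A", "RPL14", "RPL15",
    "RPL17", "RPL18", "RPL18A", "RPL19", "RPL21", "RPL22", "RPL23", "RPL23A",
    "RPL24", "RPL26", "RPL27", "RPL27A", "RPL28", "RPL29", "RPL30", "RPL31",
    "RPL32", "RPL34", "RPL35", "RPL35A", "RPL36", "RPL36A", "RPL37", "RPL37A",
    "RPL38", "RPL39", "RPL41", "RPLP0", "RPLP1", "RPLP2"
  )
}

#' Read an RP gene panel from a text file
#'
#' Reads a one-symbol-per-line file (blank lines and `#` comments ignored),
#' uppercases the symbols and checks for duplicates.
#'
#' @param path Path to a plain-text file with one gene symbol per line.
#' @return A character vector of unique gene symbols.
#' @export
read_rp_genes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  genes <- toupper(lines[nzchar(lines)])
  if (anyDuplicated(genes)) {
    abort(paste0(
      "duplicate gene symbols in RP list: ",
      paste(unique(genes[duplicated(genes)]), collapse = ", ")
    ))
  }
  genes
}
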