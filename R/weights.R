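#' SNP weight table for the HDL-C genetic risk score
#'
#' Seven index SNPs from HDL-C-associated loci fine-mapped in African
#' Americans, with the effect allele and the published per-allele effect
#' estimate used as the weight in the weighted genetic risk score. The
#' unweighted score replaces every weight with 1. Weight magnitudes are
#' treated as abstract score weights; no unit interpretation is asserted.
#'
#' @param path Path to a tab-delimited weight table with columns
#'   `snp_id`, `gene`, `effect_allele`, `beta`. Defaults to the packaged
#'   seven-SNP table.
#'
#' @return A tibble with columns `snp_id` (rsID), `gene` (nearest gene
#'   label), `effect_allele` (single base, one of A/C/G/T) and `beta`
#'   (numeric per-allele weight).
#' @export
#' @examples
#' hdl_snp_weights()
hdl_snp_weights <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hdl_grs_weights.tsv", package = "phenogrs")
  read_snp_weights(path)
}

#' Read a SNP weight table
#'
#' @param path Tab-delimited file with columns `snp_id`, `gene`,
#'   `effect_allele`, `beta`.
#' @return A validated tibble of SNP weights.
#' @export
read_snp_weights <- function(path) {
  w <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(),
    gene = readr::col_character(),
    effect_allele = readr::col_character(),
    beta = readr::col_double()
  ))
  validate_snp_weights(w)
  w
}

#' Write a SNP weight table
#'
#' @param weights A SNP weight tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_snp_weights <- function(weights, path) {
  validate_snp_weights(weights)
  readr::write_tsv(weights, path)
  invisible(path)
}

validate_snp_weights <- function(w) {
  required <- c("snp_id", "gene", "effect_allele", "beta")
  missing_cols <- setdiff(required, names(w))
  if (length(missing_cols) > 0) {
    abort(paste0("weight table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(w$snp_id)) abort("weight table: duplicated snp_id")
  if (!all(w$effect_allele %in% c("A", "C", "G", "T"))) {
    abort("weight table: effect_allele must be a single base A/C/G/T")
  }
  if (!all(is.finite(w$beta))) abort("weight table: beta must be finite")
  invisible(w)
}
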