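#' Lipid-lowering medication lexicon
#'
#' Generic names, brand names and class terms for the five lipid-lowering
#' medication classes searched in clinical notes: fibrates, niacin, resins,
#' cholesterol-absorption inhibitors and statins, plus fixed-dose
#' combination products (mapped to class `"combination"`). Every term maps
#' to a generic name and a drug class.
#'
#' @param path Path to a tab-delimited lexicon with columns `term`,
#'   `generic`, `class` and optionally `kind` (`"name"` for drug names,
#'   `"class"` for class search terms). Defaults to the packaged lexicon.
#'
#' @return A tibble with columns `term`, `generic`, `class`, `kind`.
#' @export
#' @examples
#' default_drug_lexicon()
default_drug_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "lipid_lexicon.tsv", package = "phenogrs")
  read_drug_lexicon(path)
}

#' Read a medication lexicon
#'
#' @param path Tab-delimited file with columns `term`, `generic`, `class`
#'   and optionally `kind`.
#' @return A validated lexicon tibble.
#' @export
read_drug_lexicon <- function(path) {
  lex <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!"kind" %in% names(lex)) lex$kind <- "name"
  validate_drug_lexicon(lex)
  lex
}

drug_classes <- c("fibrate", "niacin", "resin",
                  "cholesterol-absorption-inhibitor", "statin", "combination")

validate_drug_lexicon <- function(lex) {
  required <- c("term", "generic", "class")
  missing_cols <- setdiff(required, names(lex))
  if (length(missing_cols) > 0) {
    abort(paste0("lexicon is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(lex) == 0) abort("lexicon is empty")
  folded <- stringr::str_to_lower(strip_trademarks(lex$term))
  if (anyDuplicated(folded)) {
    abort(paste0("lexicon terms not unique after case-folding: ",
                 paste(unique(lex$term[duplicated(folded)]), collapse = ", ")))
  }
  if (!all(lex$class %in% drug_classes)) {
    abort(paste0("lexicon: unknown drug class: ",
                 paste(setdiff(unique(lex$class), drug_classes), collapse = ", ")))
  }
  if (any(!nzchar(lex$term)) || any(!nzchar(lex$generic))) {
    abort("lexicon: empty term or generic")
  }
  invisible(lex)
}

# Trademark glyphs are typographic noise; remove before any matching.
strip_trademarks <- function(x) {
  stringr::str_replace_all(x, "[®™]", "")
}
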