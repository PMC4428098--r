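# Readers and writers for every on-disk format the pipeline touches.
# Conventions: ISO-8601 dates, UTF-8, comma- or tab-delimited as named,
# missing values serialized as empty fields (never sentinel numbers).

na_empty <- ""

#' Read / write demographics
#'
#' CSV with columns `subject_id`, `sex`, `birth_date` (ISO-8601).
#'
#' @param path File path.
#' @return `read_demographics()`: a tibble; `write_demographics()`:
#'   `path`, invisibly.
#' @export
read_demographics <- function(path) {
  readr::read_csv(path, na = na_empty, col_types = readr::cols(
    subject_id = readr::col_character(),
    sex = readr::col_character(),
    birth_date = readr::col_date()
  ))
}

#' @rdname read_demographics
#' @param demographics Demographics tibble.
#' @export
write_demographics <- function(demographics, path) {
  readr::write_csv(demographics, path, na = na_empty)
  invisible(path)
}

#' Read / write longitudinal lab records
#'
#' CSV with columns `subject_id`, `lab_date`, `analyte`, `value`, `units`.
#'
#' @param path File path.
#' @return `read_labs()`: a tibble; `write_labs()`: `path`, invisibly.
#' @export
read_labs <- function(path) {
  readr::read_csv(path, na = na_empty, col_types = readr::cols(
    subject_id = readr::col_character(),
    lab_date = readr::col_date(),
    analyte = readr::col_character(),
    value = readr::col_double(),
    units = readr::col_character()
  ))
}

#' @rdname read_labs
#' @param labs Lab tibble.
#' @export
write_labs <- function(labs, path) {
  readr::write_csv(labs, path, na = na_empty)
  invisible(path)
}

#' Read / write clinical notes as JSON lines
#'
#' One JSON object per line with keys `subject_id`, `note_date`, `text`.
#'
#' @param path File path.
#' @return `read_notes()`: a tibble; `write_notes()`: `path`, invisibly.
#' @export
read_notes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(subject_id = character(), note_date = as.Date(character()),
                  text = character()))
  }
  rows <- purrr::map(lines, jsonlite::fromJSON)
  tibble(
    subject_id = purrr::map_chr(rows, "subject_id"),
    note_date = as.Date(purrr::map_chr(rows, "note_date")),
    text = purrr::map_chr(rows, "text")
  )
}

#' @rdname read_notes
#' @param notes Notes tibble.
#' @export
write_notes <- function(notes, path) {
  lines <- purrr::pmap_chr(
    list(notes$subject_id, as.character(notes$note_date), notes$text),
    function(id, d, txt) {
      jsonlite::toJSON(list(subject_id = id, note_date = d, text = txt),
                       auto_unbox = TRUE)
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write medication mentions
#'
#' CSV with columns `subject_id`, `mention_date`, `matched_term`,
#' `generic`, `class`.
#'
#' @param path File path.
#' @return `read_mentions()`: a tibble; `write_mentions()`: `path`,
#'   invisibly.
#' @export
read_mentions <- function(path) {
  readr::read_csv(path, na = na_empty, col_types = readr::cols(
    subject_id = readr::col_character(),
    mention_date = readr::col_date(),
    matched_term = readr::col_character(),
    generic = readr::col_character(),
    class = readr::col_character()
  ))
}

#' @rdname read_mentions
#' @param mentions Mention tibble.
#' @export
write_mentions <- function(mentions, path) {
  readr::write_csv(mentions, path, na = na_empty)
  invisible(path)
}

#' Read / write the phenotype table
#'
#' TSV with one row per subject and the five definition columns plus
#' per-definition lab counts.
#'
#' @param path File path.
#' @return `read_phenotypes()`: a tibble; `write_phenotypes()`: `path`,
#'   invisibly.
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, na = na_empty, col_types = readr::cols(
    subject_id = readr::col_character(),
    all_hdl = readr::col_double(), first_hdl = readr::col_double(),
    last_hdl = readr::col_double(), premed_hdl = readr::col_double(),
    postmed_hdl = readr::col_double(),
    n_labs_all = readr::col_integer(), n_labs_pre = readr::col_integer(),
    n_labs_post = readr::col_integer()
  ))
}

#' @rdname read_phenotypes
#' @param phenotypes Phenotype tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path, na = na_empty)
  invisible(path)
}

#' Read / write the GRS table
#'
#' TSV with `subject_id`, `grs_unweighted`, `grs_weighted`,
#' `n_nonmissing`, `risk_allele_total`; column-compatible with average-
#' per-SNP score conventions.
#'
#' @param path File path.
#' @return `read_grs()`: a tibble; `write_grs()`: `path`, invisibly.
#' @export
read_grs <- function(path) {
  readr::read_tsv(path, na = na_empty, col_types = readr::cols(
    subject_id = readr::col_character(),
    grs_unweighted = readr::col_double(),
    grs_weighted = readr::col_double(),
    n_nonmissing = readr::col_integer(),
    risk_allele_total = readr::col_integer()
  ))
}

#' @rdname read_grs
#' @param grs GRS tibble.
#' @export
write_grs <- function(grs, path) {
  readr::write_tsv(grs, path, na = na_empty)
  invisible(path)
}

#' Write cohort genotypes as a minimal VCF v4.2
#'
#' Emits one biallelic record per SNP with GT-only genotype columns, using
#' the cohort's REF/ALT orientation (the effect allele may be REF or ALT;
#' orientation is resolved downstream by [orient_effect_alleles()]).
#' Missing calls are written as `./.`.
#'
#' @param cohort An `emr_cohort` object, or a list with elements
#'   `genotypes` (effect-allele counts) and `vcf_sites` (chrom, pos,
#'   snp_id, ref, alt with the effect allele equal to ref or alt).
#' @param path Output `.vcf` path.
#' @param effect_alleles Character vector of effect alleles aligned with
#'   `vcf_sites` rows; defaults to the cohort configuration's SNP table.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(cohort, path, effect_alleles = NULL) {
  sites <- cohort$vcf_sites
  geno <- cohort$genotypes
  effect_alleles <- effect_alleles %||% cohort$config$snp_table$effect_allele
  stopifnot(length(effect_alleles) == nrow(sites))
  samples <- geno$subject_id
  gt_strings <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(sites)), function(j) {
    counts <- geno[[sites$snp_id[j]]]
    alt_dose <- if (effect_alleles[j] == sites$alt[j]) counts else 2L - counts
    gt <- ifelse(is.na(alt_dose), "./.", gt_strings[alt_dose + 1L])
    paste(c(sites$chrom[j], sites$pos[j], sites$snp_id[j], sites$ref[j],
            sites$alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(sites$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a VCF file
#'
#' Thin wrapper around `vcfR::read.vcfR()` used by the pipeline.
#'
#' @param path VCF path.
#' @return A `vcfR` object.
#' @export
read_vcf_genotypes <- function(path) {
  vcfR::read.vcfR(path, verbose = FALSE)
}

#' Write all cohort artifacts to a directory
#'
#' demographics CSV, labs CSV, notes JSONL, genotypes VCF and the truth
#' TSV (subject_id, generative genetic value, medication start date) used
#' by recovery tests.
#'
#' @param cohort An `emr_cohort` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    demographics = file.path(dir, "demographics.csv"),
    labs = file.path(dir, "labs.csv"),
    notes = file.path(dir, "notes.jsonl"),
    genotypes = file.path(dir, "genotypes.vcf"),
    truth = file.path(dir, "truth.tsv")
  )
  write_demographics(cohort$demographics, paths["demographics"])
  write_labs(cohort$labs, paths["labs"])
  write_notes(cohort$notes, paths["notes"])
  write_vcf_genotypes(cohort, paths["genotypes"])
  readr::write_tsv(cohort$truth, paths["truth"], na = na_empty)
  invisible(paths)
}

#' Read / write association results
#'
#' TSV with one row per (definition, score mode).
#'
#' @param path File path.
#' @return `read_associations()`: a tibble; `write_associations()`:
#'   `path`, invisibly.
#' @export
read_associations <- function(path) {
  readr::read_tsv(path, na = na_empty, col_types = readr::cols(
    phenotype_definition = readr::col_character(),
    grs_mode = readr::col_character(),
    n = readr::col_integer(),
    .default = readr::col_double()
  ))
}

#' @rdname read_associations
#' @param associations Tidied association tibble.
#' @export
write_associations <- function(associations, path) {
  readr::write_tsv(associations, path, na = na_empty)
  invisible(path)
}
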