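#' Orient VCF genotypes to effect-allele counts
#'
#' A VCF stores genotypes as REF/ALT dosages; the risk score needs counts
#' of the effect allele defined by the weight table. For each SNP the
#' effect allele must equal either REF or ALT: when it is ALT the cell is
#' the ALT dosage, when it is REF the dosage is flipped (`2 - d`). Missing
#' genotype calls propagate to missing cells.
#'
#' @param vcf A `vcfR` object or path to a VCF file with GT genotypes.
#' @param weights SNP weight tibble (see [hdl_snp_weights()]); every
#'   `snp_id` must appear exactly once and be biallelic in the VCF.
#'
#' @return A tibble with `subject_id` (VCF sample names) and one
#'   effect-allele-count column per SNP, in weight-table order; counts in
#'   `{0, 1, 2}` with `NA` for missing calls.
#' @export
orient_effect_alleles <- function(vcf, weights = hdl_snp_weights()) {
  validate_snp_weights(weights)
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  for (snp in weights$snp_id) {
    hits <- sum(fix$ID == snp)
    if (hits == 0) abort(paste0("SNP absent from VCF: ", snp))
    if (hits > 1) abort(paste0("SNP duplicated in VCF: ", snp))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)

  counts <- lapply(seq_len(nrow(weights)), function(j) {
    snp <- weights$snp_id[j]
    hit <- which(fix$ID == snp)
    ref <- fix$REF[hit]
    alt <- fix$ALT[hit]
    if (grepl(",", alt, fixed = TRUE)) {
      abort(paste0("SNP is multiallelic in VCF: ", snp))
    }
    ea <- weights$effect_allele[j]
    if (!ea %in% c(ref, alt)) {
      abort(paste0("effect allele matches neither REF nor ALT for SNP: ", snp))
    }
    g <- gt[hit, ]
    missing <- is.na(g) | grepl(".", g, fixed = TRUE)
    alt_dose <- stringr::str_count(g, "1")
    alt_dose[missing] <- NA_integer_
    if (ea == ref) 2L - alt_dose else alt_dose
  })
  out <- as_tibble(setNames(counts, weights$snp_id))
  dplyr::bind_cols(tibble(subject_id = samples), out)
}

#' Compute per-subject genetic risk scores
#'
#' For each subject the score is the weighted sum of effect-allele counts
#' over the SNPs with non-missing genotypes, divided by the number of
#' non-missing SNPs — the average per-SNP contribution. The unweighted
#' score sets every weight to 1 (so it lies in `[0, 2]`); the weighted
#' score uses the weight-table betas. No imputation is performed: missing
#' SNPs simply leave both the numerator and the denominator.
#'
#' @param genotypes Tibble from [orient_effect_alleles()] (or the
#'   `genotypes` element of a simulated cohort): `subject_id` plus one
#'   count column per SNP.
#' @param weights SNP weight tibble aligned with the genotype columns.
#' @param mode `"unweighted"` or `"weighted"`.
#'
#' @return A tibble with `subject_id`, `score` (`NA` when every genotype
#'   is missing), `n_nonmissing` (0..number of SNPs) and
#'   `risk_allele_total` (total effect-allele count, `NA` unless the
#'   genotype is complete).
#' @export
#' @examples
#' g <- tibble::tibble(subject_id = "S1", rs1 = 2L, rs2 = 1L)
#' w <- tibble::tibble(snp_id = c("rs1", "rs2"), gene = c("G1", "G2"),
#'                     effect_allele = c("A", "C"), beta = c(-0.1, -0.2))
#' compute_grs(g, w, mode = "unweighted")
compute_grs <- function(genotypes, weights = hdl_snp_weights(),
                        mode = c("unweighted", "weighted")) {
  mode <- match.arg(mode)
  validate_snp_weights(weights)
  missing_cols <- setdiff(weights$snp_id, names(genotypes))
  if (length(missing_cols) > 0) {
    abort(paste0("genotypes are missing SNP column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  counts <- as.matrix(genotypes[, weights$snp_id, drop = FALSE])
  storage.mode(counts) <- "double"
  if (!all(counts %in% c(0, 1, 2) | is.na(counts))) {
    abort("genotype counts must be 0, 1, 2 or missing")
  }
  w <- if (mode == "weighted") weights$beta else rep(1, nrow(weights))
  contrib <- sweep(counts, 2, w, `*`)
  n_nonmissing <- rowSums(!is.na(counts))
  score <- rowSums(contrib, na.rm = TRUE) / n_nonmissing
  score[n_nonmissing == 0] <- NA_real_
  risk_allele_total <- as.integer(rowSums(counts))
  tibble(subject_id = genotypes$subject_id, score,
         n_nonmissing = as.integer(n_nonmissing), risk_allele_total)
}

#' Combined unweighted and weighted GRS table
#'
#' Convenience wrapper producing both score modes side by side in the
#' layout the association stage and the on-disk GRS TSV use.
#'
#' @inheritParams compute_grs
#' @return A tibble with `subject_id`, `grs_unweighted`, `grs_weighted`,
#'   `n_nonmissing`, `risk_allele_total`.
#' @export
grs_table <- function(genotypes, weights = hdl_snp_weights()) {
  u <- compute_grs(genotypes, weights, mode = "unweighted")
  w <- compute_grs(genotypes, weights, mode = "weighted")
  tibble(subject_id = u$subject_id,
         grs_unweighted = u$score,
         grs_weighted = w$score,
         n_nonmissing = u$n_nonmissing,
         risk_allele_total = u$risk_allele_total)
}
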