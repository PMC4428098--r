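#' Pipeline configuration
#'
#' Describes one end-to-end run: either simulate a cohort (the default) or
#' point at existing demographics/labs/notes/VCF files, then scan notes,
#' extract the five phenotype definitions, score genotypes and fit the
#' cross-definition comparison. A single global seed fans out to
#' per-stage child seeds so stages are individually reproducible.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer global seed.
#' @param simulate Generate the cohort (`TRUE`) or read existing inputs.
#' @param n_subjects Cohort size when simulating.
#' @param sim_args Named list of extra [simulation_config()] arguments.
#' @param demographics,labs,notes,vcf Input paths when `simulate = FALSE`.
#' @param lexicon_path Optional lexicon TSV overriding the packaged one.
#' @param weights_path Optional weight-table TSV overriding the packaged
#'   one.
#' @param modes GRS modes to fit.
#' @param min_n Minimum complete-case n per definition before flagging.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            n_subjects = 500, sim_args = list(),
                            demographics = NULL, labs = NULL, notes = NULL,
                            vcf = NULL, lexicon_path = NULL,
                            weights_path = NULL,
                            modes = c("unweighted", "weighted"),
                            min_n = 30) {
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), simulate = isTRUE(simulate),
    n_subjects = n_subjects, sim_args = sim_args,
    demographics = demographics, labs = labs, notes = notes, vcf = vcf,
    lexicon_path = lexicon_path, weights_path = weights_path,
    modes = modes, min_n = min_n
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

require_input <- function(path, stage) {
  if (is.null(path) || !file.exists(path)) {
    abort(paste0("[stage ", stage, "] required input file not found: ",
                 if (is.null(path)) "<unset>" else path))
  }
  path
}

manifest_row <- function(path) {
  n_rows <- length(readLines(path, warn = FALSE))
  tibble(file = basename(path),
         sha256 = digest::digest(path, algo = "sha256", file = TRUE),
         n_lines = n_rows)
}

#' Run the end-to-end phenotyping-sensitivity pipeline
#'
#' Executes simulate (optional) -> scan notes -> extract phenotypes ->
#' score genotypes -> fit associations -> compare definitions, writing
#' every intermediate table under `config$out_dir` together with a
#' manifest (file, sha256, line count) and a structured stage log. The
#' run is deterministic given the configuration seed.
#'
#' @param config A [pipeline_config()] object.
#' @return An object of class `phenogrs_run`: list with `comparison`
#'   (an `hdl_comparison`), `manifest`, `log`, and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stamp <- function(stage, n_in, n_out, t0) {
    log[[length(log) + 1]] <<- tibble(
      stage = stage, seconds = round(as.numeric(Sys.time()) - t0, 3),
      n_in = n_in, n_out = n_out)
  }
  paths <- c()

  lexicon <- if (is.null(config$lexicon_path)) default_drug_lexicon()
             else read_drug_lexicon(require_input(config$lexicon_path, "scan"))
  weights <- if (is.null(config$weights_path)) hdl_snp_weights()
             else read_snp_weights(require_input(config$weights_path, "grs"))

  # stage: simulate -------------------------------------------------------
  if (config$simulate) {
    t0 <- as.numeric(Sys.time())
    sim_args <- config$sim_args
    sim_args$n_subjects <- config$n_subjects
    sim_args$seed <- config$seed + 101L   # child seed for the generator
    sim_args$lexicon <- lexicon
    if (is.null(sim_args$snp_table)) sim_args$snp_table <- weights
    cohort <- simulate_cohort(do.call(simulation_config, sim_args))
    cohort_paths <- write_cohort(cohort, file.path(config$out_dir, "cohort"))
    config$demographics <- cohort_paths[["demographics"]]
    config$labs <- cohort_paths[["labs"]]
    config$notes <- cohort_paths[["notes"]]
    config$vcf <- cohort_paths[["genotypes"]]
    paths <- c(paths, cohort_paths)
    stamp("simulate", config$n_subjects, nrow(cohort$labs), t0)
  }

  # stage: scan notes ------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  notes <- read_notes(require_input(config$notes, "scan"))
  mentions <- scan_notes(notes, lexicon)
  mentions_path <- file.path(config$out_dir, "mentions.csv")
  write_mentions(mentions, mentions_path)
  paths <- c(paths, mentions = mentions_path)
  stamp("scan", nrow(notes), nrow(mentions), t0)

  # stage: extract phenotypes ----------------------------------------------
  t0 <- as.numeric(Sys.time())
  demographics <- read_demographics(require_input(config$demographics, "extract"))
  labs <- read_labs(require_input(config$labs, "extract"))
  phenotypes <- build_phenotype_table(labs, demographics, mentions)
  pheno_path <- file.path(config$out_dir, "phenotypes.tsv")
  write_phenotypes(phenotypes, pheno_path)
  paths <- c(paths, phenotypes = pheno_path)
  stamp("extract", nrow(labs), nrow(phenotypes), t0)

  # stage: genetic risk score ----------------------------------------------
  t0 <- as.numeric(Sys.time())
  vcf <- read_vcf_genotypes(require_input(config$vcf, "grs"))
  genotypes <- orient_effect_alleles(vcf, weights)
  grs <- grs_table(genotypes, weights)
  grs_path <- file.path(config$out_dir, "grs.tsv")
  write_grs(grs, grs_path)
  paths <- c(paths, grs = grs_path)
  stamp("grs", nrow(genotypes), nrow(grs), t0)

  # stage: associations -----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  fits <- fit_all_associations(phenotypes, grs, demographics,
                               modes = config$modes)
  assoc <- purrr::map_dfr(fits, tidy)
  assoc_path <- file.path(config$out_dir, "associations.tsv")
  write_associations(assoc, assoc_path)
  paths <- c(paths, associations = assoc_path)
  stamp("associate", nrow(phenotypes), nrow(assoc), t0)

  # stage: comparison -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  comparison <- compare_definitions(fits, min_n = config$min_n)
  comp_path <- file.path(config$out_dir, "comparison.tsv")
  readr::write_tsv(comparison$associations, comp_path, na = "")
  pair_path <- file.path(config$out_dir, "pairwise_z.tsv")
  readr::write_tsv(comparison$pairwise, pair_path, na = "")
  hist_path <- file.path(config$out_dir, "risk_allele_histogram.tsv")
  readr::write_tsv(suppressMessages(risk_allele_histogram(grs)), hist_path,
                   na = "")
  paths <- c(paths, comparison = comp_path, pairwise = pair_path,
             histogram = hist_path)
  stamp("compare", nrow(assoc), nrow(comparison$pairwise), t0)

  manifest <- purrr::map_dfr(unname(paths), manifest_row)
  manifest_path <- file.path(config$out_dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path, na = "")
  log_tbl <- dplyr::bind_rows(log)
  readr::write_tsv(log_tbl, file.path(config$out_dir, "pipeline_log.tsv"),
                   na = "")

  structure(list(comparison = comparison, manifest = manifest,
                 log = log_tbl, paths = paths),
            class = "phenogrs_run")
}

#' @export
print.phenogrs_run <- function(x, ...) {
  cat("<phenogrs_run> ", nrow(x$manifest), " artifacts\n", sep = "")
  print(x$comparison)
  invisible(x)
}
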