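#' Configuration for the synthetic EMR cohort generator
#'
#' Bundles and validates every parameter of the generative model used by
#' [simulate_cohort()]. Defaults describe a cohort in which HDL-C behaves the
#' way the downstream regression assumes: additive per-allele genetic effects,
#' a sex shift, a step change in lab values from the first lipid-lowering
#' medication date onward, and independent between- and within-subject noise.
#'
#' @param n_subjects Number of subjects (positive integer).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param snp_table SNP weight tibble (see [hdl_snp_weights()]); its rows
#'   define the simulated loci.
#' @param effect_allele_freqs Per-SNP effect-allele frequency in (0, 1);
#'   length must match `snp_table`. Defaults sum to 4.0 so the modal total
#'   risk-allele count is 8 of 14.
#' @param per_allele_effects Per-SNP trait shift per effect allele, mg/dl.
#'   Defaults to seven equal values of -2 mg/dl.
#' @param intercept_beta0 Baseline HDL-C, mg/dl, for a male subject with no
#'   effect alleles. The default places the cohort median of the all-labs
#'   definition near 51 mg/dl once the mean genetic load (about -16 mg/dl at
#'   the default frequencies and effects) and the sex mix are accounted for.
#' @param sex_effect Additive shift for female vs male, mg/dl. HDL-C runs
#'   higher in women; default +8.
#' @param medication_effect_delta Shift applied to labs dated on or after the
#'   medication start date, mg/dl.
#' @param prob_ever_medicated Probability a subject ever starts a
#'   lipid-lowering medication.
#' @param labs_per_subject_dist Count distribution for labs per subject:
#'   `list(name = "poisson", lambda = )`, `list(name = "nbinom", size = ,
#'   mu = )`, or `list(name = "fixed", count = )`.
#' @param obs_noise_sd Within-subject (per-lab) noise SD, mg/dl.
#' @param subject_noise_sd Between-subject random-intercept SD, mg/dl.
#' @param prob_minor_age Probability an individual lab is dated before the
#'   subject's 18th birthday (exercises the adult filter).
#' @param misspelling_rate Probability a medication note spells the drug name
#'   with one character deleted (defeats exact lexicon matching).
#' @param missing_geno_rate Probability an individual genotype call is
#'   missing.
#' @param prob_female Probability a subject is female.
#' @param date_range Length-2 `Date` vector; labs, notes and medication start
#'   dates fall in this window.
#' @param lexicon Medication lexicon whose drug-name terms seed the notes.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_subjects = 50, seed = 1)
#' cohort <- simulate_cohort(cfg)
simulation_config <- function(n_subjects,
                              seed = 1L,
                              snp_table = hdl_snp_weights(),
                              effect_allele_freqs = c(0.65, 0.55, 0.70, 0.45, 0.60, 0.50, 0.55),
                              per_allele_effects = rep(-2, nrow(snp_table)),
                              intercept_beta0 = 63,
                              sex_effect = 8,
                              medication_effect_delta = -3,
                              prob_ever_medicated = 0.42,
                              labs_per_subject_dist = list(name = "poisson", lambda = 3),
                              obs_noise_sd = 10,
                              subject_noise_sd = 8,
                              prob_minor_age = 0.05,
                              misspelling_rate = 0,
                              missing_geno_rate = 0,
                              prob_female = 0.5,
                              date_range = as.Date(c("1995-01-01", "2011-12-31")),
                              lexicon = default_drug_lexicon()) {
  cfg <- list(
    n_subjects = n_subjects, seed = seed, snp_table = snp_table,
    effect_allele_freqs = effect_allele_freqs,
    per_allele_effects = per_allele_effects,
    intercept_beta0 = intercept_beta0, sex_effect = sex_effect,
    medication_effect_delta = medication_effect_delta,
    prob_ever_medicated = prob_ever_medicated,
    labs_per_subject_dist = labs_per_subject_dist,
    obs_noise_sd = obs_noise_sd, subject_noise_sd = subject_noise_sd,
    prob_minor_age = prob_minor_age, misspelling_rate = misspelling_rate,
    missing_geno_rate = missing_geno_rate, prob_female = prob_female,
    date_range = date_range, lexicon = lexicon
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) abort(paste0("invalid simulation config: field '", field, "'"))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_subjects) || length(cfg$n_subjects) != 1 ||
      cfg$n_subjects < 1 || cfg$n_subjects != floor(cfg$n_subjects)) {
    abort("invalid simulation config: field 'n_subjects'")
  }
  check_scalar_number(cfg$seed, "seed")
  validate_snp_weights(cfg$snp_table)
  k <- nrow(cfg$snp_table)
  if (length(cfg$effect_allele_freqs) != k) {
    abort("invalid simulation config: field 'effect_allele_freqs' (length mismatch with snp_table)")
  }
  if (!all(is.finite(cfg$effect_allele_freqs)) ||
      any(cfg$effect_allele_freqs <= 0) || any(cfg$effect_allele_freqs >= 1)) {
    abort("invalid simulation config: field 'effect_allele_freqs'")
  }
  if (length(cfg$per_allele_effects) != k || !all(is.finite(cfg$per_allele_effects))) {
    abort("invalid simulation config: field 'per_allele_effects'")
  }
  check_scalar_number(cfg$intercept_beta0, "intercept_beta0")
  check_scalar_number(cfg$sex_effect, "sex_effect")
  check_scalar_number(cfg$medication_effect_delta, "medication_effect_delta")
  for (p in c("prob_ever_medicated", "prob_minor_age", "misspelling_rate",
              "missing_geno_rate", "prob_female")) {
    check_scalar_number(cfg[[p]], p, lower = 0, upper = 1)
  }
  check_scalar_number(cfg$obs_noise_sd, "obs_noise_sd", lower = 0)
  check_scalar_number(cfg$subject_noise_sd, "subject_noise_sd", lower = 0)
  d <- cfg$labs_per_subject_dist
  if (!is.list(d) || is.null(d$name) ||
      !d$name %in% c("poisson", "nbinom", "fixed")) {
    abort("invalid simulation config: field 'labs_per_subject_dist'")
  }
  if (!inherits(cfg$date_range, "Date") || length(cfg$date_range) != 2 ||
      cfg$date_range[1] > cfg$date_range[2]) {
    abort("invalid simulation config: field 'date_range'")
  }
  validate_drug_lexicon(cfg$lexicon)
  invisible(cfg)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

draw_lab_counts <- function(n, d) {
  switch(d$name,
    poisson = rpois(n, d$lambda),
    nbinom  = stats::rnbinom(n, size = d$size, mu = d$mu),
    fixed   = rep(as.integer(d$count), n)
  )
}

random_day <- function(n, from, to) {
  from + floor(runif(n) * (as.integer(to - from) + 1))
}

# One-character deletion at a random position.
corrupt_term <- function(term) {
  pos <- sample(nchar(term), 1)
  paste0(substr(term, 1, pos - 1), substr(term, pos + 1, nchar(term)))
}

#' Simulate a synthetic EMR cohort
#'
#' Generates demographics, longitudinal HDL-C labs, dated clinical-note
#' snippets and SNP genotypes under a fully seeded generative model:
#' genotypes `g_ik ~ Binomial(2, f_k)` independently per SNP; a subject
#' random intercept `b_i ~ N(0, subject_noise_sd^2)`; with probability
#' `prob_ever_medicated` a medication start date uniform in `date_range`
#' and notes naming a uniformly chosen lexicon drug on and after that
#' date; and lab values
#' `y_ij = beta0 + sex_effect * 1[female] + sum_k effect_k * g_ik +
#'  delta * 1[lab_date >= med_start] + b_i + e_ij`,
#' `e_ij ~ N(0, obs_noise_sd^2)`, with lab dates uniform in `date_range`
#' except that each lab is, with probability `prob_minor_age`, re-dated
#' before the subject's 18th birthday.
#'
#' @param config A [simulation_config()] object.
#'
#' @return An object of class `emr_cohort`: a list of tibbles
#'   `demographics` (subject_id, sex, birth_date), `labs` (subject_id,
#'   lab_date, analyte, value, units), `notes` (subject_id, note_date,
#'   text), `genotypes` (subject_id plus one effect-allele-count column
#'   per SNP, `NA` = missing call), `truth` (subject_id, genetic_value,
#'   med_start_date) and `vcf_sites` (per-SNP REF/ALT orientation used
#'   when writing VCF).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_local_seed(config$seed, {
    n <- as.integer(config$n_subjects)
    k <- nrow(config$snp_table)
    snps <- config$snp_table$snp_id
    from <- config$date_range[1]
    to <- config$date_range[2]

    subject_id <- sprintf("S%06d", seq_len(n))
    sex <- ifelse(runif(n) < config$prob_female, "female", "male")
    # Adults throughout the observation window unless a lab is re-dated minor.
    birth_date <- from - round(runif(n, 18, 80) * 365.25)
    demographics <- tibble(subject_id, sex, birth_date)

    geno_true <- vapply(seq_len(k),
                        function(j) rbinom(n, 2L, config$effect_allele_freqs[j]),
                        integer(n))
    if (n == 1) geno_true <- matrix(geno_true, nrow = 1)
    genetic_value <- drop(geno_true %*% config$per_allele_effects)
    geno_obs <- geno_true
    if (config$missing_geno_rate > 0) {
      geno_obs[runif(n * k) < config$missing_geno_rate] <- NA_integer_
    }
    genotypes <- as_tibble(setNames(as.data.frame(geno_obs), snps))
    genotypes <- dplyr::bind_cols(tibble(subject_id), genotypes)

    b <- rnorm(n, 0, config$subject_noise_sd)
    medicated <- runif(n) < config$prob_ever_medicated
    med_start <- as.Date(rep(NA, n))
    med_start[medicated] <- random_day(sum(medicated), from, to)

    n_labs <- draw_lab_counts(n, config$labs_per_subject_dist)
    idx <- rep(seq_len(n), n_labs)
    total <- length(idx)
    lab_date <- random_day(total, from, to)
    minor <- runif(total) < config$prob_minor_age
    if (any(minor)) {
      bd <- birth_date[idx[minor]]
      bday18 <- bd %m+% lubridate::years(18)
      span <- as.integer(bday18 - bd) - 731L   # window [birth + 2y, 18th bday)
      lab_date[minor] <- bd + 731L + floor(runif(sum(minor)) * span)
    }
    on_med <- !is.na(med_start[idx]) & lab_date >= med_start[idx]
    value <- config$intercept_beta0 +
      config$sex_effect * (sex[idx] == "female") +
      genetic_value[idx] +
      config$medication_effect_delta * on_med +
      b[idx] +
      rnorm(total, 0, config$obs_noise_sd)
    labs <- tibble(subject_id = subject_id[idx], lab_date,
                   analyte = "HDL-C", value, units = "mg/dl") |>
      dplyr::arrange(.data$subject_id, .data$lab_date, .data$value)

    notes <- simulate_notes(subject_id, med_start, to, config)

    vcf_sites <- simulate_vcf_sites(config$snp_table)

    truth <- tibble(subject_id, genetic_value, med_start_date = med_start)

    structure(list(demographics = demographics, labs = labs, notes = notes,
                   genotypes = genotypes, truth = truth,
                   vcf_sites = vcf_sites, config = config),
              class = "emr_cohort")
  })
}

# Notes: one neutral follow-up note per subject; medicated subjects add a
# start-of-therapy note dated exactly at med_start plus 0+ later mentions.
simulate_notes <- function(subject_id, med_start, range_end, config) {
  n <- length(subject_id)
  from <- config$date_range[1]
  neutral <- tibble(
    subject_id = subject_id,
    note_date = random_day(n, from, range_end),
    text = "Routine follow-up visit. No changes to current regimen."
  )
  medicated <- which(!is.na(med_start))
  if (length(medicated) == 0) {
    return(dplyr::arrange(neutral, .data$subject_id, .data$note_date))
  }
  drug_terms <- config$lexicon$term[config$lexicon$kind == "name"]
  drug <- drug_terms[sample.int(length(drug_terms), length(medicated), replace = TRUE)]
  n_extra <- rpois(length(medicated), 1)

  spell <- function(term) {
    if (config$misspelling_rate > 0 && runif(1) < config$misspelling_rate) {
      corrupt_term(term)
    } else term
  }
  first_notes <- tibble(
    subject_id = subject_id[medicated],
    note_date = med_start[medicated],
    text = vapply(drug, function(d) {
      paste0("Started ", spell(d), " today for dyslipidemia.")
    }, character(1), USE.NAMES = FALSE)
  )
  eidx <- rep(seq_along(medicated), n_extra)
  extra_notes <- if (length(eidx) > 0) {
    start <- med_start[medicated][eidx]
    dt <- start + floor(runif(length(eidx)) * (as.integer(range_end - start) + 1))
    tibble(
      subject_id = subject_id[medicated][eidx],
      note_date = dt,
      text = vapply(drug[eidx], function(d) {
        paste0("Continue ", spell(d), "; lipid panel reviewed.")
      }, character(1), USE.NAMES = FALSE)
    )
  } else NULL
  dplyr::bind_rows(neutral, first_notes, extra_notes) |>
    dplyr::arrange(.data$subject_id, .data$note_date, .data$text)
}

# Assign each SNP a REF/ALT pair; the effect allele lands on REF or ALT
# with equal probability so downstream orientation is actually exercised.
simulate_vcf_sites <- function(snp_table) {
  k <- nrow(snp_table)
  bases <- c("A", "C", "G", "T")
  other <- vapply(snp_table$effect_allele, function(ea) {
    sample(setdiff(bases, ea), 1)
  }, character(1), USE.NAMES = FALSE)
  effect_is_ref <- runif(k) < 0.5
  tibble(
    chrom = as.character(seq_len(k)),
    pos = 10000L + seq_len(k),
    snp_id = snp_table$snp_id,
    ref = ifelse(effect_is_ref, snp_table$effect_allele, other),
    alt = ifelse(effect_is_ref, other, snp_table$effect_allele)
  )
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat("<emr_cohort> ", nrow(x$demographics), " subjects, ",
      nrow(x$labs), " labs, ", nrow(x$notes), " notes, ",
      nrow(x$vcf_sites), " SNPs\n", sep = "")
  invisible(x)
}
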