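# Independent oracles and fixture builders shared across test files.

# Naive per-subject, per-SNP loop implementation of the risk-score formula:
# sum of count*weight over non-missing SNPs divided by their number.
naive_grs_loop <- function(counts, w) {
  n <- nrow(counts)
  score <- numeric(n)
  nn <- integer(n)
  tot <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    s <- 0
    m <- 0L
    for (k in seq_len(ncol(counts))) {
      c_ik <- counts[i, k]
      if (!is.na(c_ik)) {
        s <- s + c_ik * w[k]
        m <- m + 1L
      }
    }
    nn[i] <- m
    score[i] <- if (m == 0L) NA_real_ else s / m
    if (!anyNA(counts[i, ])) tot[i] <- as.integer(sum(counts[i, ]))
  }
  list(score = score, n_nonmissing = nn, risk_allele_total = tot)
}

# Closed-form OLS via the normal equations, with t-based standard errors.
ols_normal_equations <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(sigma2 * solve(XtX)))
  list(beta = drop(beta), se = unname(se), df = df)
}

random_genotype_tibble <- function(n, weights, miss_rate = 0.1) {
  k <- nrow(weights)
  m <- matrix(
    sample(c(0L, 1L, 2L, NA),
           n * k, replace = TRUE,
           prob = c((1 - miss_rate) * c(0.3, 0.45, 0.25), miss_rate)),
    nrow = n
  )
  out <- tibble::as_tibble(stats::setNames(as.data.frame(m), weights$snp_id))
  dplyr::bind_cols(tibble::tibble(subject_id = sprintf("R%04d", seq_len(n))), out)
}

# Three-subject fixture with hand-computed phenotype values.
# P1 (male, born 1960-01-01): adult labs 40 (2000-01-10), 50 (2001-02-10),
#   72 (2003-03-10); medication evidence from 2001-01-01.
#   all = median(40,50,72) = 50; first = 40; last = 72;
#   pre = median(40) = 40; post = median(50,72) = 61.
# P2 (female, born 1970-06-15): lab 99 at age 16 (dropped), 44 on the 18th
#   birthday (kept), 64 in 2005; no medication evidence.
#   all = median(44,64) = 54; first = 44; last = 64; pre = 54; post = NA.
# P3 (female, born 1980-01-01): single lab at age 16 -> everything NA.
toy_emr_fixture <- function() {
  demographics <- tibble::tibble(
    subject_id = c("P1", "P2", "P3"),
    sex = c("male", "female", "female"),
    birth_date = as.Date(c("1960-01-01", "1970-06-15", "1980-01-01"))
  )
  labs <- tibble::tibble(
    subject_id = c("P1", "P1", "P1", "P2", "P2", "P2", "P3"),
    lab_date = as.Date(c("2000-01-10", "2001-02-10", "2003-03-10",
                         "1986-12-01", "1988-06-15", "2005-05-05",
                         "1996-05-01")),
    analyte = "HDL-C",
    value = c(40, 50, 72, 99, 44, 64, 55),
    units = "mg/dl"
  )
  mentions <- tibble::tibble(
    subject_id = "P1",
    mention_date = as.Date("2001-01-01"),
    matched_term = "Lipitor",
    generic = "atorvastatin",
    class = "statin"
  )
  expected <- tibble::tibble(
    subject_id = c("P1", "P2", "P3"),
    all_hdl = c(50, 54, NA),
    first_hdl = c(40, 44, NA),
    last_hdl = c(72, 64, NA),
    premed_hdl = c(40, 54, NA),
    postmed_hdl = c(61, NA, NA),
    n_labs_all = c(3L, 2L, 0L),
    n_labs_pre = c(1L, 2L, 0L),
    n_labs_post = c(2L, 0L, 0L)
  )
  list(demographics = demographics, labs = labs, mentions = mentions,
       expected = expected)
}

# Random per-subject lab histories for property tests.
random_lab_cohort <- function(n_subjects, seed, max_labs = 6,
                              prob_medicated = 0.5) {
  withr::with_seed(seed, {
    ids <- sprintf("Q%04d", seq_len(n_subjects))
    demographics <- tibble::tibble(
      subject_id = ids,
      sex = sample(c("male", "female"), n_subjects, replace = TRUE),
      birth_date = as.Date("1990-01-01") - sample(6000:20000, n_subjects,
                                                  replace = TRUE)
    )
    n_labs <- sample(0:max_labs, n_subjects, replace = TRUE)
    idx <- rep(seq_len(n_subjects), n_labs)
    labs <- tibble::tibble(
      subject_id = ids[idx],
      lab_date = as.Date("2000-01-01") + sample(0:4000, length(idx),
                                                replace = TRUE),
      analyte = "HDL-C",
      value = round(runif(length(idx), 20, 110), 1),
      units = "mg/dl"
    )
    medicated <- runif(n_subjects) < prob_medicated
    mentions <- tibble::tibble(
      subject_id = ids[medicated],
      mention_date = as.Date("2000-01-01") + sample(0:4000, sum(medicated),
                                                    replace = TRUE),
      matched_term = "Zocor", generic = "simvastatin", class = "statin"
    )
    list(demographics = demographics, labs = labs, mentions = mentions)
  })
}

# Brute-force per-subject phenotype extraction, independent of the grouped
# dplyr path used by build_phenotype_table().
naive_phenotypes <- function(labs, demographics, mentions) {
  rows <- lapply(seq_len(nrow(demographics)), function(i) {
    id <- demographics$subject_id[i]
    bd <- demographics$birth_date[i]
    sub <- labs[labs$subject_id == id, , drop = FALSE]
    adult18 <- lubridate::add_with_rollback(bd, lubridate::years(18))
    adult <- sub[sub$lab_date >= adult18, , drop = FALSE]
    med_dates <- mentions$mention_date[mentions$subject_id == id]
    med <- if (length(med_dates) == 0) as.Date(NA) else min(med_dates)
    if (nrow(adult) == 0) {
      return(tibble::tibble(subject_id = id, all_hdl = NA_real_,
                            first_hdl = NA_real_, last_hdl = NA_real_,
                            premed_hdl = NA_real_, postmed_hdl = NA_real_,
                            n_labs_all = 0L, n_labs_pre = 0L, n_labs_post = 0L))
    }
    pre <- if (is.na(med)) adult$value else adult$value[adult$lab_date < med]
    post <- if (is.na(med)) numeric(0) else adult$value[adult$lab_date >= med]
    med_or_na <- function(x) if (length(x) == 0) NA_real_ else median(x)
    tibble::tibble(
      subject_id = id,
      all_hdl = median(adult$value),
      first_hdl = min(adult$value[adult$lab_date == min(adult$lab_date)]),
      last_hdl = max(adult$value[adult$lab_date == max(adult$lab_date)]),
      premed_hdl = med_or_na(pre),
      postmed_hdl = med_or_na(post),
      n_labs_all = nrow(adult),
      n_labs_pre = length(pre),
      n_labs_post = length(post)
    )
  })
  dplyr::bind_rows(rows)
}

# Minimal single-lab cohort simulation settings used by the calibration and
# recovery studies: one lab per subject, nobody medicated, no minors.
single_lab_args <- function(n_subjects, seed, per_allele_effects,
                            snp_table, lexicon) {
  simulation_config(
    n_subjects = n_subjects, seed = seed,
    snp_table = snp_table, lexicon = lexicon,
    per_allele_effects = per_allele_effects,
    labs_per_subject_dist = list(name = "fixed", count = 1),
    prob_ever_medicated = 0, prob_minor_age = 0
  )
}

# One lab per subject joined to its unweighted score and sex: the data frame
# the calibration/recovery regressions run on.
single_lab_frame <- function(cohort, weights) {
  grs <- compute_grs(cohort$genotypes, weights, mode = "unweighted")
  cohort$labs |>
    dplyr::left_join(grs, by = "subject_id") |>
    dplyr::left_join(cohort$demographics, by = "subject_id")
}

# Single-subject genotype row in the tibble layout compute_grs expects.
geno_row <- function(counts, weights) {
  g <- tibble::as_tibble(stats::setNames(as.data.frame(t(counts)),
                                         weights$snp_id))
  dplyr::bind_cols(tibble::tibble(subject_id = "S1"), g)
}
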