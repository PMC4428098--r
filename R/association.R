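#' Sex-adjusted association between a phenotype definition and the GRS
#'
#' Ordinary least squares of the phenotype on the genetic risk score with a
#' sex indicator (female = 1) as the only covariate, on complete cases.
#' The coefficient of interest is the one on the GRS; its confidence
#' interval and two-sided p-value use the t distribution with `n - 3`
#' degrees of freedom. The GRS coefficient is invariant to how sex is
#' coded.
#'
#' @param data A tibble holding one row per subject.
#' @param phenotype Name of the phenotype column (mg/dl).
#' @param grs Name of the GRS column.
#' @param sex Name of the sex column (`"male"`/`"female"`).
#' @param definition Label for the phenotype definition (defaults to the
#'   phenotype column name).
#' @param grs_mode Label for the score mode (`"unweighted"`/`"weighted"`).
#' @param conf_level Confidence level for the interval.
#'
#' @return An object of class `hdl_assoc` wrapping the `lm` fit together
#'   with the extracted GRS effect; see [tidy.hdl_assoc()] and
#'   [glance.hdl_assoc()].
#' @export
#' @examples
#' d <- tibble::tibble(y = c(43, 53, 48, 58), g = c(0, 2, 1, 3),
#'                     sex = c("male", "male", "female", "female"))
#' fit_association(d, "y", "g", definition = "all")
fit_association <- function(data, phenotype, grs, sex = "sex",
                            definition = phenotype,
                            grs_mode = "unweighted",
                            conf_level = 0.95) {
  for (col in c(phenotype, grs, sex)) {
    if (!col %in% names(data)) abort(paste0("column not found: ", col))
  }
  d <- tibble(
    y = data[[phenotype]],
    g = data[[grs]],
    female = as.numeric(data[[sex]] == "female")
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 3) abort(paste0("insufficient data: ", n, " complete cases (< 3)"))
  if (length(unique(d$g)) < 2) {
    abort("singular design: GRS has zero variance among complete cases")
  }
  fit <- lm(y ~ g + female, data = d)
  sm <- summary(fit)$coefficients
  beta <- sm["g", "Estimate"]
  se <- sm["g", "Std. Error"]
  df <- fit$df.residual
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  p <- if (se > 0) 2 * pt(abs(beta / se), df, lower.tail = FALSE) else 0
  structure(list(
    definition = definition, grs_mode = grs_mode, n = n,
    beta = beta, se = se, df = df,
    ci95_low = beta - tcrit * se, ci95_high = beta + tcrit * se,
    p_value = p, conf_level = conf_level, fit = fit
  ), class = "hdl_assoc")
}

#' @export
print.hdl_assoc <- function(x, ...) {
  cat(sprintf(
    "<hdl_assoc> %s / %s GRS: beta = %.3f (95%% CI %.3f to %.3f), p = %.3g, n = %d\n",
    x$definition, x$grs_mode, x$beta, x$ci95_low, x$ci95_high, x$p_value, x$n
  ))
  invisible(x)
}

#' Tidy an association fit
#'
#' One row in the layout of the cross-definition report: definition and
#' score-mode labels, complete-case n, the GRS coefficient with SE,
#' confidence interval and p-value.
#'
#' @param x An `hdl_assoc` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy hdl_assoc
#' @export
tidy.hdl_assoc <- function(x, ...) {
  tibble(phenotype_definition = x$definition, grs_mode = x$grs_mode,
         n = x$n, beta = x$beta, se = x$se,
         ci95_low = x$ci95_low, ci95_high = x$ci95_high,
         p_value = x$p_value)
}

#' Model-level summary of an association fit
#'
#' @param x An `hdl_assoc` object.
#' @param ... Unused.
#' @return A one-row tibble with `r.squared`, `sigma`, `df.residual`, `n`.
#' @method glance hdl_assoc
#' @export
glance.hdl_assoc <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(r.squared = sm$r.squared, sigma = sm$sigma,
         df.residual = x$df, n = x$n)
}

#' Fit every phenotype definition against the GRS
#'
#' Joins the phenotype table, GRS table and demographics and fits one
#' sex-adjusted regression per (definition, score mode). Complete-case
#' analysis per definition, so n varies across results.
#'
#' @param phenotypes Phenotype table from [build_phenotype_table()].
#' @param grs GRS table from [grs_table()].
#' @param demographics Demographics tibble (`subject_id`, `sex`).
#' @param modes Score modes to fit.
#'
#' @return A named list of `hdl_assoc` objects.
#' @export
fit_all_associations <- function(phenotypes, grs, demographics,
                                 modes = c("unweighted", "weighted")) {
  data <- phenotypes |>
    dplyr::left_join(grs, by = "subject_id") |>
    dplyr::left_join(dplyr::select(demographics, "subject_id", "sex"),
                     by = "subject_id")
  defs <- phenotype_definitions()
  grid <- tidyr::expand_grid(definition = defs, mode = modes)
  fits <- purrr::map2(grid$definition, grid$mode, function(def, mode) {
    fit_association(data, paste0(def, "_hdl"),
                    grs = paste0("grs_", mode), sex = "sex",
                    definition = def, grs_mode = mode)
  })
  names(fits) <- paste(grid$definition, grid$mode, sep = ".")
  fits
}

#' Cross-definition effect-size comparison
#'
#' Collates association results into a forest-plot-ready table ordered
#' all/first/last/premed/postmed and computes pairwise
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)` between definitions within each
#' score mode. Because the definitions share subjects the pairwise z is a
#' descriptive heterogeneity screen only, not a calibrated test; it is
#' labeled as such in the output. Definitions fit on fewer than `min_n`
#' subjects are flagged, not dropped.
#'
#' @param results A list of `hdl_assoc` objects (e.g. from
#'   [fit_all_associations()]) or an already-tidied tibble.
#' @param min_n Minimum complete-case n below which a result is flagged.
#'
#' @return An object of class `hdl_comparison`: list with `associations`
#'   (tibble with a `low_n` flag), `pairwise` (tibble of approximate z
#'   statistics) and `note`.
#' @export
compare_definitions <- function(results, min_n = 30) {
  tbl <- if (inherits(results, "data.frame")) {
    as_tibble(results)
  } else {
    purrr::map_dfr(results, tidy)
  }
  if (nrow(tbl) < 2) abort("need at least 2 association results to compare")
  order_levels <- phenotype_definitions()
  tbl <- tbl |>
    dplyr::mutate(
      phenotype_definition = factor(.data$phenotype_definition,
                                    levels = order_levels),
      low_n = .data$n < min_n
    ) |>
    dplyr::arrange(.data$grs_mode, .data$phenotype_definition)

  pairwise <- tbl |>
    dplyr::group_by(.data$grs_mode) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2) return(tibble())
      pairs <- utils::combn(seq_len(nrow(g)), 2)
      tibble(
        definition1 = as.character(g$phenotype_definition[pairs[1, ]]),
        definition2 = as.character(g$phenotype_definition[pairs[2, ]]),
        z = (g$beta[pairs[1, ]] - g$beta[pairs[2, ]]) /
          sqrt(g$se[pairs[1, ]]^2 + g$se[pairs[2, ]]^2)
      )
    }) |>
    dplyr::ungroup()

  structure(list(
    associations = dplyr::mutate(
      tbl, phenotype_definition = as.character(.data$phenotype_definition)),
    pairwise = pairwise,
    note = paste("pairwise z is approximate: definitions share subjects,",
                 "so estimates are correlated")
  ), class = "hdl_comparison")
}

#' @export
print.hdl_comparison <- function(x, ...) {
  cat("<hdl_comparison>\n")
  print(x$associations)
  cat("max |pairwise z|:", sprintf("%.3f", max(abs(x$pairwise$z))), "\n")
  cat("note:", x$note, "\n")
  invisible(x)
}

#' Do all confidence intervals in a comparison mutually overlap?
#'
#' @param comparison An `hdl_comparison` object.
#' @param grs_mode Score mode to assess.
#' @return `TRUE` when every pair of definitions' intervals overlaps.
#' @export
all_cis_overlap <- function(comparison, grs_mode = "unweighted") {
  a <- dplyr::filter(comparison$associations, .data$grs_mode == !!grs_mode)
  if (nrow(a) < 2) return(TRUE)
  pairs <- utils::combn(seq_len(nrow(a)), 2)
  all(a$ci95_low[pairs[1, ]] <= a$ci95_high[pairs[2, ]] &
        a$ci95_low[pairs[2, ]] <= a$ci95_high[pairs[1, ]])
}

#' Histogram of total risk-allele counts
#'
#' Counts subjects by total effect-allele count over the score SNPs,
#' excluding subjects with any missing genotype (their total is
#' undefined); the counts sum to the number of complete-genotype subjects.
#'
#' @param grs A tibble with a `risk_allele_total` column ([compute_grs()]
#'   or [grs_table()] output).
#' @return A tibble with `risk_allele_total` and `n_subjects`, one row per
#'   observed total.
#' @export
risk_allele_histogram <- function(grs) {
  excluded <- sum(is.na(grs$risk_allele_total))
  if (excluded > 0) {
    rlang::inform(paste0(excluded,
      " subject(s) with missing genotypes excluded from risk-allele histogram"))
  }
  grs |>
    dplyr::filter(!is.na(.data$risk_allele_total)) |>
    dplyr::count(.data$risk_allele_total, name = "n_subjects") |>
    dplyr::arrange(.data$risk_allele_total)
}
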