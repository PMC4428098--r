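test_that("a perfectly linear phenotype is recovered with zero residual", {
  d <- tibble::tibble(
    g = c(0, 1, 2, 3, 1.5, 2.5),
    sex = rep(c("male", "female"), 3),
    y = 3 + 5 * g
  )
  fit <- suppressWarnings(fit_association(d, "y", "g"))
  expect_equal(fit$beta, 5)
  expect_lt(fit$se, 1e-10)
  expect_identical(fit$n, 6L)
})

test_that("coefficients equal the hand normal-equation solution", {
  d <- tibble::tibble(
    y = c(43, 53, 48, 58),
    g = c(0, 2, 1, 3),
    sex = c("male", "male", "female", "female")
  )
  X <- cbind(1, d$g, as.numeric(d$sex == "female"))
  want <- ols_normal_equations(X, d$y)
  fit <- suppressWarnings(fit_association(d, "y", "g"))
  expect_equal(fit$beta, want$beta[2], tolerance = 1e-10)
  expect_equal(fit$se, want$se[2], tolerance = 1e-10)
  expect_identical(fit$df, want$df)
})

test_that("OLS agrees with the closed form on random designs", {
  withr::with_seed(55, {
    for (rep in 1:25) {
      n <- sample(10:200, 1)
      d <- tibble::tibble(
        g = rnorm(n),
        sex = sample(c("male", "female"), n, replace = TRUE),
        y = rnorm(n, 50 - 3 * g, 5)
      )
      fit <- fit_association(d, "y", "g")
      X <- cbind(1, d$g, as.numeric(d$sex == "female"))
      want <- ols_normal_equations(X, d$y)
      expect_equal(fit$beta, want$beta[2], tolerance = 1e-8)
      expect_equal(fit$se, want$se[2], tolerance = 1e-8)
      tcrit <- qt(0.975, want$df)
      expect_equal(fit$ci95_low, want$beta[2] - tcrit * want$se[2],
                   tolerance = 1e-8)
    }
  })
})

test_that("degenerate designs raise named errors", {
  d <- tibble::tibble(g = rep(1, 10),
                      sex = rep(c("male", "female"), 5),
                      y = rnorm(10))
  expect_error(fit_association(d, "y", "g"), "singular")
  expect_error(fit_association(d[1:2, ], "y", "g"), "insufficient")
  expect_error(fit_association(d, "y", "missing_col"), "missing_col")
})

test_that("missing phenotype or score rows are dropped as complete cases", {
  withr::with_seed(56, {
    d <- tibble::tibble(
      g = c(rnorm(20), NA, 0.5),
      sex = sample(c("male", "female"), 22, replace = TRUE),
      y = c(rnorm(20, 50), 55, NA)
    )
  })
  fit <- fit_association(d, "y", "g")
  expect_identical(fit$n, 20L)
})

test_that("tidy and glance return the documented one-row summaries", {
  d <- tibble::tibble(g = rnorm(30), sex = rep(c("male", "female"), 15),
                      y = rnorm(30, 50 + 2 * g, 3))
  fit <- fit_association(d, "y", "g", definition = "all",
                         grs_mode = "unweighted")
  td <- tidy(fit)
  expect_named(td, c("phenotype_definition", "grs_mode", "n", "beta", "se",
                     "ci95_low", "ci95_high", "p_value"))
  expect_identical(td$phenotype_definition, "all")
  expect_true(td$ci95_low <= td$beta && td$beta <= td$ci95_high)
  gl <- glance(fit)
  expect_named(gl, c("r.squared", "sigma", "df.residual", "n"))
  expect_identical(gl$n, 30L)
})

fake_result <- function(definition, beta, se, n = 100,
                        grs_mode = "unweighted") {
  tibble::tibble(
    phenotype_definition = definition, grs_mode = grs_mode, n = n,
    beta = beta, se = se,
    ci95_low = beta - 1.96 * se, ci95_high = beta + 1.96 * se,
    p_value = 0.5
  )
}

test_that("identical results give zero pairwise z; disjoint CIs exceed 1.96", {
  same <- dplyr::bind_rows(fake_result("all", 5, 0.5),
                           fake_result("first", 5, 0.5))
  cmp <- compare_definitions(same)
  expect_identical(cmp$pairwise$z, 0)
  expect_true(all_cis_overlap(cmp))

  apart <- dplyr::bind_rows(fake_result("all", 5, 0.1),
                            fake_result("first", 10, 0.1))
  cmp2 <- compare_definitions(apart)
  expect_gt(max(abs(cmp2$pairwise$z)), 1.96)
  expect_false(all_cis_overlap(cmp2))
})

test_that("comparison orders definitions canonically and flags low n", {
  res <- dplyr::bind_rows(
    fake_result("postmed", 4, 1, n = 12),
    fake_result("all", 5, 1),
    fake_result("premed", 5, 1),
    fake_result("last", 5, 1),
    fake_result("first", 5, 1)
  )
  cmp <- compare_definitions(res, min_n = 30)
  expect_identical(cmp$associations$phenotype_definition,
                   c("all", "first", "last", "premed", "postmed"))
  expect_identical(cmp$associations$low_n, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(compare_definitions(res[1, ]), "at least 2")
})

test_that("risk-allele histogram counts complete genotypes only", {
  grs <- tibble::tibble(subject_id = c("A", "B", "C"),
                        risk_allele_total = c(8L, 8L, NA))
  expect_message(h <- risk_allele_histogram(grs), "excluded")
  expect_identical(as.data.frame(h),
                   data.frame(risk_allele_total = 8L, n_subjects = 2L))
  empty <- risk_allele_histogram(tibble::tibble(risk_allele_total = integer()))
  expect_identical(nrow(empty), 0L)
})

test_that("forest and histogram plots build without error", {
  res <- dplyr::bind_rows(fake_result("all", 5, 0.5),
                          fake_result("first", 5.5, 0.5))
  cmp <- compare_definitions(res)
  p <- ggplot2::ggplot_build(autoplot(cmp))
  expect_s3_class(p$plot, "ggplot")
  h <- plot_risk_allele_histogram(
    tibble::tibble(risk_allele_total = c(7L, 8L, 8L)))
  expect_s3_class(h, "ggplot")
})

test_that("equal score weights give identical t statistics in both modes", {
  w <- hdl_snp_weights()
  w_equal <- dplyr::mutate(w, beta = -2)
  g <- withr::with_seed(57, random_genotype_tibble(500, w, miss_rate = 0.05))
  tab <- grs_table(g, w_equal)
  withr::with_seed(58, {
    d <- dplyr::mutate(tab,
      sex = sample(c("male", "female"), dplyr::n(), replace = TRUE),
      y = 50 - 14 * grs_unweighted + rnorm(dplyr::n(), 0, 10))
  })
  fu <- fit_association(d, "y", "grs_unweighted")
  fw <- fit_association(d, "y", "grs_weighted")
  # the rescaling factor is the (negative) common weight, so the t statistic
  # is preserved up to sign and the two-sided p exactly
  expect_equal(abs(fu$beta / fu$se), abs(fw$beta / fw$se), tolerance = 1e-6)
  expect_equal(fu$p_value, fw$p_value, tolerance = 1e-6)
  expect_equal(fw$beta, fu$beta / -2, tolerance = 1e-10)
})
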