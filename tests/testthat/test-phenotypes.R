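demo1 <- tibble::tibble(subject_id = "A", sex = "male",
                        birth_date = as.Date("1980-03-05"))

lab1 <- function(dates, values = seq_along(dates) + 40) {
  tibble::tibble(subject_id = "A", lab_date = as.Date(dates),
                 analyte = "HDL-C", value = values, units = "mg/dl")
}

test_that("adult filter keeps the 18th birthday and drops the day before", {
  on_bday <- lab1("1998-03-05")
  day_before <- lab1("1998-03-04")
  expect_identical(nrow(filter_adult_labs(on_bday, demo1)), 1L)
  expect_identical(nrow(filter_adult_labs(day_before, demo1)), 0L)
  empty <- lab1(character(0), numeric(0))
  expect_identical(nrow(filter_adult_labs(empty, demo1)), 0L)
})

test_that("labs before birth or from unknown subjects are data errors", {
  expect_error(filter_adult_labs(lab1("1979-01-01"), demo1), "birth")
  bad <- dplyr::mutate(lab1("2000-01-01"), subject_id = "ZZ")
  expect_error(filter_adult_labs(bad, demo1), "absent")
})

test_that("median definition follows the odd/even/empty conventions", {
  expect_identical(all_hdl(c(40, 50, 72)), 50)
  expect_identical(all_hdl(c(40, 60)), 50)
  expect_identical(all_hdl(numeric(0)), NA_real_)
})

test_that("first/last use lab dates with the deterministic tie rule", {
  two <- tibble::tibble(lab_date = as.Date(c("2001-01-01", "2005-06-01")),
                        value = c(44, 58))
  expect_identical(first_last_hdl(two), list(first = 44, last = 58))
  one <- tibble::tibble(lab_date = as.Date("2003-01-01"), value = 51)
  expect_identical(first_last_hdl(one), list(first = 51, last = 51))
  tie <- tibble::tibble(lab_date = as.Date(c("2003-01-01", "2003-01-01")),
                        value = c(47, 45))
  expect_identical(first_last_hdl(tie), list(first = 45, last = 47))
  expect_identical(first_last_hdl(two[0, ]),
                   list(first = NA_real_, last = NA_real_))
})

test_that("pre/post partition splits at the first medication date", {
  labs <- tibble::tibble(lab_date = as.Date(c("2000-06-01", "2002-06-01")),
                         value = c(50, 44))
  got <- pre_post_hdl(labs, as.Date("2001-01-01"))
  expect_identical(got[c("premed", "postmed")], list(premed = 50, postmed = 44))
  # no evidence: everything is pre-medication
  none <- pre_post_hdl(labs, NA)
  expect_identical(none[c("premed", "postmed")],
                   list(premed = 47, postmed = NA_real_))
  # a lab dated exactly at the start date counts as post
  same_day <- pre_post_hdl(labs, as.Date("2000-06-01"))
  expect_identical(same_day$n_post, 2L)
  expect_identical(same_day$premed, NA_real_)
})

test_that("the three-subject fixture reproduces all five definitions", {
  fx <- toy_emr_fixture()
  got <- build_phenotype_table(fx$labs, fx$demographics, fx$mentions)
  expect_equal(as.data.frame(got), as.data.frame(fx$expected))
})

test_that("mentions for unknown subjects are a data error", {
  fx <- toy_emr_fixture()
  bad <- dplyr::mutate(fx$mentions, subject_id = "P9")
  expect_error(build_phenotype_table(fx$labs, fx$demographics, bad), "absent")
})

test_that("without mentions the premed column equals the all column", {
  fx <- toy_emr_fixture()
  got <- build_phenotype_table(fx$labs, fx$demographics, NULL)
  expect_identical(got$premed_hdl, got$all_hdl)
  expect_true(all(is.na(got$postmed_hdl)))
  expect_identical(got$n_labs_post, c(0L, 0L, 0L))
})

test_that("phenotype table matches a brute-force oracle on random cohorts", {
  co <- random_lab_cohort(500, seed = 101)
  got <- build_phenotype_table(co$labs, co$demographics, co$mentions)
  want <- naive_phenotypes(co$labs, co$demographics, co$mentions)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("phenotype invariants hold on random cohorts", {
  co <- random_lab_cohort(500, seed = 202)
  tab <- build_phenotype_table(co$labs, co$demographics, co$mentions)

  # partition: pre and post stratum sizes sum to the adult lab count
  expect_identical(tab$n_labs_pre + tab$n_labs_post, tab$n_labs_all)

  # a value is NA exactly when its eligible set is empty, and within range
  adult <- filter_adult_labs(co$labs, co$demographics)
  rng <- adult |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(lo = min(value), hi = max(value))
  j <- dplyr::left_join(tab, rng, by = "subject_id")
  for (col in c("all_hdl", "first_hdl", "last_hdl", "premed_hdl",
                "postmed_hdl")) {
    v <- j[[col]]
    ok <- is.na(v) | (v >= j$lo & v <= j$hi)
    expect_true(all(ok), label = col)
  }
  expect_identical(is.na(tab$all_hdl), tab$n_labs_all == 0L)
  expect_identical(is.na(tab$premed_hdl), tab$n_labs_pre == 0L)
  expect_identical(is.na(tab$postmed_hdl), tab$n_labs_post == 0L)

  # single eligible lab: all three undated definitions coincide
  singles <- tab$n_labs_all == 1L
  expect_true(all(tab$all_hdl[singles] == tab$first_hdl[singles]))
  expect_true(all(tab$all_hdl[singles] == tab$last_hdl[singles]))

  # permutation invariance of lab input order
  perm <- withr::with_seed(1, co$labs[sample(nrow(co$labs)), ])
  expect_equal(build_phenotype_table(perm, co$demographics, co$mentions), tab)

  # translation equivariance: +c on every lab adds c to every phenotype
  shifted <- dplyr::mutate(co$labs, value = value + 7.5)
  tab2 <- build_phenotype_table(shifted, co$demographics, co$mentions)
  for (col in c("all_hdl", "first_hdl", "last_hdl", "premed_hdl",
                "postmed_hdl")) {
    expect_equal(tab2[[col]], tab[[col]] + 7.5, label = col)
  }

  # unmedicated subjects: premed equals all exactly
  unmed <- !tab$subject_id %in% co$mentions$subject_id
  expect_identical(tab$premed_hdl[unmed], tab$all_hdl[unmed])
})
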