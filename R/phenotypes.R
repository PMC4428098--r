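#' Keep only labs drawn at age 18 or older
#'
#' A lab is retained when its date falls on or after the subject's 18th
#' birthday, computed by calendar-date comparison (a lab on the 18th
#' birthday itself is retained).
#'
#' @param labs Tibble with columns `subject_id`, `lab_date`, `value` (and
#'   any others, which pass through).
#' @param demographics Tibble with columns `subject_id`, `birth_date`.
#'
#' @return The adult subset of `labs`, same columns.
#' @export
filter_adult_labs <- function(labs, demographics) {
  joined <- dplyr::left_join(
    labs, dplyr::select(demographics, "subject_id", "birth_date"),
    by = "subject_id"
  )
  if (anyNA(joined$birth_date)) {
    abort("labs reference subject_id absent from demographics")
  }
  if (any(joined$lab_date < joined$birth_date)) {
    abort("lab dated before subject birth_date")
  }
  adult <- joined$lab_date >= (joined$birth_date %m+% years(18))
  labs[adult, , drop = FALSE]
}

# Median with the even-count convention made explicit: mean of the two
# middle order statistics. Returns NA_real_ on an empty set.
median_or_na <- function(x) {
  if (length(x) == 0) return(NA_real_)
  median(x)
}

#' Median of all HDL-C labs for one subject
#'
#' @param values Numeric lab values (already adult-filtered, one subject).
#' @return The median (even counts: mean of the middle pair), or `NA`
#'   when no labs are eligible.
#' @export
all_hdl <- function(values) {
  median_or_na(values)
}

#' First and last HDL-C for one subject
#'
#' First = value at the earliest lab date, last = value at the latest.
#' Same-date ties are broken deterministically: the minimum value is
#' "first", the maximum is "last" (EMRs carry no reliable intraday
#' ordering).
#'
#' @param labs Tibble with columns `lab_date`, `value` for one subject,
#'   adult-filtered.
#' @return A list with elements `first` and `last` (each `NA` when empty).
#' @export
first_last_hdl <- function(labs) {
  if (nrow(labs) == 0) return(list(first = NA_real_, last = NA_real_))
  first_set <- labs$value[labs$lab_date == min(labs$lab_date)]
  last_set <- labs$value[labs$lab_date == max(labs$lab_date)]
  list(first = min(first_set), last = max(last_set))
}

#' Pre- and post-medication HDL-C medians for one subject
#'
#' Labs strictly before the first medication date form the pre-medication
#' stratum; labs on or after it form the post-medication stratum (a lab on
#' the start date itself cannot be confirmed medication-naive, so it counts
#' as post). Subjects with no medication evidence contribute all labs to
#' the pre-medication stratum and none to the post.
#'
#' @param labs Tibble with columns `lab_date`, `value` for one subject,
#'   adult-filtered.
#' @param med_start First medication date (`Date`), or `NA`/`NULL` for no
#'   evidence.
#' @return A list with elements `premed`, `postmed` (stratum medians,
#'   `NA` when the stratum is empty) and `n_pre`, `n_post` (stratum sizes).
#' @export
pre_post_hdl <- function(labs, med_start = NULL) {
  if (is.null(med_start) || is.na(med_start)) {
    return(list(premed = median_or_na(labs$value), postmed = NA_real_,
                n_pre = nrow(labs), n_post = 0L))
  }
  pre <- labs$value[labs$lab_date < med_start]
  post <- labs$value[labs$lab_date >= med_start]
  list(premed = median_or_na(pre), postmed = median_or_na(post),
       n_pre = length(pre), n_post = length(post))
}

#' Build the five-definition HDL-C phenotype table
#'
#' Applies the adult-age filter, then extracts all five per-subject HDL-C
#' phenotype values — median of all labs, first, last, pre-medication
#' median and post-medication median — using the first dated medication
#' mention as the pre/post cut. Every subject in `demographics` appears in
#' the output; subjects with no eligible labs carry `NA` in every
#' definition.
#'
#' @param labs Lab tibble (`subject_id`, `lab_date`, `value`, ...).
#' @param demographics Demographics tibble (`subject_id`, `sex`,
#'   `birth_date`).
#' @param mentions Medication-mention tibble from [scan_notes()]; may have
#'   zero rows.
#'
#' @return A tibble with one row per subject: `subject_id`, `all_hdl`,
#'   `first_hdl`, `last_hdl`, `premed_hdl`, `postmed_hdl`, `n_labs_all`,
#'   `n_labs_pre`, `n_labs_post`.
#' @export
build_phenotype_table <- function(labs, demographics, mentions = NULL) {
  if (is.null(mentions) || nrow(mentions) == 0) {
    mentions <- tibble(subject_id = character(),
                       mention_date = as.Date(character()))
  }
  if (!all(mentions$subject_id %in% demographics$subject_id)) {
    abort("mentions reference subject_id absent from demographics")
  }
  adult <- filter_adult_labs(labs, demographics)
  med <- first_medication_date(mentions, subject_id = demographics$subject_id)

  per_subject <- adult |>
    dplyr::left_join(med, by = "subject_id") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      all_hdl = median(.data$value),
      first_hdl = min(.data$value[.data$lab_date == min(.data$lab_date)]),
      last_hdl = max(.data$value[.data$lab_date == max(.data$lab_date)]),
      premed_hdl = if (is.na(.data$med_start_date[1])) {
        median(.data$value)
      } else {
        median_or_na(.data$value[.data$lab_date < .data$med_start_date[1]])
      },
      postmed_hdl = if (is.na(.data$med_start_date[1])) {
        NA_real_
      } else {
        median_or_na(.data$value[.data$lab_date >= .data$med_start_date[1]])
      },
      n_labs_all = dplyr::n(),
      n_labs_pre = if (is.na(.data$med_start_date[1])) dplyr::n()
                   else sum(.data$lab_date < .data$med_start_date[1]),
      n_labs_post = if (is.na(.data$med_start_date[1])) 0L
                    else sum(.data$lab_date >= .data$med_start_date[1]),
      .groups = "drop"
    )

  tibble(subject_id = demographics$subject_id) |>
    dplyr::left_join(per_subject, by = "subject_id") |>
    dplyr::mutate(
      n_labs_all = dplyr::coalesce(.data$n_labs_all, 0L),
      n_labs_pre = dplyr::coalesce(.data$n_labs_pre, 0L),
      n_labs_post = dplyr::coalesce(.data$n_labs_post, 0L)
    )
}

#' The five phenotype definition labels, in report order
#' @return Character vector `c("all", "first", "last", "premed", "postmed")`.
#' @export
phenotype_definitions <- function() {
  c("all", "first", "last", "premed", "postmed")
}
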