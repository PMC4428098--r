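#' Scan clinical notes for lipid-lowering medication mentions
#'
#' Searches free-text notes for every lexicon term (generic names, brand
#' names and medication class terms) and returns one dated mention per
#' (note, matched term) pair. Matching is case-insensitive, exact
#' substring on word boundaries; trademark glyphs are stripped from both
#' the lexicon and the text first. No negation handling is attempted
#' ("denies taking statins" still counts as a mention), and misspelled
#' names do not match — both are deliberate properties of a plain term
#' search.
#'
#' @param notes Tibble of notes with columns `subject_id`, `note_date`
#'   (`Date`) and `text`.
#' @param lexicon Medication lexicon (see [default_drug_lexicon()]).
#'
#' @return A tibble with columns `subject_id`, `mention_date`,
#'   `matched_term`, `generic`, `class`; zero rows when nothing matches.
#' @export
#' @examples
#' notes <- tibble::tibble(
#'   subject_id = "S1", note_date = as.Date("2004-05-01"),
#'   text = "started Lipitor 10mg qd"
#' )
#' scan_notes(notes)
scan_notes <- function(notes, lexicon = default_drug_lexicon()) {
  validate_drug_lexicon(lexicon)
  required <- c("subject_id", "note_date", "text")
  missing_cols <- setdiff(required, names(notes))
  if (length(missing_cols) > 0) {
    abort(paste0("notes are missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  empty <- tibble(subject_id = character(), mention_date = as.Date(character()),
                  matched_term = character(), generic = character(),
                  class = character())
  if (nrow(notes) == 0) return(empty)

  text <- strip_trademarks(notes$text)
  hits <- purrr::pmap_dfr(
    list(lexicon$term, lexicon$generic, lexicon$class),
    function(term, generic, class) {
      pattern <- stringr::regex(
        paste0("\\b", escape_regex(strip_trademarks(term)), "\\b"),
        ignore_case = TRUE
      )
      sel <- stringr::str_detect(text, pattern)
      if (!any(sel)) return(NULL)
      tibble(subject_id = notes$subject_id[sel],
             mention_date = notes$note_date[sel],
             matched_term = term, generic = generic, class = class)
    }
  )
  if (nrow(hits) == 0) return(empty)
  dplyr::arrange(hits, .data$subject_id, .data$mention_date, .data$matched_term)
}

escape_regex <- function(x) {
  stringr::str_replace_all(x, "([.^$|()\\[\\]{}*+?\\\\])", "\\\\\\1")
}

#' First dated medication evidence per subject
#'
#' The earliest mention date for each requested subject, or `NA` when the
#' subject has no mentions (such subjects are treated as never-medicated:
#' all their labs count as pre-medication downstream).
#'
#' @param mentions Mention tibble from [scan_notes()].
#' @param subject_id Character vector of subjects to look up; defaults to
#'   the subjects present in `mentions`.
#'
#' @return A tibble with columns `subject_id` and `med_start_date`
#'   (`Date`, `NA` when no evidence).
#' @export
first_medication_date <- function(mentions, subject_id = NULL) {
  subject_id <- subject_id %||% unique(mentions$subject_id)
  firsts <- if (nrow(mentions) == 0) {
    tibble(subject_id = character(), med_start_date = as.Date(character()))
  } else {
    mentions |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(med_start_date = min(.data$mention_date),
                       .groups = "drop")
  }
  tibble(subject_id = subject_id) |>
    dplyr::left_join(firsts, by = "subject_id")
}
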