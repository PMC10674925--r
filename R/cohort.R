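#' Index date of one patient's dispensing history
#'
#' The index date is the day of the first fill of the target drug inside the
#' enrolment window; it anchors the 12-month observation period.
#'
#' @param events One patient's dispensing events (`day`, `atc`).
#' @param enrol_window Length-2 integer vector `(start, end)`, half-open, in
#'   study day offsets.
#' @param atc Target drug ATC code (sacubitril/valsartan by default).
#' @return The index day, or `NA_integer_` when no qualifying fill exists.
#' @export
find_index_date <- function(events, enrol_window, atc = "C09DX04") {
  d <- events$day[events$atc == atc &
                    events$day >= enrol_window[1] &
                    events$day < enrol_window[2]]
  if (!length(d)) return(NA_integer_)
  as.integer(min(d))
}

#' Apply cohort exclusion rules
#'
#' Excludes, in this fixed precedence order, patients who (1) left the region
#' after their index date, (2) have less than one full year of follow-up
#' before the end of the study period, or (3) died inside the observation
#' window. Each excluded patient gets exactly one reason (the first matching
#' rule).
#'
#' @param patients Patient table with `patient_id` and optional
#'   `region_exit_date`, `death_date` columns (study day offsets, `NA` when
#'   absent).
#' @param index_dates Tibble `patient_id`, `index_date`.
#' @param study_end Last study day (exclusive); follow-up requires
#'   `index_date + observation_days <= study_end`.
#' @param observation_days Length of the observation window (default 365).
#' @return A list: `included` (tibble `patient_id`, `index_date`) and
#'   `exclusions` (tibble `patient_id`, `reason`).
#' @export
apply_exclusions <- function(patients, index_dates, study_end,
                             observation_days = 365) {
  df <- dplyr::inner_join(index_dates, patients, by = "patient_id")
  exit <- if ("region_exit_date" %in% names(df)) df$region_exit_date else
    rep(NA_real_, nrow(df))
  death <- if ("death_date" %in% names(df)) df$death_date else
    rep(NA_real_, nrow(df))
  moved <- !is.na(exit) & exit > df$index_date
  short <- df$index_date + observation_days > study_end
  died <- !is.na(death) & death >= df$index_date &
    death < df$index_date + observation_days
  reason <- dplyr::case_when(moved ~ "moved",
                             short ~ "short_followup",
                             died ~ "death",
                             .default = NA_character_)
  list(
    included = tibble::as_tibble(df[is.na(reason), c("patient_id", "index_date")]),
    exclusions = tibble::tibble(patient_id = df$patient_id[!is.na(reason)],
                                reason = reason[!is.na(reason)])
  )
}

#' Build the incident-user cohort
#'
#' Finds each patient's index date (first target-drug fill in the enrolment
#' window, with no earlier fill anywhere in the supplied history, i.e.
#' incident use), applies the exclusion rules, and re-expresses every included
#' patient's events relative to their index date.
#'
#' @param events Dispensing events (`patient_id`, `day`, `atc`,
#'   `days_supply`) in study day offsets.
#' @param patients Patient table (see [apply_exclusions()]).
#' @param enrol_window Half-open enrolment window in study day offsets.
#' @param study_end End of the study period (exclusive).
#' @param observation_days Observation window length.
#' @param atc Target drug code.
#' @return A list: `cohort` (patient_id, index_date), `events` (included
#'   patients' events with `day` re-based to the index date), `exclusions`.
#' @export
build_cohort <- function(events, patients, enrol_window,
                         study_end = enrol_window[2] + 365,
                         observation_days = 365, atc = "C09DX04") {
  idx <- events |>
    dplyr::filter(.data$atc == !!atc) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_ever = min(.data$day),
                     index_date = {
                       d <- .data$day[.data$day >= enrol_window[1] &
                                        .data$day < enrol_window[2]]
                       if (length(d)) min(d) else NA_integer_
                     },
                     .groups = "drop") |>
    dplyr::filter(!is.na(.data$index_date),
                  .data$first_ever >= enrol_window[1]) |>
    dplyr::select("patient_id", "index_date") |>
    dplyr::arrange(.data$patient_id)
  res <- apply_exclusions(patients, idx, study_end, observation_days)
  ev <- events |>
    dplyr::inner_join(res$included, by = "patient_id") |>
    dplyr::mutate(day = .data$day - .data$index_date) |>
    dplyr::filter(.data$day >= 0, .data$day < observation_days) |>
    dplyr::select(-"index_date") |>
    dplyr::arrange(.data$patient_id, .data$day)
  list(cohort = res$included, events = ev, exclusions = res$exclusions)
}

#' Read a cohort from the CSV interchange files
#'
#' Reads `dispensing.csv` and `patients.csv` (and `groups.csv` when present)
#' as written by [write_cohort_csv()] or supplied by the user with the same
#' headers.
#'
#' @param dir Directory containing the files.
#' @return A list of tibbles `events`, `patients`, and optionally `truth`.
#' @export
read_cohort_csv <- function(dir) {
  ev_path <- file.path(dir, "dispensing.csv")
  pat_path <- file.path(dir, "patients.csv")
  for (p in c(ev_path, pat_path)) {
    if (!file.exists(p)) stop("missing input file: ", p)
  }
  out <- list(events = readr::read_csv(ev_path, show_col_types = FALSE),
              patients = readr::read_csv(pat_path, show_col_types = FALSE))
  gp <- file.path(dir, "groups.csv")
  if (file.exists(gp)) out$truth <- readr::read_csv(gp, show_col_types = FALSE)
  out
}
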