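#' Charlson condition weights
#'
#' The standard weight table (1/2/3/6) used by [compute_acci()].
#'
#' @return A named integer vector, condition name to weight.
#' @export
acci_weights <- function() {
  c(mi = 1L, chf = 1L, pvd = 1L, cvd = 1L, dementia = 1L, copd = 1L,
    rheumatic = 1L, pud = 1L, mild_liver = 1L, diabetes = 1L,
    diabetes_complications = 2L, hemiplegia = 2L, renal_disease = 2L,
    malignancy = 2L, moderate_severe_liver = 3L, metastatic = 6L, aids = 6L)
}

#' Age-adjusted Charlson comorbidity index
#'
#' Sum of the Charlson weights of the patient's conditions plus age points:
#' +1 per decade from 50-59 (so +1 for 50-59, +2 for 60-69, +3 for 70-79, +4
#' for 80 and over).
#'
#' @param conditions Character vector of condition names (see
#'   [acci_weights()]) or a named logical vector of flags. Unknown condition
#'   names are an error.
#' @param age Age in years at the index date.
#' @return Integer ACCI score.
#' @export
#' @examples
#' compute_acci(c("diabetes", "renal_disease"), age = 72)  # 3 + 3 = 6
compute_acci <- function(conditions, age) {
  stopifnot(length(age) == 1, age >= 0)
  if (is.logical(conditions)) conditions <- names(conditions)[conditions]
  w <- acci_weights()
  unknown <- setdiff(conditions, names(w))
  if (length(unknown)) {
    stop("unknown comorbidity condition(s): ", paste(unknown, collapse = ", "))
  }
  age_points <- if (age >= 80) 4L else if (age >= 70) 3L else
    if (age >= 60) 2L else if (age >= 50) 1L else 0L
  as.integer(sum(w[conditions]) + age_points)
}

#' Classify an ACCI score
#'
#' Low for scores 0-1, mild for 2-3, severe for 4 and over.
#'
#' @param score Integer ACCI score(s).
#' @return Character vector of classes.
#' @export
classify_acci <- function(score) {
  stopifnot(all(score >= 0))
  dplyr::case_when(score <= 1 ~ "low", score <= 3 ~ "mild",
                   .default = "severe")
}

#' Classify polypharmacy level
#'
#' No polypharmacy for up to 4 concurrent drugs, polypharmacy for 5-9, and
#' excessive polypharmacy for 10 or more.
#'
#' @param n_distinct_drugs Nonnegative integer count(s) of distinct drugs.
#' @return Character vector: `"none"`, `"polypharmacy"` or `"excessive"`.
#' @export
classify_polypharmacy <- function(n_distinct_drugs) {
  if (any(n_distinct_drugs < 0)) stop("drug counts must be nonnegative")
  dplyr::case_when(n_distinct_drugs <= 4 ~ "none",
                   n_distinct_drugs <= 9 ~ "polypharmacy",
                   .default = "excessive")
}

#' Days on treatment (persistence)
#'
#' Days from the index date to the supply exhaustion of the last fill before
#' the first refill gap exceeding the grace period, with supply exhaustion
#' chained through carryover and capped at the period length. Returns the
#' persistence and the discontinuation day (`NA` when the patient persists to
#' the period end).
#'
#' @param events One patient's target-drug events (`day`, `days_supply`),
#'   days relative to the index date.
#' @param period_days Observation period length.
#' @param grace_days Allowed gap beyond supply exhaustion before the patient
#'   counts as discontinued (default 30).
#' @return A list with `days_on_treatment` (integer) and `discontinuation_day`
#'   (integer or `NA`).
#' @export
days_on_treatment <- function(events, period_days = 365, grace_days = 30) {
  day <- events$day[events$day >= 0 & events$day < period_days]
  supply <- events$days_supply[events$day >= 0 & events$day < period_days]
  if (!length(day)) {
    return(list(days_on_treatment = 0L, discontinuation_day = 0L))
  }
  o <- order(day)
  day <- day[o]; supply <- supply[o]
  exhaust <- day[1] + supply[1]
  for (i in seq_along(day)[-1]) {
    if (day[i] > exhaust + grace_days) break
    exhaust <- max(exhaust, day[i]) + supply[i]
  }
  dot <- min(exhaust, period_days)
  disc <- if (exhaust >= period_days) NA_integer_ else as.integer(exhaust)
  list(days_on_treatment = as.integer(dot), discontinuation_day = disc)
}

#' Detect switching to another heart-failure drug class
#'
#' A switch is the first fill of an alternative heart-failure treatment
#' (diuretics C03, beta blockers C07, renin-angiotensin agents C09) at or
#' after the discontinuation day. The switch is binned by time from the index
#' date: within 1 month (day <= 30), within 2 months (<= 60), within 6 months
#' (<= 180), or later.
#'
#' @param all_events One patient's events including non-target drugs (`day`,
#'   `atc`), days relative to the index date.
#' @param discontinuation_day Day the patient discontinued the target drug
#'   (`NA` means still on treatment, hence no switch).
#' @param alt_classes ATC-II prefixes counting as alternatives.
#' @return A one-row tibble: `switched`, `switch_day`, `bin`,
#'   `target_atc_class`.
#' @export
detect_switch <- function(all_events, discontinuation_day,
                          alt_classes = c("C03", "C07", "C09")) {
  no_switch <- tibble::tibble(switched = FALSE, switch_day = NA_integer_,
                              bin = NA_character_,
                              target_atc_class = NA_character_)
  if (is.na(discontinuation_day)) return(no_switch)
  is_alt <- substr(all_events$atc, 1, 3) %in% alt_classes &
    all_events$atc != "C09DX04"
  cand <- all_events[is_alt & all_events$day >= discontinuation_day, ]
  if (!nrow(cand)) return(no_switch)
  first <- cand[which.min(cand$day), ]
  d <- first$day
  bin <- if (d <= 30) "within_1_month" else if (d <= 60) "within_2_months"
    else if (d <= 180) "within_6_months" else "later"
  tibble::tibble(switched = TRUE, switch_day = as.integer(d), bin = bin,
                 target_atc_class = substr(first$atc, 1, 3))
}

#' Per-patient covariate and treatment-pattern profiles
#'
#' Derives, for every cohort patient, the ACCI score and class, polypharmacy
#' class, persistence, discontinuation and switching record.
#'
#' @param patients Patient table with `patient_id`, `age_at_index`, `sex`,
#'   `n_distinct_drugs`, `n_hosp_hf`, `n_hosp_other` and logical comorbidity
#'   flag columns.
#' @param events Index-based dispensing events for the same patients
#'   (`patient_id`, `day`, `atc`, `days_supply`).
#' @param period_days,grace_days See [days_on_treatment()].
#' @param atc Target drug code.
#' @return A tibble, one row per patient, of class `patient_profiles`.
#' @export
patient_profiles <- function(patients, events, period_days = 365,
                             grace_days = 30, atc = "C09DX04") {
  flag_cols <- intersect(names(patients), names(acci_weights()))
  prof <- patients |>
    dplyr::rowwise() |>
    dplyr::mutate(
      acci_score = compute_acci(
        unlist(dplyr::pick(dplyr::all_of(flag_cols))), .data$age_at_index)) |>
    dplyr::ungroup() |>
    dplyr::mutate(acci_class = classify_acci(.data$acci_score),
                  polypharmacy_class =
                    classify_polypharmacy(.data$n_distinct_drugs))
  ids <- patients$patient_id
  target <- events[events$atc == atc, ]
  ev_split <- split(target[c("day", "days_supply")],
                    factor(target$patient_id, levels = ids))
  all_split <- split(events[c("day", "atc")],
                     factor(events$patient_id, levels = ids))
  pers <- purrr::map(ev_split, days_on_treatment, period_days = period_days,
                     grace_days = grace_days)
  sw <- purrr::map2(all_split, pers,
                    ~detect_switch(.x, .y$discontinuation_day))
  out <- prof |>
    dplyr::mutate(
      days_on_treatment = purrr::map_int(pers, "days_on_treatment"),
      discontinuation_day = purrr::map_int(pers, "discontinuation_day"),
      discontinued = !is.na(.data$discontinuation_day)) |>
    dplyr::bind_cols(dplyr::bind_rows(sw))
  class(out) <- c("patient_profiles", class(out))
  out
}

#' Summarize trajectory groups
#'
#' Per labeled trajectory group: size and share of the cohort, mean (SD)
#' overall CMA9, median (IQR) days on treatment, switcher count and share,
#' and the switch-time bins as percentages of switchers.
#'
#' @param profiles A [patient_profiles()] tibble.
#' @param trajectories A [cma_trajectories()] tibble.
#' @param assignments Tibble `patient_id`, `label` (e.g. from
#'   [select_k()]'s assignments).
#' @return A tibble with one row per group.
#' @export
summarize_groups <- function(profiles, trajectories, assignments) {
  ids <- sort(assignments$patient_id)
  if (!identical(sort(profiles$patient_id), ids) ||
      !identical(sort(trajectories$patient_id), ids)) {
    stop("profiles, trajectories and assignments must cover the same patients")
  }
  df <- assignments |>
    dplyr::inner_join(trajectories[c("patient_id", "overall")],
                      by = "patient_id") |>
    dplyr::inner_join(profiles, by = "patient_id")
  n_total <- nrow(df)
  df |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct = 100 * dplyr::n() / n_total,
      cma_mean = mean(.data$overall),
      cma_sd = stats::sd(.data$overall),
      dot_median = stats::median(.data$days_on_treatment),
      dot_iqr = stats::IQR(.data$days_on_treatment),
      n_switchers = sum(.data$switched),
      pct_switchers = 100 * mean(.data$switched),
      pct_switch_1m = 100 * sum(.data$bin %in% "within_1_month") /
        max(1, sum(.data$switched)),
      pct_switch_2m = 100 * sum(.data$bin %in% "within_2_months") /
        max(1, sum(.data$switched)),
      pct_switch_6m = 100 * sum(.data$bin %in% "within_6_months") /
        max(1, sum(.data$switched)),
      pct_acci_severe = 100 * mean(.data$acci_class == "severe"),
      pct_polypharmacy = 100 * mean(.data$polypharmacy_class != "none"),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$cma_mean))
}
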