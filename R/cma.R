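#' Per-day medication availability ratios for one refill history
#'
#' Expands a single patient's refill history into one availability value per
#' day of the observation period. Each inter-refill interval (the last one
#' runs from the final fill to the end of the period) is assigned the ratio
#' `min(1, available supply / interval length)`; supply in excess of the
#' interval length is carried into the next interval, and supply that would
#' overflow the end of the period is discarded (end-period exclusion). Days
#' before the first in-period fill get 0.
#'
#' @param events Data frame with columns `day` (integer offset from the start
#'   of the observation period) and `days_supply`. Fills falling outside
#'   `[0, period_days)` are ignored; same-day fills are merged by summing
#'   their supplies.
#' @param period_days Length of the observation period in days (default 365).
#' @return Numeric vector of length `period_days`, each value in `[0, 1]`.
#' @seealso [compute_cma9()], [compute_cma9_windows()]
#' @export
#' @examples
#' daily_ratio_vector(data.frame(day = 0, days_supply = 30), period_days = 90)[1]
daily_ratio_vector <- function(events, period_days = 365) {
  stopifnot(period_days >= 1)
  iv <- supply_intervals(events$day, events$days_supply, period_days)
  if (is.null(iv)) return(rep(0, period_days))
  c(rep(0, iv$start[1]), rep(iv$ratio, iv$end - iv$start))
}

# Interval decomposition with left-to-right carryover chaining.
# Returns NULL when no in-period fill exists, else a list of parallel vectors
# start/end (half-open day offsets), available (fill + carryover in), ratio,
# carryover_out.
supply_intervals <- function(day, days_supply, period_days) {
  keep <- day >= 0 & day < period_days
  day <- day[keep]
  days_supply <- days_supply[keep]
  if (!length(day)) return(NULL)
  s <- vapply(split(as.numeric(days_supply), day), sum, 0)
  t0 <- sort(unique(day))
  ends <- c(t0[-1], period_days)
  len <- ends - t0
  m <- length(t0)
  avail <- ratio <- carry <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    avail[i] <- s[i] + run
    ratio[i] <- min(1, avail[i] / len[i])
    run <- max(0, avail[i] - len[i])
    carry[i] <- run
  }
  list(start = t0, end = ends, available = avail, ratio = ratio,
       carryover_out = carry)
}

#' Overall CMA9 for one refill history
#'
#' The continuous-medication-availability estimate: the mean of the per-day
#' availability ratios over the whole observation period, i.e. the ratio of
#' theoretical medication-use days to the period length, accounting for supply
#' carryover between refills and excluding supply that runs past the end of
#' the period.
#'
#' @inheritParams daily_ratio_vector
#' @return A single number in `[0, 1]`; 0 when the history has no in-period
#'   fill.
#' @export
#' @examples
#' compute_cma9(data.frame(day = c(0, 60), days_supply = 30), period_days = 90)
compute_cma9 <- function(events, period_days = 365) {
  stopifnot(period_days >= 1)
  iv <- supply_intervals(events$day, events$days_supply, period_days)
  if (is.null(iv)) return(0)
  sum(iv$ratio * (iv$end - iv$start)) / period_days
}

#' Windowed CMA9 trajectory for one refill history
#'
#' Splits the observation period into contiguous non-overlapping windows
#' (12 windows of 30 days by default, matching the typical delivery period)
#' and averages the per-day availability ratio within each. Residual days
#' beyond the last full window (days 360-364 of a 365-day period) contribute
#' only to the overall estimate.
#'
#' @inheritParams daily_ratio_vector
#' @param window_days Window length in days; must divide
#'   `floor(period_days / window_days) * window_days` windows into the period
#'   (default 30, giving 12 windows over 365 days).
#' @return A tibble with one row: `w1 ... w<n>` window means and `overall`.
#' @export
compute_cma9_windows <- function(events, period_days = 365, window_days = 30) {
  stopifnot(window_days >= 1, period_days >= window_days)
  n_win <- floor(period_days / window_days)
  daily <- daily_ratio_vector(events, period_days)
  w <- colMeans(matrix(daily[seq_len(n_win * window_days)], nrow = window_days))
  out <- tibble::as_tibble(as.list(stats::setNames(w, paste0("w", seq_len(n_win)))))
  out$overall <- mean(daily)
  out
}

#' CMA9 trajectories for a whole cohort
#'
#' Computes the windowed adherence trajectory of every patient in a cohort of
#' dispensing events, restricted to one target drug. Patients present in
#' `cohort` but with no qualifying event still get a row (all-zero
#' trajectory), so the output always has one row per cohort patient.
#'
#' @param events Dispensing events: `patient_id`, `day` (offset from each
#'   patient's index date), `days_supply`, and optionally `atc` used with
#'   `atc_filter`.
#' @param cohort Optional data frame with a `patient_id` column fixing the
#'   patient set and output order; defaults to the patients present in
#'   `events`.
#' @param atc_filter ATC code(s) to keep, e.g. `"C09DX04"`; `NULL` keeps all
#'   events.
#' @inheritParams compute_cma9_windows
#' @return A tibble: `patient_id`, `w1 ... w12`, `overall`, of class
#'   `cma_trajectories`.
#' @export
cma_trajectories <- function(events, cohort = NULL, atc_filter = "C09DX04",
                             period_days = 365, window_days = 30) {
  if (!is.null(atc_filter) && "atc" %in% names(events)) {
    events <- dplyr::filter(events, .data$atc %in% atc_filter)
  }
  ids <- if (is.null(cohort)) sort(unique(events$patient_id)) else cohort$patient_id
  n_win <- floor(period_days / window_days)
  ev <- split(events[c("day", "days_supply")],
              factor(events$patient_id, levels = ids))
  rows <- purrr::map(ev, function(e) {
    daily <- daily_ratio_vector(e, period_days)
    c(colMeans(matrix(daily[seq_len(n_win * window_days)], nrow = window_days)),
      mean(daily))
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- c(paste0("w", seq_len(n_win)), "overall")
  out <- dplyr::bind_cols(tibble::tibble(patient_id = ids),
                          tibble::as_tibble(mat))
  class(out) <- c("cma_trajectories", class(out))
  out
}

#' Fix or resample refill durations
#'
#' Either sets every fill's supply to 30 days (the primary analysis choice) or,
#' for sensitivity analyses, keeps the first fill of each patient at 30 days
#' and draws every subsequent fill's supply uniformly from {30, 60, 90}.
#'
#' @param events Dispensing events with `patient_id`, `day`, `days_supply`.
#' @param mode `"fixed30"` or `"sampled"`.
#' @param seed Integer seed used when `mode = "sampled"`.
#' @return The events tibble with `days_supply` rewritten.
#' @export
assign_refill_durations <- function(events, mode = c("fixed30", "sampled"),
                                    seed = NULL) {
  mode <- match.arg(mode)
  events <- tibble::as_tibble(events)
  if (mode == "fixed30") {
    events$days_supply <- 30L
    return(events)
  }
  if (!is.null(seed)) set.seed(seed)
  ord <- order(events$patient_id, events$day)
  first <- !duplicated(events$patient_id[ord])
  supply <- sample(c(30L, 60L, 90L), nrow(events), replace = TRUE)
  supply[first] <- 30L
  events$days_supply[ord] <- supply
  events
}
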