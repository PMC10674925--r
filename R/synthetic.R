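#' Adherence archetype specification
#'
#' An archetype describes one generating process for a 12-month refill
#' history. Steady archetypes refill with lognormally distributed inter-fill
#' gaps around `gap_mean` until the period ends (or until `stop_month`, after
#' which no refills occur). The drop-off archetype keeps `gap_mean` gaps
#' through `drop_month`, then refills at most once per month with probability
#' `p_refill_late`, emulating patients with high early adherence who largely
#' stop after some time.
#'
#' @param label One of `"high"`, `"partial_drop_off"`, `"moderate"`, `"low"`.
#' @param gap_mean Mean inter-refill gap in days.
#' @param gap_cv Coefficient of variation of the gap distribution.
#' @param stop_month Month index (1-based) after which no refills occur, or
#'   `NA` for none. The low archetype must stop by month 3; the high archetype
#'   must not stop.
#' @param drop_month For the drop-off shape: last month of regular refilling.
#' @param p_refill_late Per-month refill probability after `drop_month`.
#' @param target_mean_cma Expected overall CMA9 in `[0, 1]`, used by
#'   calibration checks.
#' @return A list of class `archetype_spec`.
#' @export
archetype_spec <- function(label, gap_mean, gap_cv = 0.15, stop_month = NA,
                           drop_month = NA, p_refill_late = NA,
                           target_mean_cma) {
  label <- match.arg(label, c("high", "partial_drop_off", "moderate", "low"))
  stopifnot(target_mean_cma >= 0, target_mean_cma <= 1, gap_mean >= 1)
  if (label == "high" && !is.na(stop_month)) {
    stop("the high-adherence archetype must not have a stop_month")
  }
  if (label == "low" && (is.na(stop_month) || stop_month > 3)) {
    stop("the low-adherence archetype must stop by month 3")
  }
  structure(list(label = label, gap_mean = gap_mean, gap_cv = gap_cv,
                 stop_month = stop_month, drop_month = drop_month,
                 p_refill_late = p_refill_late,
                 target_mean_cma = target_mean_cma),
            class = "archetype_spec")
}

#' Default calibrated archetypes
#'
#' The four archetypes behind the default synthetic cohort, with gap
#' parameters calibrated by Monte-Carlo so that the mean overall CMA9 of each
#' lands on the published group means 0.91 / 0.63 / 0.54 / 0.17.
#'
#' @return Named list of [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  list(
    high = archetype_spec("high", gap_mean = 33, target_mean_cma = 0.91),
    partial_drop_off = archetype_spec("partial_drop_off", gap_mean = 30,
                                      drop_month = 6, p_refill_late = 0.21,
                                      target_mean_cma = 0.63),
    moderate = archetype_spec("moderate", gap_mean = 58,
                              target_mean_cma = 0.54),
    low = archetype_spec("low", gap_mean = 35, stop_month = 2,
                         target_mean_cma = 0.17)
  )
}

#' Default covariate-to-group effects
#'
#' Log odds (relative to the high-adherence reference group) planted in the
#' default synthetic cohort: polypharmacy raises the odds of partial drop-off
#' (OR 1.194), and hospitalizations raise the odds of low adherence (OR 1.165
#' for heart-failure admissions, OR 1.481 for other admissions).
#'
#' @return A tibble with columns `covariate`, `group`, `beta`.
#' @export
default_coefficients <- function() {
  tibble::tribble(
    ~covariate,      ~group,             ~beta,
    "polypharmacy",  "partial_drop_off", log(1.194),
    "hosp_hf",       "low",              log(1.165),
    "hosp_other",    "low",              log(1.481)
  )
}

#' Synthetic-cohort generator configuration
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed (mandatory; the generator is fully deterministic
#'   given the config).
#' @param mixture_weights Named numeric of length 4 (high, partial_drop_off,
#'   moderate, low) summing to 1; the marginal trajectory-group proportions.
#' @param coefficients Tibble (`covariate`, `group`, `beta`) of planted
#'   log-odds effects of binary covariates on non-reference group membership,
#'   or `NULL` for none. Intercepts are solved numerically so the marginal
#'   group proportions still equal `mixture_weights`.
#' @param archetypes Named list of [archetype_spec()]s, one per group label.
#' @param covariate_prevalences Named probabilities of the binary covariates
#'   and comorbidity flags.
#' @param observation_days,supply_days Observation window and per-fill supply.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_patients, seed,
                             mixture_weights = c(high = 1898,
                                                 partial_drop_off = 874,
                                                 moderate = 862,
                                                 low = 821) / 4455,
                             coefficients = default_coefficients(),
                             archetypes = default_archetypes(),
                             covariate_prevalences = default_prevalences(),
                             observation_days = 365, supply_days = 30) {
  stopifnot(is.numeric(n_patients), length(n_patients) == 1, n_patients >= 1)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (abs(sum(mixture_weights) - 1) > 1e-9) {
    stop("mixture_weights must sum to 1")
  }
  if (any(mixture_weights < 0)) stop("mixture_weights must be nonnegative")
  stopifnot(setequal(names(mixture_weights), names(archetypes)))
  if (!is.null(coefficients) && any(!is.finite(coefficients$beta))) {
    stop("planted coefficients must be finite")
  }
  prev <- covariate_prevalences
  if (any(unlist(prev[c("polypharmacy", "hosp_hf", "hosp_other")]) < 0) ||
      any(unlist(prev[c("polypharmacy", "hosp_hf", "hosp_other")]) > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 mixture_weights = mixture_weights,
                 coefficients = coefficients, archetypes = archetypes,
                 covariate_prevalences = prev,
                 observation_days = observation_days,
                 supply_days = supply_days),
            class = "generator_config")
}

#' Default covariate prevalences
#'
#' Marginal prevalences for the generated binary covariates and comorbidity
#' flags, taken from the published baseline table of the emulated cohort
#' (male 70%, polypharmacy i.e. >= 5 drugs 68.7%, >= 1 HF hospitalization
#' 33.4%, comorbidity frequencies as printed).
#'
#' @return Named list of probabilities plus age mean/sd and the polypharmacy
#'   class split.
#' @export
default_prevalences <- function() {
  list(
    male = 0.70, age_mean = 69.1, age_sd = 12.0,
    # no / ordinary / excessive polypharmacy class split
    poly_classes = c(none = 0.306, polypharmacy = 0.316, excessive = 0.371),
    polypharmacy = 0.687,           # P(>= 5 distinct drugs)
    hosp_hf_rate = 0.407,           # Poisson rate giving P(>=1) = 0.334
    hosp_other_rate = 0.82,         # Poisson rate giving P(>=2) = 0.196
    hosp_hf = 1 - exp(-0.407),
    hosp_other = 1 - exp(-0.82),
    flags = c(mi = 0.077, diabetes = 0.114, renal_disease = 0.046,
              copd = 0.030, hypertension = 0.050, ccs = 0.076,
              atrial_fibrillation = 0.033)
  )
}

rgap_lognormal <- function(n, gap_mean, cv) {
  sdl <- sqrt(log(1 + cv^2))
  pmax(1, round(stats::rlnorm(n, log(gap_mean) - sdl^2 / 2, sdl)))
}

#' Simulate one refill history from an archetype
#'
#' Draws a dispensing history from the archetype's gap process using the
#' ambient RNG stream: the first fill is at day 0 (the index date), gaps are
#' lognormal (coefficient of variation `gap_cv`, truncated at 1 day), no fill
#' occurs after `stop_month` when present, and the drop-off shape switches to
#' sparse monthly Bernoulli refills after `drop_month`.
#'
#' @param spec An [archetype_spec()].
#' @param observation_days Length of the observation window.
#' @param supply_days Days of supply per fill.
#' @return A tibble with columns `day` and `days_supply`; all days lie in
#'   `[0, observation_days)`.
#' @export
simulate_archetype_events <- function(spec, observation_days = 365,
                                      supply_days = 30) {
  stopifnot(inherits(spec, "archetype_spec"))
  limit <- if (!is.na(spec$drop_month)) spec$drop_month * 30 else
    if (!is.na(spec$stop_month)) min(observation_days, spec$stop_month * 30) else
      observation_days
  cum <- cumsum(rgap_lognormal(ceiling(limit / spec$gap_mean * 2) + 3,
                               spec$gap_mean, spec$gap_cv))
  while (cum[length(cum)] < limit) {
    cum <- c(cum, cum[length(cum)] +
               cumsum(rgap_lognormal(5, spec$gap_mean, spec$gap_cv)))
  }
  days <- c(0, cum[cum < limit])
  if (!is.na(spec$drop_month)) {
    for (m in spec$drop_month:(floor(observation_days / 30) - 1)) {
      if (stats::runif(1) < spec$p_refill_late) {
        days <- c(days, m * 30 + sample(0:29, 1))
      }
    }
    days <- sort(unique(days))
  }
  days <- days[days < observation_days]
  tibble::tibble(day = as.integer(days),
                 days_supply = as.integer(rep(supply_days, length(days))))
}

#' Draw a trajectory-group label from planted multinomial-logit effects
#'
#' Group probabilities follow a multinomial logit: P(g) proportional to
#' exp(intercept_g + sum_j x_j beta_jg), with the reference group's
#' coefficients all zero. Coefficients absent from `coefficients` are 0.
#'
#' @param covariates Named logical/numeric vector of the patient's binary
#'   covariates.
#' @param intercepts Named numeric of per-group intercepts (reference
#'   included, typically 0 for the reference).
#' @param coefficients Tibble (`covariate`, `group`, `beta`) or `NULL`.
#' @return A single group label drawn with the implied probabilities.
#' @export
plant_group_membership <- function(covariates, intercepts,
                                   coefficients = NULL) {
  if (!is.null(coefficients) && any(!is.finite(coefficients$beta))) {
    stop("planted coefficients must be finite")
  }
  eta <- intercepts
  if (!is.null(coefficients)) {
    for (i in seq_len(nrow(coefficients))) {
      cv <- coefficients$covariate[i]
      g <- coefficients$group[i]
      eta[g] <- eta[g] + coefficients$beta[i] * as.numeric(covariates[[cv]])
    }
  }
  p <- exp(eta - max(eta))
  sample(names(intercepts), 1, prob = p / sum(p))
}

# Vectorized group planting for a whole covariate table: the same multinomial
# logit as plant_group_membership, drawn by inverse CDF with one uniform per
# patient.
plant_groups <- function(covariates, intercepts, coefficients = NULL) {
  groups <- names(intercepts)
  x <- as.matrix(as.data.frame(lapply(covariates, as.numeric)))
  beta <- matrix(0, ncol(x), length(groups),
                 dimnames = list(colnames(x), groups))
  if (!is.null(coefficients)) {
    if (any(!is.finite(coefficients$beta))) {
      stop("planted coefficients must be finite")
    }
    for (i in seq_len(nrow(coefficients))) {
      beta[coefficients$covariate[i], coefficients$group[i]] <-
        coefficients$beta[i]
    }
  }
  eta <- sweep(x %*% beta, 2, intercepts, `+`)
  p <- exp(eta - apply(eta, 1, max))
  p <- p / rowSums(p)
  cum <- t(apply(p, 1, cumsum))
  u <- stats::runif(nrow(x))
  groups[rowSums(u > cum) + 1]
}

# Solve per-group intercepts so that the marginal group probabilities, after
# averaging the multinomial logit over the joint law of the (independent
# binary) planted covariates, equal the requested mixture weights. The three
# binary covariates give 8 cells, so the expectation is exact; a fixed-point
# update on log-scale converges in a few iterations.
solve_intercepts <- function(weights, coefficients, prevalences) {
  groups <- names(weights)
  covs <- c("polypharmacy", "hosp_hf", "hosp_other")
  p <- unlist(prevalences[covs])
  cells <- as.matrix(expand.grid(rep(list(0:1), length(covs))))
  colnames(cells) <- covs
  cellp <- apply(cells, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  beta <- matrix(0, length(covs), length(groups),
                 dimnames = list(covs, groups))
  if (!is.null(coefficients)) {
    for (i in seq_len(nrow(coefficients))) {
      beta[coefficients$covariate[i], coefficients$group[i]] <-
        coefficients$beta[i]
    }
  }
  alpha <- log(weights) - log(weights[1])
  for (iter in 1:100) {
    eta <- sweep(cells %*% beta, 2, alpha, `+`)
    pr <- exp(eta)
    pr <- pr / rowSums(pr)
    marg <- colSums(pr * cellp)
    if (max(abs(marg - weights)) < 1e-12) break
    alpha <- alpha + log(weights) - log(marg)
    alpha <- alpha - alpha[1]
  }
  alpha
}

#' Generate a synthetic incident-user cohort
#'
#' Draws patients' covariates, trajectory-group memberships and full
#' dispensing histories. Every patient has a fill of the target drug
#' (C09DX04) at their index day 0; subsequent fills follow the archetype of
#' the patient's group. Group membership follows the multinomial logit
#' implied by `config$coefficients`, with intercepts solved so the marginal
#' group proportions equal `config$mixture_weights`. Patients who discontinue
#' may also receive fills of the alternative drug classes (C03/C07/C09) so
#' that switching analyses have material to work on.
#'
#' @param config A [generator_config()].
#' @return A list of tibbles: `events` (patient_id, day, atc, days_supply),
#'   `patients` (covariates at index), `truth` (patient_id, true_group).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  prev <- config$covariate_prevalences
  groups <- names(config$mixture_weights)

  poly_class <- sample(names(prev$poly_classes), n, replace = TRUE,
                       prob = prev$poly_classes)
  n_drugs <- dplyr::case_match(poly_class,
                               "none" ~ sample(1:4, n, replace = TRUE),
                               "polypharmacy" ~ sample(5:9, n, replace = TRUE),
                               "excessive" ~ sample(10:14, n, replace = TRUE))
  patients <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    sex = ifelse(stats::runif(n) < prev$male, "M", "F"),
    age_at_index = pmin(100, pmax(18, round(stats::rnorm(n, prev$age_mean,
                                                         prev$age_sd)))),
    n_distinct_drugs = n_drugs,
    n_hosp_hf = stats::rpois(n, prev$hosp_hf_rate),
    n_hosp_other = stats::rpois(n, prev$hosp_other_rate)
  )
  for (fl in names(prev$flags)) {
    patients[[fl]] <- stats::runif(n) < prev$flags[[fl]]
  }
  patients$chf <- TRUE  # every cohort member has heart failure
  patients$polypharmacy <- patients$n_distinct_drugs >= 5
  patients$hosp_hf <- patients$n_hosp_hf >= 1
  patients$hosp_other <- patients$n_hosp_other >= 1

  alpha <- solve_intercepts(config$mixture_weights, config$coefficients, prev)
  truth <- plant_groups(
    patients[c("polypharmacy", "hosp_hf", "hosp_other")],
    alpha, config$coefficients)

  ev <- vector("list", n)
  for (i in seq_len(n)) {
    e <- simulate_archetype_events(config$archetypes[[truth[i]]],
                                   config$observation_days,
                                   config$supply_days)
    e$patient_id <- patients$patient_id[i]
    e$atc <- "C09DX04"
    # discontinuers may pick up an alternative heart-failure drug afterwards
    last_end <- max(e$day) + config$supply_days
    if (last_end < config$observation_days - 30 && stats::runif(1) < 0.5) {
      sw_day <- last_end + sample(0:45, 1)
      if (sw_day < config$observation_days) {
        e <- dplyr::bind_rows(e, tibble::tibble(
          day = as.integer(sw_day), days_supply = 30L,
          patient_id = patients$patient_id[i],
          atc = sample(c("C03", "C07", "C09"), 1)))
      }
    }
    ev[[i]] <- e
  }
  events <- dplyr::bind_rows(ev)[, c("patient_id", "day", "atc", "days_supply")]
  list(events = events,
       patients = patients,
       truth = tibble::tibble(patient_id = patients$patient_id,
                              true_group = truth))
}

#' Write a generated cohort to plain CSV files
#'
#' Emits `dispensing.csv`, `patients.csv` and `groups.csv` into `dir`, the
#' interchange format consumed by [build_cohort()] and test harnesses.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("dispensing.csv", "patients.csv", "groups.csv"))
  readr::write_csv(cohort$events, paths[1])
  readr::write_csv(cohort$patients, paths[2])
  readr::write_csv(cohort$truth, paths[3])
  invisible(paths)
}
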