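#' Derive a stage seed from the pipeline seed
#'
#' One pipeline seed fans out deterministically to per-stage seeds (the stage
#' name is hashed into the offset), so individual stages can be re-run in
#' isolation with the same stream they saw inside the full run.
#'
#' @param seed Integer pipeline seed.
#' @param stage Stage name.
#' @return An integer below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full adherence-trajectory pipeline
#'
#' Generate (or ingest) a cohort, compute CMA9 trajectories, cluster and
#' label them, profile the groups, fit the multinomial membership model, and
#' write all tables plus a JSON run manifest. Identical configuration and
#' seed give identical outputs.
#'
#' @param generator A [generator_config()] for a synthetic run, or `NULL`
#'   when `input_dir` is given.
#' @param input_dir Directory of CSV inputs (see [read_cohort_csv()]);
#'   exactly one of `generator` / `input_dir` must be supplied. CSV inputs
#'   must carry index-based event days (day 0 = index date).
#' @param output_dir Directory for the output CSVs and manifest; `NULL`
#'   writes nothing.
#' @param seed Pipeline seed (mandatory; stages derive their own seeds via
#'   [stage_seed()]).
#' @param observation_days,window_days,grace_days,k_range,n_starts,p_threshold
#'   Stage parameters; defaults match the primary analysis (365-day window,
#'   12 x 30-day windows, 30-day grace, k in 2..6, 20 starts, p < 0.05).
#' @param model_covariates Covariates offered to the stepwise multinomial
#'   stage.
#' @return A list of class `adherence_pipeline`: `cohort`, `trajectories`,
#'   `clusters`, `profiles`, `group_summary`, `model` (stepwise result),
#'   `effects`, `manifest`.
#' @export
run_pipeline <- function(generator = NULL, input_dir = NULL,
                         output_dir = NULL, seed,
                         observation_days = 365, window_days = 30,
                         grace_days = 30, k_range = 2:6, n_starts = 20,
                         p_threshold = 0.05,
                         model_covariates = c("polypharmacy", "hosp_hf",
                                              "hosp_other", "age_at_index",
                                              "sex")) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(generator) == is.null(input_dir)) {
    stop("supply exactly one of 'generator' or 'input_dir'")
  }
  manifest <- list(seed = seed, stages = list())
  t0 <- Sys.time()
  note <- function(stage, ...) {
    message(sprintf("[%s] %s (%.1fs)", stage, paste0(...),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  if (!is.null(generator)) {
    cohort <- generate_cohort(generator)
    manifest$stages$simulate <- list(seed = generator$seed,
                                     n_patients = nrow(cohort$patients))
  } else {
    cohort <- read_cohort_csv(input_dir)
    manifest$stages$simulate <- list(source = input_dir,
                                     n_patients = nrow(cohort$patients))
  }
  note("cohort", nrow(cohort$patients), " patients, ",
       nrow(cohort$events), " dispensing events")

  traj <- cma_trajectories(cohort$events, cohort = cohort$patients,
                           period_days = observation_days,
                           window_days = window_days)
  manifest$stages$adherence <- list(n = nrow(traj),
                                    window_days = window_days,
                                    mean_overall = mean(traj$overall))
  note("adherence", "mean overall CMA9 = ",
       round(mean(traj$overall), 4))

  clus <- select_k(traj, k_range = k_range, n_starts = n_starts,
                   seed = stage_seed(seed, "cluster"))
  manifest$stages$cluster <- list(seed = stage_seed(seed, "cluster"),
                                  selected_k = clus$k,
                                  ch_by_k = as.list(stats::setNames(
                                    clus$ch_by_k$ch,
                                    paste0("k", clus$ch_by_k$k))),
                                  labels = clus$labels)
  note("cluster", "selected k = ", clus$k)

  prof <- patient_profiles(cohort$patients, cohort$events,
                           period_days = observation_days,
                           grace_days = grace_days)
  summ <- summarize_groups(prof, traj,
                           clus$assignments[c("patient_id", "label")])
  manifest$stages$profile <- list(groups = summ$label,
                                  group_n = as.list(stats::setNames(summ$n,
                                                                    summ$label)))
  note("profile", nrow(summ), " groups summarized")

  model_data <- dplyr::inner_join(
    clus$assignments[c("patient_id", "label")],
    prof, by = "patient_id")
  step <- stepwise_select(model_data, group = "label",
                          candidates = model_covariates,
                          p_threshold = p_threshold, reference = "high")
  effects <- if (!is.null(step$fit)) report_effects(step$fit) else
    tibble::tibble()
  manifest$stages$model <- list(selected = step$selected,
                                p_threshold = p_threshold)
  note("model", "selected covariates: ",
       paste(step$selected, collapse = ", "))

  out <- structure(list(cohort = cohort, trajectories = traj, clusters = clus,
                        profiles = prof, group_summary = summ, model = step,
                        effects = effects, manifest = manifest),
                   class = "adherence_pipeline")
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$trajectories, file.path(output_dir,
                                                  "trajectories.csv"))
  readr::write_csv(result$clusters$assignments,
                   file.path(output_dir, "assignments.csv"))
  cen <- tibble::as_tibble(result$clusters$centroids,
                           .name_repair = ~paste0("w", seq_along(.x)))
  cen$label <- result$clusters$labels
  readr::write_csv(cen, file.path(output_dir, "centroids.csv"))
  readr::write_csv(result$group_summary,
                   file.path(output_dir, "group_summary.csv"))
  if (nrow(result$effects)) {
    readr::write_csv(result$effects, file.path(output_dir, "effects.csv"))
  }
  jsonlite::write_json(result$manifest,
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.adherence_pipeline <- function(x, ...) {
  cat("Adherence-trajectory pipeline run\n")
  cat("  patients:", nrow(x$trajectories), "| selected k:", x$clusters$k,
      "\n")
  print(x$group_summary[c("label", "n", "pct", "cma_mean", "cma_sd")])
  invisible(x)
}
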