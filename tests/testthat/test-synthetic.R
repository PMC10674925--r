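test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(100, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(generator_config(100, seed = 43))
  expect_false(identical(a$events, c2$events))
})

test_that("config validation rejects bad weights, seeds and prevalences", {
  expect_error(generator_config(100, seed = 1,
                                mixture_weights = c(high = 0.5,
                                                    partial_drop_off = 0.5,
                                                    moderate = 0.2,
                                                    low = -0.2)))
  expect_error(generator_config(100, seed = 1,
                                mixture_weights = c(high = 0.3,
                                                    partial_drop_off = 0.3,
                                                    moderate = 0.3,
                                                    low = 0.3)),
               "sum to 1")
  expect_error(generator_config(-5, seed = 1))
  expect_error(generator_config(100), "seed")
  bad <- default_coefficients()
  bad$beta[1] <- Inf
  expect_error(generator_config(100, seed = 1, coefficients = bad), "finite")
})

test_that("archetype invariants are enforced", {
  expect_error(archetype_spec("high", 33, stop_month = 2,
                              target_mean_cma = 0.9), "stop_month")
  expect_error(archetype_spec("low", 35, stop_month = 5,
                              target_mean_cma = 0.17), "month 3")
  expect_error(archetype_spec("moderate", 58, target_mean_cma = 1.4))
})

test_that("archetype event streams respect their structural constraints", {
  set.seed(1)
  arch <- default_archetypes()
  for (i in 1:50) {
    low <- simulate_archetype_events(arch$low)
    expect_equal(low$day[1], 0L)
    expect_true(all(low$day < 60))        # no refills after stop month 2
    expect_lte(nrow(low), 3)
    pdo <- simulate_archetype_events(arch$partial_drop_off)
    expect_true(all(pdo$day >= 0 & pdo$day < 365))
    high <- simulate_archetype_events(arch$high)
    expect_true(all(diff(high$day) >= 1))
  }
})

test_that("zero-dispersion 30-day gaps give exact monthly fills", {
  spec <- archetype_spec("high", gap_mean = 30, gap_cv = 1e-9,
                         target_mean_cma = 1)
  e <- simulate_archetype_events(spec, observation_days = 360)
  expect_equal(e$day, seq(0L, 330L, 30L))
})

test_that("each archetype's mean CMA9 is calibrated to its target", {
  set.seed(20)
  arch <- default_archetypes()
  for (nm in names(arch)) {
    cma <- vapply(1:1000, function(i) {
      compute_cma9(simulate_archetype_events(arch[[nm]]), 365)
    }, 0)
    expect_lt(abs(mean(cma) - arch[[nm]]$target_mean_cma), 0.03,
              label = paste("archetype", nm, "mean", round(mean(cma), 3)))
  }
})

test_that("degenerate mixture weights send every patient to one archetype", {
  cfg <- generator_config(300, seed = 5,
                          mixture_weights = c(high = 1, partial_drop_off = 0,
                                              moderate = 0, low = 0),
                          coefficients = NULL)
  co <- generate_cohort(cfg)
  expect_true(all(co$truth$true_group == "high"))
  tr <- cma_trajectories(co$events, cohort = co$patients)
  se <- stats::sd(tr$overall) / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$overall) - 0.91), 3 * se + 0.03)
})

test_that("mixture weights are conserved in expectation", {
  co <- generate_cohort(generator_config(2000, seed = 9,
                                         coefficients = NULL))
  w <- c(high = 1898, partial_drop_off = 874, moderate = 862, low = 821) / 4455
  frac <- table(factor(co$truth$true_group, names(w))) / 2000
  for (g in names(w)) {
    se <- sqrt(w[[g]] * (1 - w[[g]]) / 2000)
    expect_lt(abs(frac[[g]] - w[[g]]), 3 * se)
  }
})

test_that("planted membership follows the multinomial logit", {
  groups <- c(high = 0, partial_drop_off = 0, moderate = 0, low = 0)
  set.seed(31)
  draws <- replicate(4000, plant_group_membership(list(x = 0), groups, NULL))
  frac <- table(draws) / 4000
  expect_true(all(abs(frac - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000)))
  # a planted log(2) effect doubles the odds of its group exactly in the law
  cf <- tibble::tibble(covariate = "x", group = "low", beta = log(2))
  set.seed(32)
  d1 <- replicate(6000, plant_group_membership(list(x = 1), groups, cf))
  d0 <- replicate(6000, plant_group_membership(list(x = 0), groups, cf))
  or_hat <- (mean(d1 == "low") / mean(d1 == "high")) /
    (mean(d0 == "low") / mean(d0 == "high"))
  expect_lt(abs(or_hat - 2), 0.35)
  expect_error(plant_group_membership(list(x = 1), groups,
                                      tibble::tibble(covariate = "x",
                                                     group = "low",
                                                     beta = NaN)),
               "finite")
})

test_that("intercept solving reproduces the target marginal mixture", {
  prev <- default_prevalences()
  w <- c(high = 1898, partial_drop_off = 874, moderate = 862, low = 821) / 4455
  alpha <- adheretraj:::solve_intercepts(w, default_coefficients(), prev)
  # recompute the implied marginal by exact enumeration over the 8 cells
  covs <- c("polypharmacy", "hosp_hf", "hosp_other")
  p <- unlist(prev[covs])
  cells <- as.matrix(expand.grid(rep(list(0:1), 3)))
  colnames(cells) <- covs
  cellp <- apply(cells, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  beta <- matrix(0, 3, 4, dimnames = list(covs, names(w)))
  cf <- default_coefficients()
  for (i in seq_len(nrow(cf))) beta[cf$covariate[i], cf$group[i]] <- cf$beta[i]
  pr <- exp(sweep(cells %*% beta, 2, alpha, `+`))
  pr <- pr / rowSums(pr)
  expect_equal(colSums(pr * cellp), w, tolerance = 1e-10)
})

test_that("cohort CSVs round-trip through the interchange format", {
  co <- generate_cohort(generator_config(40, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  back <- read_cohort_csv(dir)
  expect_equal(back$events$day, co$events$day)
  expect_equal(back$patients$patient_id, co$patients$patient_id)
  expect_equal(back$truth$true_group, co$truth$true_group)
})
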