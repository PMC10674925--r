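#' Multinomial logistic regression of trajectory-group membership
#'
#' Fits a maximum-likelihood multinomial logit of group membership on
#' covariates, with the high-adherence group as the reference by default.
#' Wald 95% confidence intervals are reported on the odds-ratio scale.
#'
#' @param data Data frame containing the group column and the covariates.
#' @param group Name of the group column (character/factor).
#' @param covariates Character vector of covariate column names. Continuous
#'   covariates enter untransformed; factors/characters are dummy-coded
#'   against their most prevalent level; logicals against `FALSE`.
#' @param reference Reference group label (default `"high"`).
#' @param maxit Maximum optimizer iterations.
#' @return An `adherence_multinom` object wrapping the fit, with a tidy
#'   effects table (see [tidy.adherence_multinom()]).
#' @export
fit_trajectory_multinom <- function(data, group = "true_group", covariates,
                                    reference = "high", maxit = 500) {
  stopifnot(length(covariates) >= 1)
  g <- as.character(data[[group]])
  lv <- unique(g)
  if (length(lv) < 2) stop("need at least 2 groups present")
  if (!reference %in% lv) stop("reference group '", reference, "' not present")
  y <- factor(g, levels = c(reference, sort(setdiff(lv, reference))))
  x <- data[covariates]
  for (j in names(x)) {
    if (is.character(x[[j]]) || is.factor(x[[j]])) {
      tab <- sort(table(x[[j]]), decreasing = TRUE)
      x[[j]] <- factor(as.character(x[[j]]), levels = names(tab))
    } else {
      x[[j]] <- as.numeric(x[[j]])
    }
  }
  mm <- stats::model.matrix(~., data = x)
  if (qr(mm)$rank < ncol(mm)) {
    stop("rank-deficient design: remove collinear or constant covariates")
  }
  df <- data.frame(.group = y, x, check.names = FALSE)
  fit <- nnet::multinom(.group ~ ., data = df, Hess = TRUE, trace = FALSE,
                        maxit = maxit, reltol = 1e-14)
  coefs <- stats::coef(fit)
  if (length(lv) == 2) coefs <- matrix(coefs, nrow = 1,
                                       dimnames = list(levels(y)[2],
                                                       names(coefs)))
  ses <- summary(fit)$standard.errors
  if (length(lv) == 2) ses <- matrix(ses, nrow = 1,
                                     dimnames = dimnames(coefs))
  big <- abs(coefs) > 12 & (ses > 50 | ses < 1e-8)
  if (any(big)) {
    bad <- unique(colnames(coefs)[which(big, arr.ind = TRUE)[, 2]])
    stop("possible perfect separation for covariate(s): ",
         paste(setdiff(bad, "(Intercept)"), collapse = ", "))
  }
  structure(list(fit = fit, reference = reference, covariates = covariates,
                 coefficients = coefs, standard_errors = ses,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n = nrow(df)),
            class = "adherence_multinom")
}

#' Tidy odds-ratio table of a multinomial fit
#'
#' One row per (non-reference group, model term): log-odds estimate, standard
#' error, odds ratio, Wald 95% CI and p-value, sorted by group then term.
#' Intercept rows are kept (`term == "(Intercept)"`).
#'
#' @param x An `adherence_multinom` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.adherence_multinom <- function(x, ...) {
  co <- x$coefficients
  se <- x$standard_errors
  out <- tibble::tibble(
    group = rep(rownames(co), times = ncol(co)),
    term = rep(colnames(co), each = nrow(co)),
    estimate = as.vector(co),
    std_error = as.vector(se)
  ) |>
    dplyr::mutate(odds_ratio = exp(.data$estimate),
                  ci_low = exp(.data$estimate - 1.96 * .data$std_error),
                  ci_high = exp(.data$estimate + 1.96 * .data$std_error),
                  p_value = 2 * stats::pnorm(-abs(.data$estimate /
                                                    .data$std_error))) |>
    dplyr::arrange(.data$group, .data$term)
  out
}

#' One-row summary of a multinomial fit
#'
#' @inheritParams tidy.adherence_multinom
#' @return A tibble: `n`, `n_groups`, `log_likelihood`, `deviance`, `edf`.
#' @export
glance.adherence_multinom <- function(x, ...) {
  tibble::tibble(n = x$n, n_groups = nrow(x$coefficients) + 1,
                 log_likelihood = x$log_likelihood,
                 deviance = x$fit$deviance, edf = x$fit$edf)
}

#' Odds-ratio effects table
#'
#' The tidy effects table without intercept rows, the forest-plot input.
#'
#' @param fit An `adherence_multinom` object.
#' @return A tibble (group, term, odds_ratio, ci_low, ci_high, p_value).
#' @export
report_effects <- function(fit) {
  tidy.adherence_multinom(fit) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::select("group", "term", "odds_ratio", "ci_low", "ci_high",
                  "p_value")
}

#' Forest plot of group-membership odds ratios
#'
#' @param object An `adherence_multinom` object.
#' @param ... Unused.
#' @return A ggplot object: odds ratios with Wald 95% CIs per covariate,
#'   faceted by non-reference group.
#' @export
autoplot.adherence_multinom <- function(object, ...) {
  eff <- report_effects(object)
  ggplot2::ggplot(eff, ggplot2::aes(.data$odds_ratio, .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Odds ratio (vs high adherence)", y = NULL) +
    ggplot2::theme_minimal()
}

# likelihood-ratio p-value for nested multinomial fits
lr_pvalue <- function(fit_small, fit_big) {
  stat <- 2 * (fit_big$log_likelihood - fit_small$log_likelihood)
  df <- fit_big$fit$edf - fit_small$fit$edf
  stats::pchisq(max(0, stat), df = max(1, df), lower.tail = FALSE)
}

null_loglik <- function(data, group, reference) {
  g <- as.character(data[[group]])
  p <- table(g) / length(g)
  ll <- sum(log(p[g]))
  k <- length(p)
  list(log_likelihood = ll, fit = list(edf = k - 1))
}

#' Stepwise covariate selection for the multinomial model
#'
#' Forward stepwise with backward pruning on likelihood-ratio tests: at each
#' step the candidate with the smallest LR p-value below the threshold is
#' added; after every addition any included covariate whose removal p-value
#' is at or above the threshold is dropped; stops when nothing changes. Ties
#' are broken alphabetically, so the procedure is deterministic.
#'
#' @inheritParams fit_trajectory_multinom
#' @param candidates Character vector of candidate covariates.
#' @param p_threshold Significance threshold (default 0.05).
#' @return A list: `selected` (character, possibly empty) and `fit` (the
#'   final `adherence_multinom`, or `NULL` when nothing was selected).
#' @export
stepwise_select <- function(data, group = "true_group", candidates,
                            p_threshold = 0.05, reference = "high") {
  stopifnot(length(candidates) >= 1)
  selected <- character(0)
  fit_cache <- function(covs) {
    if (!length(covs)) null_loglik(data, group, reference) else
      fit_trajectory_multinom(data, group, sort(covs), reference)
  }
  current <- fit_cache(selected)
  repeat {
    changed <- FALSE
    # forward step
    pool <- sort(setdiff(candidates, selected))
    if (length(pool)) {
      pvals <- purrr::map_dbl(pool, function(cv) {
        lr_pvalue(current, fit_cache(c(selected, cv)))
      })
      if (any(pvals < p_threshold)) {
        add <- pool[which.min(pvals)]  # alphabetical order breaks ties
        selected <- c(selected, add)
        current <- fit_cache(selected)
        changed <- TRUE
      }
    }
    # backward pruning
    repeat {
      if (!length(selected)) break
      drop_p <- purrr::map_dbl(sort(selected), function(cv) {
        lr_pvalue(fit_cache(setdiff(selected, cv)), current)
      })
      worst <- which.max(drop_p)
      if (drop_p[worst] >= p_threshold) {
        selected <- setdiff(selected, sort(selected)[worst])
        current <- fit_cache(selected)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  list(selected = sort(selected),
       fit = if (length(selected)) current else NULL)
}
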