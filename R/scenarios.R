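#' Named analysis scenarios
#'
#' The end-to-end comparisons the analysis runs: the two all-subsets
#' averaging scenarios (ISAW metrics alone; ISAW metrics plus fall
#' history and age), the clinical reference models (fall history + age;
#' age alone; gait speed alone), the dual-task-cost discriminators, and
#' the augmented space that adds the turn-velocity dual-task cost to the
#' 17 single-task metrics as an 18th candidate predictor.
#'
#' @return Character vector of valid scenario ids.
#' @export
scenario_ids <- function() {
  c("isaw_only", "isaw_history_age", "history_age_only", "age_only",
    "gait_speed_only", "dtc_gait_speed", "dtc_turn_velocity",
    "isaw_plus_dtc_turn")
}

#' Run one named scenario end-to-end
#'
#' Restricts the cohort to determinate fall status, then runs the
#' scenario's analysis: all-subsets BIC-weighted model averaging with a
#' model frontier and the ROC of the averaged risk (BMA scenarios); a
#' single logistic fit (history + age); or a raw-score discriminator
#' (single metrics and dual-task costs, reported in both the natural
#' orientation and the AUC >= 0.5 orientation).  Dual-task scenarios
#' first derive the per-participant dual-task cost column and can
#' optionally add the base covariates.
#'
#' @param scenario One of [scenario_ids()].
#' @param cohort Cohort data frame.
#' @param registry Metric registry.
#' @param top_count Frontier size for BMA scenarios.
#' @param seed Seed for the bootstrap confidence interval.
#' @param ci_reps Bootstrap replicates.
#' @param max_size Optional subset-size cap for BMA scenarios.
#' @param with_covariates For dual-task scenarios, additionally fit
#'   `outcome ~ dtc + age + prior_falls` and report its AUC.
#' @return Object of class `scenario_result`: list with `scenario`,
#'   `auc`, `ci`, `roc`, and scenario-specific members (`bma`,
#'   `frontier`, `fit`, `auc_raw`, `orientation`, `auc_with_covariates`).
#' @export
run_scenario <- function(scenario, cohort, registry = isaw_metrics(),
                         top_count = 100, seed = 1L, ci_reps = 2000,
                         max_size = NULL, with_covariates = FALSE) {
  scenario <- match.arg(scenario, scenario_ids())
  cohort <- analysis_subset(cohort)
  y <- cohort$future_faller
  out <- list(scenario = scenario, n = nrow(cohort))

  score_bundle <- function(score) {
    a_raw <- auc(score, y)
    oriented <- if (a_raw >= 0.5) score else -score
    ci <- auc_ci(oriented, y, reps = ci_reps, seed = seed)
    list(auc_raw = a_raw, auc = max(a_raw, 1 - a_raw),
         orientation = if (a_raw >= 0.5) "higher score = higher risk"
                       else "lower score = higher risk",
         ci = ci$ci, roc = roc_curve(oriented, y))
  }

  if (scenario %in% c("isaw_only", "isaw_history_age", "isaw_plus_dtc_turn")) {
    if (scenario == "isaw_plus_dtc_turn") {
      cohort$turn_velocity_dtc <- cohort_dtc(cohort, "turn_velocity", registry)
      registry <- rbind(
        as_registry(registry),
        data.frame(name = "turn_velocity_dtc", domain = "T",
                   log_scale = FALSE, units = "%", stringsAsFactors = FALSE)
      )
    }
    b <- run_bma(cohort, registry,
                 include_history_age = scenario == "isaw_history_age",
                 max_size = max_size, scenario = scenario)
    ci <- auc_ci(b$avg_risk, y, reps = ci_reps, seed = seed)
    out$bma <- b
    out$frontier <- frontier(b, top_count)
    out$roc <- roc_curve(b$avg_risk, y)
    out$auc <- ci$auc
    out$ci <- ci$ci
  } else if (scenario == "history_age_only") {
    fit <- fit_logistic(y, cbind(age = cohort$age,
                                 prior_falls = cohort$prior_falls))
    ci <- auc_ci(fit$fitted, y, reps = ci_reps, seed = seed)
    out$fit <- fit
    out$roc <- roc_curve(fit$fitted, y)
    out$auc <- ci$auc
    out$ci <- ci$ci
  } else if (scenario %in% c("age_only", "gait_speed_only")) {
    score <- if (scenario == "age_only") cohort$age else cohort$gait_speed
    out <- c(out, score_bundle(score))
  } else {
    metric <- sub("^dtc_", "", scenario)
    out$dtc <- cohort_dtc(cohort, metric, registry)
    out <- c(out, score_bundle(out$dtc))
    if (with_covariates) {
      fit <- fit_logistic(y, cbind(dtc = out$dtc, age = cohort$age,
                                   prior_falls = cohort$prior_falls))
      out$fit_with_covariates <- fit
      out$auc_with_covariates <- auc(fit$fitted, y)
    }
  }
  class(out) <- "scenario_result"
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario:", x$scenario, sprintf("(n = %d)\n", x$n))
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC = %.3f", x$auc))
    if (!is.null(x$ci)) cat(sprintf(" (%.3f, %.3f)", x$ci[1], x$ci[2]))
    cat("\n")
  }
  if (!is.null(x$orientation)) cat("  orientation:", x$orientation, "\n")
  if (!is.null(x$bma)) print(x$bma)
  invisible(x)
}

#' Posterior-inclusion-probability table across the two BMA scenarios
#'
#' One row per metric with its domain tag and the PIP under (a) metrics
#' alone and (b) metrics plus fall history and age, flagging
#' probabilities above the reporting threshold (default 0.40).
#'
#' @param bma_isaw [run_bma()] result without base covariates.
#' @param bma_history_age [run_bma()] result with base covariates.
#' @param registry Metric registry (for domain tags).
#' @param threshold Flagging threshold.
#' @return Data frame `name`, `domain`, `pip_isaw_only`,
#'   `pip_history_age`, `flag_isaw_only`, `flag_history_age`.
#' @export
pip_table <- function(bma_isaw, bma_history_age, registry = isaw_metrics(),
                      threshold = 0.40) {
  registry <- as_registry(registry)
  nm <- names(bma_isaw$pip)
  stopifnot(identical(nm, names(bma_history_age$pip)))
  data.frame(
    name = nm,
    domain = registry$domain[match(nm, registry$name)],
    pip_isaw_only = unname(bma_isaw$pip),
    pip_history_age = unname(bma_history_age$pip),
    flag_isaw_only = unname(bma_isaw$pip > threshold),
    flag_history_age = unname(bma_history_age$pip > threshold),
    stringsAsFactors = FALSE
  )
}
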