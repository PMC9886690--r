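#' Two-sample Student t-test from summary statistics
#'
#' Pooled-variance two-sample t-test computed from group means, SDs and
#' sizes, with `df = n1 + n2 - 2`.  The t statistic is signed as
#' `mean2 - mean1`, so passing non-fallers first and fallers second gives
#' the faller-minus-non-faller convention.  A Welch (unequal-variance)
#' variant is available behind `welch = TRUE`.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param welch Use the Welch-Satterthwaite approximation instead of the
#'   pooled variance.
#' @return List with elements `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' # group difference in gait speed (m/s) between 123 and 91 participants
#' student_t_pvalue(1.064, 0.176, 123, 1.000, 0.187, 91)
student_t_pvalue <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    warning("both SDs zero with unequal means; p = 0 by convention")
    return(list(t = sign(mean2 - mean1) * Inf, df = n1 + n2 - 2, p = 0))
  }
  if (welch) {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (mean2 - mean1) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Per-metric group summary with t-tests
#'
#' One row per registry metric: mean and SD in each outcome group on the
#' analysis scale, plus the pooled Student t statistic and two-sided
#' p-value for the faller-minus-non-faller difference.
#'
#' @param cohort Cohort data frame with determinate `future_faller`.
#' @param registry Metric registry.
#' @param welch Passed to [student_t_pvalue()].
#' @return Data frame with columns `name`, `domain`, `mean_nonfaller`,
#'   `sd_nonfaller`, `mean_faller`, `sd_faller`, `t`, `p`.
#' @export
group_summary <- function(cohort, registry = isaw_metrics(), welch = FALSE) {
  registry <- as_registry(registry)
  y <- cohort$future_faller
  if (!any(y == 0, na.rm = TRUE)) stop("no non-fallers in cohort")
  if (!any(y == 1, na.rm = TRUE)) stop("no fallers in cohort")
  nf <- which(y == 0)
  fa <- which(y == 1)
  rows <- lapply(seq_len(nrow(registry)), function(j) {
    m <- registry$name[j]
    x0 <- cohort[[m]][nf]
    x1 <- cohort[[m]][fa]
    if (stats::sd(x0) == 0 && stats::sd(x1) == 0 && mean(x0) == mean(x1)) {
      tt <- list(t = 0, p = 1)
    } else {
      tt <- student_t_pvalue(mean(x0), stats::sd(x0), length(x0),
                             mean(x1), stats::sd(x1), length(x1),
                             welch = welch)
    }
    data.frame(name = m,
               domain = if ("domain" %in% names(registry)) registry$domain[j] else NA,
               mean_nonfaller = mean(x0), sd_nonfaller = stats::sd(x0),
               mean_faller = mean(x1), sd_faller = stats::sd(x1),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_nonfaller") <- length(nf)
  attr(out, "n_faller") <- length(fa)
  out
}

#' Prior-by-prospective fall status cross-tabulation
#'
#' Dichotomises fall history at one or more prior-year falls and
#' cross-tabulates against prospective faller status, with conditional
#' row percentages (the share of prior non-fallers who stayed fall-free,
#' and of prior fallers who fell again).
#'
#' @param cohort Cohort with `prior_falls` and determinate
#'   `future_faller` for all rows.
#' @return Object of class `fall_crosstab`: list with `counts` (2x2
#'   integer matrix, rows prior status, columns future status), `row_pct`
#'   (conditional row percentages), and `n`.
#' @export
fall_status_crosstab <- function(cohort) {
  if (anyNA(cohort$future_faller)) {
    stop("cohort contains indeterminate fall status; apply analysis_subset() first")
  }
  prior <- factor(cohort$prior_falls >= 1, levels = c(FALSE, TRUE),
                  labels = c("prior_nonfaller", "prior_faller"))
  future <- factor(cohort$future_faller, levels = c(0, 1),
                   labels = c("future_nonfaller", "future_faller"))
  counts <- table(prior, future)
  counts <- matrix(as.integer(counts), 2, 2, dimnames = dimnames(counts))
  row_pct <- 100 * counts / pmax(rowSums(counts), 1L)
  row_pct[rowSums(counts) == 0, ] <- NA_real_
  structure(list(counts = counts, row_pct = row_pct, n = nrow(cohort)),
            class = "fall_crosstab")
}

#' @export
print.fall_crosstab <- function(x, ...) {
  cat("Fall-status cross-tabulation (n = ", x$n, ")\n\n", sep = "")
  print(x$counts)
  cat("\nConditional row percentages:\n")
  print(round(x$row_pct, 1))
  invisible(x)
}

#' Dual-task cost
#'
#' `100 * (dual - single) / single` percent: the signed relative change
#' in a metric when the task is performed under a concurrent cognitive
#' load.  Negative values mean the dual task degraded (slowed, shrank)
#' the metric.
#'
#' @param single_task,dual_task Metric values on the natural scale;
#'   vectorised.
#' @return Signed percentage cost.
#' @export
#' @examples
#' dual_task_cost(1.0, 0.8)   # -20% : gait slowed by a fifth
#' dual_task_cost(160, 180)   # +12.5% : turn sped up
dual_task_cost <- function(single_task, dual_task) {
  if (any(single_task == 0)) stop("dual-task cost undefined for single_task = 0")
  100 * (dual_task - single_task) / single_task
}

# Dual-task cost column for one metric of a cohort, computed on the
# natural scale (log-scale metrics are exponentiated first).
cohort_dtc <- function(cohort, metric, registry = isaw_metrics()) {
  registry <- as_registry(registry)
  dt_col <- paste0(metric, "_dt")
  if (!metric %in% names(cohort) || !dt_col %in% names(cohort)) {
    stop("cohort lacks single- or dual-task column for metric '", metric, "'")
  }
  on_log <- isTRUE(registry$log_scale[registry$name == metric])
  single <- if (on_log) exp(cohort[[metric]]) else cohort[[metric]]
  dual <- if (on_log) exp(cohort[[dt_col]]) else cohort[[dt_col]]
  dual_task_cost(single, dual)
}
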