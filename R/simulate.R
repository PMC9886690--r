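#' Configuration for the synthetic cohort generator
#'
#' Bundles everything the generator needs: group sizes, the master seed,
#' the inter-metric dependence structure, the prior-fall count model, the
#' age distribution, dual-task cost parameters, and the prospective
#' fall-status missingness rate.
#'
#' Defaults reproduce the reference study conditions: 123 non-fallers and
#' 91 fallers; probability of at least one prior-year fall 0.260
#' (non-fallers) and 0.527 (fallers) with group mean counts 40/123 and
#' 125/91; ages centred in the low 80s with per-group median (IQR) of
#' 83 (80, 86) and 84 (80, 89) over the range 78-96; mean dual-task cost
#' on gait speed of about -20% in both groups; mean dual-task cost on turn
#' velocity of -13.33% (non-fallers) versus -3.14% (fallers); no
#' indeterminate fall status.
#'
#' @param n_nonfallers,n_fallers Non-negative group sizes.
#' @param seed Integer master seed; all random streams are derived from it.
#' @param correlation Either a single exchangeable correlation `rho` in
#'   \[0, 1) applied to every metric pair (0 = independent metrics, the
#'   default), or a full symmetric positive-definite 17x17 (or p x p)
#'   correlation matrix.
#' @param prior_fall_params Named list with elements `nonfaller` and
#'   `faller`, each `list(p_any = , mean = )`: the probability of at least
#'   one prior-year fall and the mean prior-year fall count.
#' @param max_prior_falls Truncation cap on the simulated per-participant
#'   prior-year fall count (default 13, the published per-participant
#'   maximum).
#' @param age_params Named list with elements `nonfaller` and `faller`,
#'   each `c(q25, median, q75)`, plus `min` and `max` range endpoints.
#' @param dtc_params Data frame with columns `name`, `mean_nonfaller`,
#'   `sd_nonfaller`, `mean_faller`, `sd_faller` giving per-metric,
#'   per-group dual-task cost (percent) distributions.  Only listed
#'   metrics receive dual-task counterpart columns.
#' @param missingness_rate Probability in \[0, 1\] that a participant's
#'   prospective fall status is indeterminate.
#' @return An object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(n_nonfallers = 123,
                          n_fallers = 91,
                          seed = 1L,
                          correlation = 0,
                          prior_fall_params = list(
                            nonfaller = list(p_any = 0.260, mean = 40 / 123),
                            faller = list(p_any = 0.527, mean = 125 / 91)
                          ),
                          max_prior_falls = 13L,
                          age_params = list(
                            nonfaller = c(q25 = 80, median = 83, q75 = 86),
                            faller = c(q25 = 80, median = 84, q75 = 89),
                            min = 78, max = 96
                          ),
                          dtc_params = default_dtc_params(),
                          missingness_rate = 0) {
  if (n_nonfallers < 0 || n_fallers < 0) {
    stop("group sizes must be non-negative")
  }
  for (g in c("nonfaller", "faller")) {
    p <- prior_fall_params[[g]]
    if (is.null(p) || p$p_any < 0 || p$p_any > 1) {
      stop("prior_fall_params$", g, "$p_any must be a probability in [0, 1]")
    }
    if (p$mean < p$p_any) {
      stop("prior_fall_params$", g,
           ": mean count must be at least P(>=1 fall)")
    }
  }
  if (missingness_rate < 0 || missingness_rate > 1) {
    stop("missingness_rate must be in [0, 1]")
  }
  if (is.matrix(correlation)) {
    if (!isSymmetric(correlation)) {
      stop("correlation matrix must be symmetric")
    }
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      stop("correlation matrix must be positive-definite")
    }
  } else if (length(correlation) != 1 || correlation < 0 || correlation >= 1) {
    stop("exchangeable correlation must be a single value in [0, 1)")
  }
  structure(
    list(n_nonfallers = as.integer(n_nonfallers),
         n_fallers = as.integer(n_fallers),
         seed = as.integer(seed),
         correlation = correlation,
         prior_fall_params = prior_fall_params,
         max_prior_falls = as.integer(max_prior_falls),
         age_params = age_params,
         dtc_params = dtc_params,
         missingness_rate = missingness_rate),
    class = "cohort_config"
  )
}

#' Default dual-task cost parameters
#'
#' Dual-task cost (DTC) is `100 * (dual - single) / single` percent, so a
#' slowing under the concurrent cognitive task is a negative cost.  Group
#' means follow the published values: gait speed slows by about 20% in
#' both groups (-20.53% fallers, -19.99% non-fallers); turn velocity slows
#' by 13.33% in non-fallers but only 3.14% on average in fallers (roughly
#' half of fallers sped their turns up).  Spreads are not published; the
#' defaults (SD 10 percentage points for gait speed, 15 for turn velocity)
#' make nearly all participants slow their gait while roughly half the
#' fallers speed up their turns, matching the qualitative description.
#'
#' @return Data frame with columns `name`, `mean_nonfaller`,
#'   `sd_nonfaller`, `mean_faller`, `sd_faller` (percent units).
#' @export
default_dtc_params <- function() {
  data.frame(
    name = c("gait_speed", "turn_velocity"),
    mean_nonfaller = c(-19.99, -13.33),
    sd_nonfaller = c(10, 15),
    mean_faller = c(-20.53, -3.14),
    sd_faller = c(10, 15),
    stringsAsFactors = FALSE
  )
}

# Deterministic substream seed from the master seed and a stream label,
# kept below 2^31.  A simple polynomial string hash is enough: streams only
# need to be distinct and reproducible.
stream_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1009
  (abs(as.numeric(seed)) * 1013 + h * 2654435 + 17) %% 2147483587
}

# Solve zero-inflated Poisson parameters from the two printed moments:
# P(X >= 1) = (1 - pzero) * (1 - exp(-lambda)) and
# E[X]      = (1 - pzero) * lambda,
# so lambda solves (1 - exp(-lambda)) / lambda = p_any / mean.  Sampling
# uses the equivalent hurdle form: the count is positive with probability
# exactly p_any, and the positive part is Poisson(lambda) truncated to
# >= 1 (identical to the ZIP distribution conditioned on positivity).
solve_zip <- function(p_any, mean_count) {
  if (p_any == 0) {
    return(list(p_positive = 0, lambda = 0))
  }
  ratio <- p_any / mean_count # in (0, 1]
  if (ratio >= 1 - 1e-9) {
    # lambda -> 0 limit: positive counts are all exactly 1
    return(list(p_positive = p_any, lambda = 1e-8))
  }
  f <- function(l) (1 - exp(-l)) / l - ratio
  lambda <- stats::uniroot(f, c(1e-8, 500), tol = 1e-12)$root
  list(p_positive = p_any, lambda = lambda)
}

#' Draw prior-year fall counts for one outcome group
#'
#' Counts follow a zero-inflated Poisson whose zero mass and rate are
#' solved from the configured per-group probability of at least one fall
#' and mean count, truncated at `config$max_prior_falls`.
#'
#' @param group `"nonfaller"` or `"faller"`.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this draw.
#' @param n Number of counts to draw.
#' @return Integer vector of length `n`.
#' @export
generate_prior_falls <- function(group, config, seed, n = 1L) {
  if (!group %in% c("nonfaller", "faller")) {
    stop("unknown group label: ", group)
  }
  par <- config$prior_fall_params[[group]]
  zip <- solve_zip(par$p_any, par$mean)
  with_seed(seed, {
    nonzero <- stats::runif(n) < zip$p_positive
    counts <- integer(n)
    if (any(nonzero)) {
      # positive component: Poisson conditioned on >= 1 via inverse CDF on
      # a uniform restricted above P(0)
      u <- stats::runif(sum(nonzero))
      p0 <- stats::dpois(0, zip$lambda)
      counts[nonzero] <- stats::qpois(p0 + u * (1 - p0), zip$lambda)
    }
    pmin(counts, config$max_prior_falls)
  })
}

# Evaluate `code` under a temporary RNG state so generator substreams do
# not disturb (or depend on) the caller's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# Piecewise-linear quantile sampler through (0, min), (.25, q25),
# (.5, median), (.75, q75), (1, max); ages reported in whole years.
sample_ages <- function(n, quartiles, lo, hi, seed) {
  u <- with_seed(seed, stats::runif(n))
  qs <- stats::approx(x = c(0, 0.25, 0.5, 0.75, 1),
                      y = c(lo, quartiles[["q25"]], quartiles[["median"]],
                            quartiles[["q75"]], hi),
                      xout = u, method = "linear")$y
  as.integer(round(qs))
}

#' Generate a synthetic ISAW cohort
#'
#' Draws a case-control cohort whose group-conditional structure matches
#' configured marginal summaries: each metric is Gaussian on its analysis
#' scale (natural log for flagged sway metrics) with the per-group mean
#' and SD from `params`; inter-metric dependence follows a Gaussian copula
#' (exchangeable `rho` or a supplied correlation matrix; independent by
#' default).  Prior-year fall counts are zero-inflated Poisson hitting the
#' configured per-group probability of falling and mean count; ages come
#' from a quantile-matched discrete distribution; dual-task counterparts
#' are `single * (1 + DTC/100)` with per-group Gaussian DTC (applied on
#' the natural scale for log-scale metrics).  The same seed and
#' configuration always reproduce the identical cohort.
#'
#' @param config A [cohort_config()].
#' @param params Group parameter table as from [isaw_group_params()]:
#'   columns `name`, `mean_nonfaller`, `sd_nonfaller`, `mean_faller`,
#'   `sd_faller`.
#' @param registry Metric registry as from [isaw_metrics()]; must cover
#'   every row of `params`.
#' @return A data frame (class `cohort` first) with columns `id`, `age`,
#'   `prior_falls`, `future_faller` (0/1, NA when indeterminate), one
#'   column per metric (analysis scale), and `<metric>_dt` columns for
#'   metrics with dual-task parameters.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_nonfallers = 20, n_fallers = 15,
#'                                      seed = 7))
#' table(coh$future_faller)
generate_cohort <- function(config = cohort_config(),
                            params = isaw_group_params(),
                            registry = isaw_metrics()) {
  stopifnot(inherits(config, "cohort_config"))
  registry <- as_registry(registry)
  missing_par <- setdiff(registry$name, params$name)
  if (length(missing_par)) {
    stop("params missing metrics: ", paste(missing_par, collapse = ", "))
  }
  params <- params[match(registry$name, params$name), ]
  p <- nrow(registry)
  n <- config$n_nonfallers + config$n_fallers
  group <- rep(c("nonfaller", "faller"),
               c(config$n_nonfallers, config$n_fallers))

  cols <- list(
    id = sprintf("P%04d", seq_len(n)),
    age = integer(0),
    prior_falls = integer(0),
    future_faller = integer(0)
  )
  if (n == 0) {
    out <- data.frame(id = character(0), age = integer(0),
                      prior_falls = integer(0), future_faller = integer(0),
                      stringsAsFactors = FALSE)
    for (m in registry$name) out[[m]] <- numeric(0)
    for (m in config$dtc_params$name) out[[paste0(m, "_dt")]] <- numeric(0)
    class(out) <- c("cohort", class(out))
    return(out)
  }

  cols$future_faller <- as.integer(group == "faller")
  cols$age <- integer(n)
  cols$prior_falls <- integer(n)
  for (g in c("nonfaller", "faller")) {
    idx <- which(group == g)
    if (!length(idx)) next
    cols$age[idx] <- sample_ages(
      length(idx), config$age_params[[g]],
      config$age_params$min, config$age_params$max,
      stream_seed(config$seed, paste0("age_", g)))
    cols$prior_falls[idx] <- generate_prior_falls(
      g, config, stream_seed(config$seed, paste0("falls_", g)),
      n = length(idx))
  }

  # Gaussian copula draw for the metric block
  R <- if (is.matrix(config$correlation)) {
    config$correlation
  } else {
    matrix(config$correlation, p, p) + diag(1 - config$correlation, p)
  }
  if (nrow(R) != p) stop("correlation matrix dimension != number of metrics")
  L <- chol(R)
  Z <- with_seed(stream_seed(config$seed, "metrics"),
                 matrix(stats::rnorm(n * p), n, p)) %*% L
  X <- matrix(NA_real_, n, p, dimnames = list(NULL, registry$name))
  for (j in seq_len(p)) {
    mu <- ifelse(group == "faller", params$mean_faller[j],
                 params$mean_nonfaller[j])
    sd <- ifelse(group == "faller", params$sd_faller[j],
                 params$sd_nonfaller[j])
    X[, j] <- mu + sd * Z[, j]
  }

  out <- data.frame(id = cols$id, age = cols$age,
                    prior_falls = cols$prior_falls,
                    future_faller = cols$future_faller,
                    stringsAsFactors = FALSE)
  for (m in registry$name) out[[m]] <- X[, m]

  # dual-task counterparts: dual = single * (1 + DTC/100) on the natural
  # scale; log-scale metrics are exponentiated first and re-logged
  dtc <- config$dtc_params
  if (!is.null(dtc) && nrow(dtc)) {
    E <- with_seed(stream_seed(config$seed, "dtc"),
                   matrix(stats::rnorm(n * nrow(dtc)), n, nrow(dtc)))
    for (j in seq_len(nrow(dtc))) {
      m <- dtc$name[j]
      if (!m %in% registry$name) {
        stop("dtc_params metric not in registry: ", m)
      }
      mu <- ifelse(group == "faller", dtc$mean_faller[j], dtc$mean_nonfaller[j])
      sd <- ifelse(group == "faller", dtc$sd_faller[j], dtc$sd_nonfaller[j])
      cost <- pmax(mu + sd * E[, j], -99.9)
      on_log <- registry$log_scale[registry$name == m]
      single_nat <- if (on_log) exp(out[[m]]) else out[[m]]
      dual_nat <- single_nat * (1 + cost / 100)
      out[[paste0(m, "_dt")]] <- if (on_log) log(dual_nat) else dual_nat
    }
  }

  if (config$missingness_rate > 0) {
    out <- apply_missingness(out, config$missingness_rate,
                             stream_seed(config$seed, "missing"))
  }
  class(out) <- c("cohort", class(out))
  out
}

#' Mark a random subset of prospective fall statuses as indeterminate
#'
#' Emulates losses to follow-up (unreturned or incomplete fall-report
#' postcards): each record's `future_faller` is independently set to `NA`
#' with probability `rate`.
#'
#' @param cohort A cohort data frame.
#' @param rate Probability in \[0, 1\].
#' @param seed Integer seed.
#' @return The cohort with some `future_faller` values set `NA`.
#' @export
apply_missingness <- function(cohort, rate, seed) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  n <- nrow(cohort)
  if (n == 0 || rate == 0) return(cohort)
  drop <- with_seed(seed, stats::runif(n)) < rate
  cohort$future_faller[drop] <- NA_integer_
  cohort
}
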