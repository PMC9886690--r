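#' Enumerate all subsets of a metric registry
#'
#' The model space of the all-subsets analysis: every subset of the
#' candidate metrics, including the empty set, in a fixed deterministic
#' order (binary counting: subset `m`, for `m = 0, ..., 2^p - 1`, contains
#' metric `j` when bit `j - 1` of `m` is set).  With the 17-metric ISAW
#' registry this is 131,072 candidate models.
#'
#' @param metrics Character vector of metric names, or a registry data
#'   frame with a `name` column.
#' @param max_size Optional cap on subset cardinality; larger subsets are
#'   dropped, order otherwise preserved.
#' @return Logical membership matrix (subsets x metrics) with the metric
#'   names as column names.
#' @export
#' @examples
#' nrow(enumerate_subsets(c("a", "b", "c")))  # 8
enumerate_subsets <- function(metrics, max_size = NULL) {
  if (is.data.frame(metrics)) metrics <- metrics$name
  stopifnot(is.character(metrics), !anyDuplicated(metrics))
  p <- length(metrics)
  if (p > 25) stop("refusing to enumerate 2^", p, " subsets")
  m <- seq_len(2^p) - 1L
  members <- vapply(seq_len(p),
                    function(j) bitwAnd(m, bitwShiftL(1L, j - 1L)) > 0L,
                    logical(length(m)))
  members <- matrix(members, nrow = length(m), ncol = p,
                    dimnames = list(NULL, metrics))
  if (!is.null(max_size)) {
    members <- members[rowSums(members) <= max_size, , drop = FALSE]
  }
  members
}

# Core logistic MLE on a design matrix that already carries its intercept.
# IRLS via stats::glm.fit at tight tolerance; flags quasi-separation by
# fitted probabilities at the boundary together with diverging
# coefficients.
logistic_mle <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  )
  mu <- fit$fitted.values
  loglik <- sum(stats::dbinom(y, 1, mu, log = TRUE))
  separated <- (any(mu < 1e-8) || any(mu > 1 - 1e-8)) &&
    max(abs(fit$coefficients)) > 15
  list(coefficients = fit$coefficients,
       fitted = mu,
       loglik = loglik,
       converged = fit$converged && !fit$boundary && !separated,
       separated = separated)
}

#' Fit a single logistic regression model
#'
#' Maximum-likelihood logistic regression of a binary outcome on a
#' (possibly empty) predictor matrix, with intercept.  Reports the
#' maximised log-likelihood and BIC, and flags quasi-complete separation.
#'
#' @param outcome 0/1 vector with both classes present.
#' @param predictors Numeric matrix (or NULL for the intercept-only
#'   model); columns are predictors.
#' @return Object of class `model_fit`: list with `coefficients`,
#'   `fitted`, `loglik`, `bic`, `k`, `n`, `converged`, `separated`,
#'   `subset` (predictor names).
#' @export
fit_logistic <- function(outcome, predictors = NULL) {
  y <- as.numeric(outcome)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("outcome must be 0/1 with no NA")
  if (length(unique(y)) < 2) stop("outcome has a single class; cannot fit")
  if (is.null(predictors)) {
    predictors <- matrix(numeric(0), nrow = length(y), ncol = 0)
  }
  predictors <- as.matrix(predictors)
  if (!all(is.finite(predictors))) stop("predictors must be finite")
  if (is.null(colnames(predictors)) && ncol(predictors) > 0) {
    colnames(predictors) <- paste0("x", seq_len(ncol(predictors)))
  }
  X <- cbind(`(Intercept)` = 1, predictors)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop("design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  ml <- logistic_mle(X, y)
  k <- ncol(X)
  n <- length(y)
  structure(
    list(coefficients = stats::setNames(ml$coefficients, colnames(X)),
         fitted = ml$fitted,
         loglik = ml$loglik,
         bic = bic(ml$loglik, k, n),
         k = k, n = n,
         converged = ml$converged,
         separated = ml$separated,
         subset = colnames(predictors)),
    class = "model_fit"
  )
}

#' Bayesian Information Criterion
#'
#' `k * ln(n) - 2 * loglik`; lower is better.  `k` counts every estimated
#' coefficient including the intercept; `n` is the number of
#' participants, held constant across the model space so that BIC
#' differences (and hence model weights) are well defined.
#'
#' @param loglik Maximised log-likelihood (nats).
#' @param k Number of estimated coefficients.
#' @param n Sample size.
#' @return The BIC value.
#' @export
bic <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 1)
  k * log(n) - 2 * loglik
}

#' BIC model weights
#'
#' Posterior model probabilities under a uniform model prior and the BIC
#' approximation to the marginal likelihood:
#' `w_m` proportional to `exp(-(BIC_m - min BIC) / 2)`, normalised to sum
#' to one.  The minimum is subtracted before exponentiating for overflow
#' safety; models with infinite BIC get weight exactly zero.
#'
#' @param bics Numeric vector of BIC values (may contain `Inf` for
#'   excluded models).
#' @return Normalised weights summing to 1.
#' @export
bma_weights <- function(bics) {
  finite <- is.finite(bics)
  if (!any(finite)) stop("all BIC values are infinite; no models to weight")
  w <- numeric(length(bics))
  w[finite] <- exp(-(bics[finite] - min(bics[finite])) / 2)
  w / sum(w)
}

#' Exhaustive all-subsets Bayesian model averaging
#'
#' Fits a logistic regression of prospective faller status on every
#' subset of the registry metrics (optionally forcing age and prior-year
#' fall count into every model), converts BICs to model weights, and
#' aggregates: per-metric posterior inclusion probabilities (PIP, the
#' total weight of models containing the metric), model-averaged
#' coefficients (unconditional, i.e. zero contribution from models that
#' exclude the predictor; the conditional average is also reported), and
#' model-averaged per-participant risk (the weight-mixed predicted
#' probability across models).
#'
#' Non-converged or quasi-separated fits are excluded from the average
#' and the weights renormalised, with a warning giving the count.
#'
#' @param cohort Cohort data frame with determinate `future_faller` for
#'   every row and metric columns on the analysis scale.
#' @param registry Metric registry naming the candidate predictors.
#' @param include_history_age Force `age` and `prior_falls` into every
#'   model as base covariates.
#' @param max_size Optional cap on subset cardinality.
#' @param scenario Free-text tag stored with the result.
#' @return Object of class `bma`; see Details.  Key fields: `weights`,
#'   `pip`, `avg_coef`, `avg_coef_conditional`, `avg_risk`,
#'   `avg_risk_from_avg_coef`, `bic`, `loglik`, `k`, `converged`,
#'   `members`, `coef`, `design`, `y`, `n_nonconverged`.
#' @export
run_bma <- function(cohort, registry = isaw_metrics(),
                    include_history_age = FALSE, max_size = NULL,
                    scenario = NULL) {
  registry <- as_registry(registry)
  y <- as.numeric(cohort$future_faller)
  if (anyNA(y)) {
    stop("cohort contains indeterminate fall status; apply analysis_subset() first")
  }
  if (length(unique(y)) < 2) stop("outcome has a single class; cannot fit")
  missing_m <- setdiff(registry$name, names(cohort))
  if (length(missing_m)) {
    stop("cohort is missing metric column(s): ",
         paste(missing_m, collapse = ", "))
  }
  n <- length(y)
  Xm <- as.matrix(cohort[registry$name])
  base <- if (include_history_age) {
    cbind(age = cohort$age, prior_falls = cohort$prior_falls)
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }
  design <- cbind(`(Intercept)` = 1, base, Xm)
  qr_X <- qr(design)
  if (qr_X$rank < ncol(design)) {
    dropped <- colnames(design)[qr_X$pivot[(qr_X$rank + 1):ncol(design)]]
    stop("full design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  members <- enumerate_subsets(registry$name, max_size)
  M <- nrow(members)
  p_base <- ncol(base)
  base_idx <- seq_len(1 + p_base)            # intercept + forced covariates
  metric_col <- 1 + p_base + seq_len(ncol(Xm))

  coefs <- matrix(0, M, ncol(design), dimnames = list(NULL, colnames(design)))
  loglik <- numeric(M)
  conv <- logical(M)
  for (m in seq_len(M)) {
    idx <- c(base_idx, metric_col[members[m, ]])
    ml <- logistic_mle(design[, idx, drop = FALSE], y)
    coefs[m, idx] <- ml$coefficients
    loglik[m] <- ml$loglik
    conv[m] <- ml$converged
  }
  k <- 1 + p_base + rowSums(members)
  bics <- bic(loglik, k, n)

  n_nonconverged <- sum(!conv)
  if (n_nonconverged > 0) {
    warning(n_nonconverged,
            " model(s) failed to converge and were excluded from the average")
  }
  bics_w <- ifelse(conv, bics, Inf)
  weights <- bma_weights(bics_w)

  pip <- as.numeric(crossprod(members, weights))
  names(pip) <- colnames(members)
  avg_coef <- as.numeric(crossprod(coefs, weights))
  names(avg_coef) <- colnames(design)
  incl_prob <- c(rep(1, 1 + p_base), pip)    # intercept & forced covariates
  avg_coef_conditional <- ifelse(incl_prob > 0, avg_coef / incl_prob, 0)
  names(avg_coef_conditional) <- colnames(design)

  # model-averaged risk, accumulated over model chunks to bound memory
  avg_risk <- numeric(n)
  chunk <- 4096L
  for (s in seq(1, M, by = chunk)) {
    e <- min(s + chunk - 1L, M)
    idx <- s:e
    if (all(weights[idx] == 0)) next
    eta <- design %*% t(coefs[idx, , drop = FALSE])
    avg_risk <- avg_risk + as.numeric(stats::plogis(eta) %*% weights[idx])
  }

  structure(
    list(weights = weights, pip = pip,
         avg_coef = avg_coef, avg_coef_conditional = avg_coef_conditional,
         avg_risk = avg_risk,
         avg_risk_from_avg_coef = as.numeric(stats::plogis(design %*% avg_coef)),
         bic = bics, loglik = loglik, k = k, converged = conv,
         members = members, coef = coefs, design = design, y = y,
         n = n, base_covariates = colnames(base),
         n_nonconverged = n_nonconverged,
         scenario = scenario),
    class = "bma"
  )
}

#' @export
print.bma <- function(x, ...) {
  cat("BIC-weighted Bayesian model average",
      if (!is.null(x$scenario)) paste0(" [", x$scenario, "]"), "\n", sep = "")
  cat(sprintf("  %d models over %d metrics, n = %d (%d events)\n",
              length(x$weights), ncol(x$members), x$n, sum(x$y)))
  if (length(x$base_covariates)) {
    cat("  forced covariates:", paste(x$base_covariates, collapse = ", "), "\n")
  }
  cat("  top posterior inclusion probabilities:\n")
  top <- sort(x$pip, decreasing = TRUE)[seq_len(min(5, length(x$pip)))]
  for (nm in names(top)) cat(sprintf("    %-22s %.3f\n", nm, top[[nm]]))
  invisible(x)
}

#' Rank fitted models by BIC
#'
#' @param bma A [run_bma()] result.
#' @param count Number of models to return.
#' @param n_metrics Optional filter to models with exactly this many
#'   metrics.
#' @return Data frame ordered by ascending BIC (ties broken by
#'   lexicographic subset order): `model_id` (row index into the bma
#'   object), `subset`, `n_metrics`, `bic`, `delta_bic`, `weight`.
#' @export
top_models <- function(bma, count = 100, n_metrics = NULL) {
  keep <- seq_along(bma$bic)
  if (!is.null(n_metrics)) {
    keep <- keep[rowSums(bma$members[keep, , drop = FALSE]) == n_metrics]
  }
  subset_str <- apply(bma$members[keep, , drop = FALSE], 1, function(r) {
    paste(colnames(bma$members)[r], collapse = "+")
  })
  ord <- order(bma$bic[keep], subset_str)
  if (count > length(keep)) {
    warning("only ", length(keep), " models available; returning all")
    count <- length(keep)
  }
  sel <- keep[ord][seq_len(count)]
  data.frame(
    model_id = sel,
    subset = vapply(sel, function(i) {
      paste(colnames(bma$members)[bma$members[i, ]], collapse = "+")
    }, character(1)),
    n_metrics = rowSums(bma$members[sel, , drop = FALSE]),
    bic = bma$bic[sel],
    delta_bic = bma$bic[sel] - min(bma$bic[bma$converged]),
    weight = bma$weights[sel],
    stringsAsFactors = FALSE
  )
}
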