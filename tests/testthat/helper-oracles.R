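# Independent reference implementations used as oracles.  These
# deliberately take different routes from the package code: formula-based
# glm + combn enumeration for the model average, and literal pair
# enumeration for the AUC.

# Brute-force all-subsets BIC-weighted model average.
brute_bma <- function(cohort, metrics, include_history_age = FALSE) {
  y <- cohort$future_faller
  n <- length(y)
  subsets <- list(character(0))
  for (k in seq_along(metrics)) {
    subsets <- c(subsets, utils::combn(metrics, k, simplify = FALSE))
  }
  fits <- lapply(subsets, function(s) {
    rhs <- c(if (include_history_age) c("age", "prior_falls"), s)
    f <- if (length(rhs)) stats::reformulate(rhs, "future_faller")
         else future_faller ~ 1
    fit <- stats::glm(f, stats::binomial(), data = cohort,
                      control = stats::glm.control(epsilon = 1e-12,
                                                   maxit = 200))
    ll <- as.numeric(stats::logLik(fit))
    list(subset = s, coef = stats::coef(fit), ll = ll,
         bic = length(stats::coef(fit)) * log(n) - 2 * ll,
         fitted = stats::fitted(fit))
  })
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  w <- exp(-(bics - min(bics)) / 2)
  w <- w / sum(w)
  pip <- vapply(metrics, function(m) {
    sum(w[vapply(fits, function(f) m %in% f$subset, logical(1))])
  }, numeric(1))
  coef_names <- c("(Intercept)",
                  if (include_history_age) c("age", "prior_falls"), metrics)
  avg_coef <- stats::setNames(numeric(length(coef_names)), coef_names)
  risk <- numeric(n)
  for (i in seq_along(fits)) {
    cf <- fits[[i]]$coef
    avg_coef[names(cf)] <- avg_coef[names(cf)] + w[i] * cf
    risk <- risk + w[i] * fits[[i]]$fitted
  }
  key <- vapply(subsets, function(s) {
    if (length(s)) paste(sort(s), collapse = "+") else "(none)"
  }, character(1))
  list(weights = stats::setNames(w, key), pip = pip, avg_coef = avg_coef,
       avg_risk = unname(risk), bic = stats::setNames(bics, key))
}

# Subset key for a package bma object, aligned with brute_bma's keys.
bma_subset_keys <- function(bma) {
  apply(bma$members, 1, function(r) {
    if (any(r)) paste(sort(colnames(bma$members)[r]), collapse = "+")
    else "(none)"
  })
}

# AUC by literal enumeration of all (positive, negative) pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Small two-group cohort with configurable group separation on a few
# named metrics; all other structure minimal.
toy_cohort <- function(n0, n1, metrics, shift = numeric(length(metrics)),
                       seed = 1) {
  set.seed(seed)
  n <- n0 + n1
  y <- rep(c(0L, 1L), c(n0, n1))
  out <- data.frame(id = sprintf("T%03d", seq_len(n)),
                    age = sample(78:96, n, replace = TRUE),
                    prior_falls = stats::rpois(n, 0.5 + 0.5 * y),
                    future_faller = y)
  for (j in seq_along(metrics)) {
    out[[metrics[j]]] <- stats::rnorm(n) + shift[j] * y
  }
  out
}
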