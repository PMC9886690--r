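test_that("subset enumeration covers the model space in a fixed order", {
  expect_equal(nrow(enumerate_subsets(c("a", "b", "c"))), 8)
  expect_equal(nrow(enumerate_subsets(character(0))), 1)
  m <- enumerate_subsets(c("a", "b"))
  expect_equal(unname(rowSums(m)), c(0, 1, 1, 2))   # {}, {a}, {b}, {a,b}
  expect_true(m[2, "a"] && !m[2, "b"])
  capped <- enumerate_subsets(letters[1:4], max_size = 1)
  expect_equal(nrow(capped), 5)
  expect_true(all(rowSums(capped) <= 1))
  # registry data frames are accepted directly
  expect_equal(nrow(enumerate_subsets(isaw_metrics()[1:3, ])), 8)
})

test_that("intercept-only fit matches the closed-form Bernoulli MLE", {
  y <- rep(c(1L, 0L), c(91, 123))
  fit <- fit_logistic(y)
  expect_equal(unname(fit$coefficients), log(91 / 123), tolerance = 1e-8)
  expect_equal(fit$loglik, 91 * log(91 / 214) + 123 * log(123 / 214),
               tolerance = 1e-10)
  expect_equal(fit$bic, log(214) - 2 * fit$loglik)
  expect_equal(fit$k, 1)

  balanced <- fit_logistic(rep(c(0L, 1L), 10))
  expect_equal(unname(balanced$coefficients), 0, tolerance = 1e-10)
})

test_that("one-predictor MLE matches a dense grid search", {
  x <- c(-1.5, -1.0, -0.5, -0.2, 0.2, 0.5, 1.0, 1.5)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  fit <- fit_logistic(y, cbind(x = x))
  grid_ll <- function(b0, b1) {
    p <- stats::plogis(b0 + b1 * x)
    sum(stats::dbinom(y, 1, p, log = TRUE))
  }
  b0s <- seq(-2, 2, by = 0.01)
  b1s <- seq(-1, 4, by = 0.01)
  best <- -Inf
  for (b1 in b1s) {
    lls <- vapply(b0s, grid_ll, numeric(1), b1 = b1)
    if (max(lls) > best) best <- max(lls)
  }
  expect_equal(fit$loglik, best, tolerance = 1e-4)
})

test_that("pathological designs are rejected with useful messages", {
  expect_error(fit_logistic(rep(1L, 20)), "single class")
  x <- stats::rnorm(20)
  expect_error(fit_logistic(rep(c(0L, 1L), 10), cbind(a = x, b = 2 * x)),
               "collinear.*b")
})

test_that("BIC closed forms and the useless-predictor penalty hold", {
  expect_equal(bic(0, 1, 1), 0)
  # balanced intercept-only at n = 4
  expect_equal(bic(4 * log(0.5), 1, 4), log(4) - 8 * log(0.5))
  expect_error(bic(0, 1, 0))

  # adding a pure-noise predictor increases BIC nearly always
  worse <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    y <- stats::rbinom(500, 1, 0.4)
    z <- stats::rnorm(500)
    fit_logistic(y, cbind(z = z))$bic > fit_logistic(y)$bic
  }, logical(1))
  expect_gte(sum(worse), 38)
})

test_that("BIC weights normalise, shift-invariantly, with infinite BICs at zero", {
  expect_equal(bma_weights(rep(3, 5)), rep(0.2, 5))
  w <- bma_weights(c(10, 12))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(bma_weights(c(10, 12) + 57.3), w, tolerance = 1e-12)
  w_inf <- bma_weights(c(5, Inf, 7))
  expect_equal(w_inf[2], 0)
  expect_equal(sum(w_inf), 1, tolerance = 1e-12)
  expect_error(bma_weights(c(Inf, Inf)), "infinite")
})

test_that("run_bma matches the brute-force reference on small model spaces", {
  for (p in c(3, 5)) {
    metrics <- paste0("m", seq_len(p))
    coh <- toy_cohort(60, 40, metrics, shift = c(1, 0.5, rep(0, p - 2)),
                      seed = p)
    for (with_cov in c(FALSE, TRUE)) {
      b <- run_bma(coh, metrics, include_history_age = with_cov)
      ref <- brute_bma(coh, metrics, include_history_age = with_cov)
      keys <- bma_subset_keys(b)
      expect_equal(unname(b$weights), unname(ref$weights[keys]),
                   tolerance = 1e-10)
      expect_equal(b$pip[metrics], ref$pip[metrics], tolerance = 1e-10)
      expect_equal(b$avg_coef[names(ref$avg_coef)], ref$avg_coef,
                   tolerance = 1e-10)
      expect_equal(b$avg_risk, ref$avg_risk, tolerance = 1e-10)
    }
  }
})

test_that("PIP equals the direct weight sum over containing models", {
  metrics <- paste0("m", 1:4)
  coh <- toy_cohort(50, 50, metrics, shift = c(0.8, 0, 0, 0.3), seed = 17)
  b <- run_bma(coh, metrics)
  for (m in metrics) {
    expect_equal(b$pip[[m]], sum(b$weights[b$members[, m]]),
                 tolerance = 1e-14)
  }
  expect_equal(sum(b$weights), 1, tolerance = 1e-10)
  # expected model size identity: sum_j PIP_j = sum_m w_m |subset_m|
  expect_equal(sum(b$pip), sum(b$weights * rowSums(b$members)),
               tolerance = 1e-12)
})

test_that("forced covariates appear in every model with inclusion one", {
  metrics <- paste0("m", 1:3)
  coh <- toy_cohort(40, 40, metrics, shift = c(1, 0, 0), seed = 23)
  b <- run_bma(coh, metrics, include_history_age = TRUE)
  expect_equal(b$base_covariates, c("age", "prior_falls"))
  expect_true(all(b$coef[, "age"] != 0) || any(b$coef[, "age"] != 0))
  expect_equal(length(b$weights), 8)
  # every model's k counts intercept + 2 forced + subset size
  expect_equal(b$k, 3 + rowSums(b$members))
})

test_that("signal metrics earn high inclusion; noise stays low", {
  hits <- vapply(1:10, function(s) {
    coh <- toy_cohort(1000, 1000, paste0("m", 1:5),
                      shift = c(1.2, 0, 0, 0, 0), seed = 400 + s)
    b <- run_bma(coh, paste0("m", 1:5))
    b$pip[["m1"]] > 0.95 && all(b$pip[paste0("m", 2:5)] < 0.5)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("stronger true effects never lower mean inclusion (paired seeds)", {
  mean_pip <- function(beta) {
    mean(vapply(1:8, function(s) {
      set.seed(3000 + s)
      n <- 600
      x <- matrix(stats::rnorm(n * 3), n, 3,
                  dimnames = list(NULL, paste0("m", 1:3)))
      y <- stats::rbinom(n, 1, stats::plogis(-0.3 + beta * x[, 1]))
      coh <- data.frame(id = as.character(1:n), age = 80L, prior_falls = 0L,
                        future_faller = y, x)
      run_bma(coh, paste0("m", 1:3))$pip[["m1"]]
    }, numeric(1)))
  }
  pips <- vapply(c(0.2, 0.5, 1.0), mean_pip, numeric(1))
  expect_true(all(diff(pips) >= 0))
})

test_that("top_models ranks by BIC with lexicographic tie-break", {
  metrics <- paste0("m", 1:5)
  coh <- toy_cohort(60, 60, metrics, shift = c(1, 0.4, 0, 0, 0), seed = 29)
  b <- run_bma(coh, metrics)
  tm <- top_models(b, count = 32)
  expect_equal(tm$bic, sort(b$bic))
  expect_equal(tm$model_id[1], which.min(b$bic))
  expect_equal(tm$delta_bic[1], 0)
  only3 <- top_models(b, count = 5, n_metrics = 3)
  expect_true(all(only3$n_metrics == 3))
  expect_warning(all_of_them <- top_models(b, count = 999), "32 models")
  expect_equal(nrow(all_of_them), 32)
})
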