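test_that("summary-statistic t-test reproduces the published anchor rows", {
  # sway velocity (log m/s) and gait speed (m/s), 123 non-fallers vs 91
  # fallers
  sway <- student_t_pvalue(-2.085, 0.595, 123, -1.888, 0.566, 91)
  expect_equal(round(sway$p, 3), 0.015)
  speed <- student_t_pvalue(1.064, 0.176, 123, 1.000, 0.187, 91)
  expect_equal(round(speed$p, 3), 0.011)
  expect_gt(sway$t, 0)   # fallers sway faster
  expect_lt(speed$t, 0)  # fallers walk slower
  expect_equal(sway$df, 212)
})

test_that("t statistic flips sign under group exchange; p is invariant", {
  a <- student_t_pvalue(1.2, 0.4, 30, 0.9, 0.5, 25)
  b <- student_t_pvalue(0.9, 0.5, 25, 1.2, 0.4, 30)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
})

test_that("p decreases monotonically in the mean difference", {
  deltas <- seq(0, 1, by = 0.1)
  ps <- vapply(deltas, function(d) {
    student_t_pvalue(0, 1, 40, d, 1, 40)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_equal(ps[1], 1)
})

test_that("degenerate zero-variance inputs follow the documented conventions", {
  same <- student_t_pvalue(2, 0, 10, 2, 0, 10)
  expect_equal(same$p, 1)
  expect_warning(diff <- student_t_pvalue(1, 0, 10, 2, 0, 10), "convention")
  expect_equal(diff$p, 0)
})

test_that("welch variant agrees with stats::t.test on raw data", {
  set.seed(42)
  x <- stats::rnorm(35, 0, 1)
  y <- stats::rnorm(20, 0.5, 2)
  ours_w <- student_t_pvalue(mean(x), stats::sd(x), 35,
                             mean(y), stats::sd(y), 20, welch = TRUE)
  ref_w <- stats::t.test(y, x)
  expect_equal(ours_w$p, ref_w$p.value, tolerance = 1e-12)
  expect_equal(ours_w$df, unname(ref_w$parameter), tolerance = 1e-10)
  ours_p <- student_t_pvalue(mean(x), stats::sd(x), 35,
                             mean(y), stats::sd(y), 20)
  ref_p <- stats::t.test(y, x, var.equal = TRUE)
  expect_equal(ours_p$p, ref_p$p.value, tolerance = 1e-12)
})

test_that("group_summary recovers generator parameters at scale", {
  coh <- generate_cohort(cohort_config(n_nonfallers = 10000,
                                       n_fallers = 10000, seed = 31))
  gs <- group_summary(coh)
  par <- isaw_group_params()
  # CLT bound on each group mean, 5 SE to keep the joint test stable
  for (j in seq_len(nrow(par))) {
    i <- which(gs$name == par$name[j])
    expect_lt(abs(gs$mean_faller[i] - par$mean_faller[j]),
              5 * par$sd_faller[j] / sqrt(10000))
    expect_lt(abs(gs$mean_nonfaller[i] - par$mean_nonfaller[j]),
              5 * par$sd_nonfaller[j] / sqrt(10000))
  }
})

test_that("group_summary handles degenerate cohorts", {
  coh <- data.frame(id = as.character(1:4), age = 80, prior_falls = 0,
                    future_faller = c(0L, 0L, 1L, 1L),
                    m1 = c(1, 1, 2, 2), m2 = c(3, 3, 3, 3))
  expect_warning(gs <- group_summary(coh, registry = c("m1", "m2")),
                 "convention")
  expect_equal(gs$sd_nonfaller, c(0, 0))
  expect_equal(gs$mean_faller, c(2, 3))
  expect_equal(gs$p[gs$name == "m2"], 1)  # constant metric
  expect_equal(gs$p[gs$name == "m1"], 0)  # perfectly separated means

  onesided <- coh[coh$future_faller == 1, ]
  expect_error(group_summary(onesided, registry = c("m1", "m2")),
               "non-fallers")
})

test_that("fall-status crosstab reproduces the published conditionals", {
  # the unique 2x2 table with margins 134/80 (prior) x 123/91 (future)
  # whose prior-faller row repeats at 60.0%
  coh <- data.frame(
    id = as.character(1:214), age = 83,
    prior_falls = rep(c(0L, 0L, 1L, 1L), c(91, 43, 32, 48)),
    future_faller = rep(c(0L, 1L, 0L, 1L), c(91, 43, 32, 48))
  )
  ct <- fall_status_crosstab(coh)
  expect_equal(as.vector(ct$counts), c(91, 32, 43, 48))
  expect_equal(round(ct$row_pct["prior_nonfaller", "future_nonfaller"], 1),
               67.9)
  expect_equal(round(ct$row_pct["prior_faller", "future_faller"], 1), 60.0)
  # margins conserved
  expect_equal(rowSums(ct$counts), c(prior_nonfaller = 134, prior_faller = 80))
  expect_equal(colSums(ct$counts),
               c(future_nonfaller = 123, future_faller = 91))
  # row-margin-weighted conditionals recompose the overall rate exactly
  overall <- sum(ct$row_pct[, "future_faller"] * rowSums(ct$counts)) /
    sum(ct$counts)
  expect_equal(overall, 100 * mean(coh$future_faller))
})

test_that("single-status crosstab degenerates gracefully", {
  coh <- data.frame(id = as.character(1:10), age = 80, prior_falls = 0L,
                    future_faller = 0L)
  ct <- fall_status_crosstab(coh)
  expect_equal(ct$counts["prior_nonfaller", "future_nonfaller"], 10)
  expect_equal(ct$row_pct["prior_nonfaller", "future_nonfaller"], 100)
  expect_true(all(is.na(ct$row_pct["prior_faller", ])))
})

test_that("dual-task cost follows the signed formula and round-trips", {
  expect_equal(dual_task_cost(1.0, 1.0), 0)
  expect_equal(dual_task_cost(1.0, 0.8), -20)
  expect_equal(dual_task_cost(160, 180), 12.5)
  expect_error(dual_task_cost(0, 1), "undefined")
  # inversion property: cost of single * (1 + c/100) is c
  set.seed(7)
  x <- stats::runif(50, 0.5, 3)
  cc <- stats::runif(50, -50, 50)
  expect_equal(dual_task_cost(x, x * (1 + cc / 100)), cc, tolerance = 1e-12)
})
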