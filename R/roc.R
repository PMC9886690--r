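#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)`: the probability a randomly
#' chosen positive (faller) outscores a randomly chosen negative, with
#' ties credited one half.  Computed from midranks, so it is exact and
#' O(n log n).
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 outcome labels.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both outcome classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve of a risk score
#'
#' Thresholds the score at every unique value, yielding the staircase of
#' (false positive rate, true positive rate) points from (0, 0) to
#' (1, 1).  The trapezoidal area under these points equals the
#' Mann-Whitney AUC (ties are traversed diagonally, matching the
#' half-tie convention).
#'
#' @inheritParams auc
#' @return Object of class `roc_result`: list with `points` (data frame
#'   `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both outcome classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  tp <- cumsum(y[ord] == 1)
  fp <- cumsum(y[ord] == 0)
  last_of_tie <- !duplicated(s, fromLast = TRUE)
  pts <- data.frame(fpr = c(0, fp[last_of_tie] / n_neg),
                    tpr = c(0, tp[last_of_tie] / n_pos))
  structure(list(points = pts, auc = auc(scores, labels),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.3f (%d pos / %d neg)\n",
              nrow(x$points), x$auc, x$n_pos, x$n_neg))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI (%s): (%.3f, %.3f)\n",
                x$ci_method, x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Confidence interval for the AUC
#'
#' Default is a stratified nonparametric bootstrap (cases and controls
#' resampled separately, percentile interval, seeded and reproducible).
#' `method = "delong"` gives the DeLong closed-form normal interval based
#' on the placement-value variance.
#'
#' @inheritParams auc
#' @param method `"bootstrap"` or `"delong"`.
#' @param reps Bootstrap replicates (>= 100).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return List with `auc`, `ci` (length-2 vector), `ci_method`, `reps`.
#' @export
auc_ci <- function(scores, labels, method = c("bootstrap", "delong"),
                   reps = 2000, seed = 1L, conf = 0.95) {
  method <- match.arg(method)
  y <- as.numeric(labels)
  a <- auc(scores, y)
  if (length(unique(scores)) == 1) {
    warning("degenerate scores (all identical); interval [0.5, 0.5]")
    return(list(auc = a, ci = c(0.5, 0.5), ci_method = "degenerate",
                reps = 0L))
  }
  alpha <- 1 - conf
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  if (method == "delong") {
    # placement values: each case scored against the control distribution
    # and vice versa
    v10 <- vapply(pos, function(s) mean(neg < s) + 0.5 * mean(neg == s),
                  numeric(1))
    v01 <- vapply(neg, function(s) mean(pos > s) + 0.5 * mean(pos == s),
                  numeric(1))
    v <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
    z <- stats::qnorm(1 - alpha / 2)
    ci <- pmin(pmax(a + c(-1, 1) * z * sqrt(v), 0), 1)
    return(list(auc = a, ci = ci, ci_method = "delong", reps = 0L))
  }
  stopifnot(reps >= 100)
  boots <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      bp <- sample(pos, replace = TRUE)
      bn <- sample(neg, replace = TRUE)
      auc(c(bp, bn), rep(c(1, 0), c(length(bp), length(bn))))
    }, numeric(1))
  })
  ci <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2)))
  list(auc = a, ci = ci, ci_method = "stratified bootstrap", reps = reps)
}

#' AUC-versus-BIC model frontier
#'
#' For the best-fitting models of an all-subsets run, the trade-off
#' between discrimination (in-sample AUC of each model's fitted risk) and
#' fit (BIC difference from the best model; best is zero on this scale),
#' with models labelled by how many metrics they carry.  Summaries of
#' median and maximum AUC by metric count are attached as attribute
#' `"by_n_metrics"`.
#'
#' @param bma A [run_bma()] result.
#' @param top_count How many lowest-BIC models to keep (all, with a
#'   warning, if fewer exist).
#' @return Data frame `model_id`, `subset`, `n_metrics`, `delta_bic`,
#'   `auc`, ordered by ascending BIC.
#' @export
frontier <- function(bma, top_count = 100) {
  tm <- top_models(bma, count = top_count)
  aucs <- vapply(seq_len(nrow(tm)), function(i) {
    eta <- as.numeric(bma$design %*% bma$coef[tm$model_id[i], ])
    auc(stats::plogis(eta), bma$y)
  }, numeric(1))
  out <- data.frame(model_id = tm$model_id, subset = tm$subset,
                    n_metrics = tm$n_metrics, delta_bic = tm$delta_bic,
                    auc = aucs, stringsAsFactors = FALSE)
  by_k <- do.call(rbind, lapply(split(out, out$n_metrics), function(d) {
    data.frame(n_metrics = d$n_metrics[1], n_models = nrow(d),
               median_auc = stats::median(d$auc), max_auc = max(d$auc))
  }))
  rownames(by_k) <- NULL
  attr(out, "by_n_metrics") <- by_k
  out
}

#' Vertically averaged, monotone-smoothed ROC curve
#'
#' Interpolates each input curve's TPR on a fixed FPR grid (step 0.01),
#' averages across curves, then enforces monotonicity by isotonic
#' regression.  This is the package's stand-in for a smoothed average of
#' a family of ROC curves.
#'
#' @param roc_list List of [roc_curve()] results (at least one).
#' @param grid_step FPR grid spacing.
#' @return Object of class `roc_result` with the averaged `points` and
#'   trapezoidal `auc`.
#' @export
smoothed_roc_average <- function(roc_list, grid_step = 0.01) {
  if (length(roc_list) == 0) stop("need at least one ROC curve to average")
  grid <- seq(0, 1, by = grid_step)
  tprs <- vapply(roc_list, function(rc) {
    pts <- rc$points
    # at duplicated FPRs (vertical segments) keep the attained (max) TPR
    stats::approx(pts$fpr, pts$tpr, xout = grid, method = "linear",
                  ties = max, rule = 2)$y
  }, numeric(length(grid)))
  avg <- rowMeans(tprs)
  avg <- stats::isoreg(grid, avg)$yf
  avg <- pmin(pmax(avg, 0), 1)
  avg[1] <- 0
  avg[length(avg)] <- 1
  a <- sum(diff(grid) * (utils::head(avg, -1) + utils::tail(avg, -1)) / 2)
  structure(list(points = data.frame(fpr = grid, tpr = avg), auc = a,
                 n_pos = NA_integer_, n_neg = NA_integer_,
                 n_curves = length(roc_list)),
            class = "roc_result")
}
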