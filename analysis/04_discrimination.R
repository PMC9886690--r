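#!/usr/bin/env Rscript
# Discrimination of the model averages: ROC/AUC with bootstrap CIs for
# both averaging scenarios, the AUC-versus-delta-BIC frontier of the top
# 100 models, and the smoothed average ROC of the best 3-metric models.
# Uses the cached fits from 03_bma.R when present.

library(fallbma)

cohort <- analysis_subset(read_cohort("results/cohort.csv"))
fits <- if (file.exists("scratch/bma_fits.rds")) {
  readRDS("scratch/bma_fits.rds")
} else {
  list(isaw_only = run_bma(cohort, scenario = "isaw_only"),
       isaw_history_age = run_bma(cohort, include_history_age = TRUE,
                                  scenario = "isaw_history_age"))
}
y <- cohort$future_faller

summary_rows <- list()
for (tag in names(fits)) {
  b <- fits[[tag]]
  ci <- auc_ci(b$avg_risk, y, reps = 2000, seed = 1)
  cat(sprintf("%s: model-average AUC = %.3f (%.3f, %.3f)\n",
              tag, ci$auc, ci$ci[1], ci$ci[2]))
  summary_rows[[tag]] <- data.frame(scenario = tag, auc = ci$auc,
                                    ci_low = ci$ci[1], ci_high = ci$ci[2])
  fr <- frontier(b, top_count = 100)
  write.csv(fr, sprintf("results/frontier_%s.csv", tag), row.names = FALSE)
  cat("  median/max AUC by number of metrics (top 100 models):\n")
  print(attr(fr, "by_n_metrics"), row.names = FALSE)
}

# smoothed average ROC over the best 3-metric models (metrics-only space)
b <- fits$isaw_only
top3 <- top_models(b, count = 10, n_metrics = 3)
curves <- lapply(top3$model_id, function(i) {
  roc_curve(plogis(as.numeric(b$design %*% b$coef[i, ])), y)
})
sm <- smoothed_roc_average(curves)
cat(sprintf("smoothed average ROC of top 10 three-metric models: AUC = %.3f\n",
            sm$auc))
write.csv(sm$points, "results/smoothed_roc_3metric.csv", row.names = FALSE)

write.csv(do.call(rbind, summary_rows), "results/bma_auc_summary.csv",
          row.names = FALSE)
cat("wrote results/frontier_*.csv, results/smoothed_roc_3metric.csv,",
    "results/bma_auc_summary.csv\n")
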