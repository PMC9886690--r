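#!/usr/bin/env Rscript
# The statistical core: exhaustive 131,072-model logistic regression with
# BIC-weighted averaging, run twice (metrics alone; metrics + fall
# history + age).  Takes a few minutes.  Writes results/pip_table.csv and
# results/top_models.csv; caches the fitted objects under scratch/ for
# the downstream scripts.

library(fallbma)

cohort <- analysis_subset(read_cohort("results/cohort.csv"))

cat("fitting all subsets, metrics only ...\n")
bma_isaw <- run_bma(cohort, scenario = "isaw_only")
cat("fitting all subsets with fall history and age ...\n")
bma_cov <- run_bma(cohort, include_history_age = TRUE,
                   scenario = "isaw_history_age")

tab <- pip_table(bma_isaw, bma_cov)
write.csv(tab, "results/pip_table.csv", row.names = FALSE)
cat("\nposterior inclusion probabilities (flagged above 0.40):\n")
print(transform(tab, pip_isaw_only = round(pip_isaw_only, 3),
                pip_history_age = round(pip_history_age, 3)),
      row.names = FALSE)

top <- top_models(bma_cov, count = 20)
write.csv(top, "results/top_models.csv", row.names = FALSE)
cat("\nbest-fitting models (history + age scenario):\n")
print(transform(top[1:5, c("subset", "n_metrics", "delta_bic", "weight")],
                delta_bic = round(delta_bic, 2), weight = round(weight, 4)),
      row.names = FALSE)

dir.create("scratch", showWarnings = FALSE)
saveRDS(list(isaw_only = bma_isaw, isaw_history_age = bma_cov),
        "scratch/bma_fits.rds")
cat("wrote results/pip_table.csv, results/top_models.csv\n")
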