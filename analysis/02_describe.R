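#!/usr/bin/env Rscript
# Descriptive layer: per-metric group summaries with pooled t-tests, the
# prior-by-prospective fall-status cross-tabulation, and dual-task costs.
# Reads results/cohort.csv; writes results/group_summary.csv and
# results/fall_crosstab.json.

library(fallbma)

cohort <- analysis_subset(read_cohort("results/cohort.csv"))

gs <- group_summary(cohort)
write.csv(gs, "results/group_summary.csv", row.names = FALSE)
cat("metrics separating the groups at p < 0.05:\n")
print(gs[gs$p < 0.05, c("name", "domain", "t", "p")], row.names = FALSE)

ct <- fall_status_crosstab(cohort)
print(ct)
jsonlite::write_json(
  list(counts = ct$counts, row_pct = round(ct$row_pct, 1), n = ct$n),
  "results/fall_crosstab.json", matrix = "rowmajor", auto_unbox = TRUE)

y <- cohort$future_faller
for (m in c("gait_speed", "turn_velocity")) {
  d <- dual_task_cost(cohort[[m]], cohort[[paste0(m, "_dt")]])
  cat(sprintf("dual-task cost on %s: %.2f%% (non-fallers) / %.2f%% (fallers)\n",
              m, mean(d[y == 0]), mean(d[y == 1])))
}
cat("wrote results/group_summary.csv, results/fall_crosstab.json\n")
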