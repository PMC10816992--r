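#!/usr/bin/env Rscript

# Step 3 — diagnostic performance of each threshold.
#
# Each cutoff is evaluated as a screening rule (ratio <= cutoff =>
# plasmatic amyloid-positive) against the CSF/PET reference, on the full
# eligible labeled subset and on its non-demented part, reproducing the
# cross-tabulation layout of the published tables.

suppressPackageStartupMessages(library(abratio))

ann <- read_cohort("results/cohort_annotated.csv")
ann$eligible <- is_eligible(ann)
status <- call_amyloid(ann)$status
dementia <- has_dementia(ann)
thr <- read.csv("results/thresholds.csv")

lab <- ann$eligible & status != "unknown"
nd <- lab & !dementia
rows <- list()
for (i in seq_len(nrow(thr))) {
  for (sub in c("all_labeled", "non_demented")) {
    sel <- if (sub == "all_labeled") lab else nd
    perf <- diagnostic_performance(ann$ratio[sel], status[sel],
                                   thr$threshold[i])
    cat(sprintf("\n-- %s threshold %.4f, %s subset (n = %d)\n",
                thr$method[i], thr$threshold[i], sub, sum(sel)))
    print(perf)
    rows[[length(rows) + 1]] <- data.frame(
      method = thr$method[i], subset = sub, threshold = thr$threshold[i],
      n = perf$n, tp = perf$cm$tp, fn = perf$cm$fn, fp = perf$cm$fp,
      tn = perf$cm$tn, sensitivity = perf$sensitivity,
      specificity = perf$specificity, lr_pos = perf$lr_pos,
      lr_neg = perf$lr_neg)
  }
}
perf_tab <- do.call(rbind, rows)
write.csv(perf_tab, "results/performance.csv", row.names = FALSE)
cat("\nwrote results/performance.csv\n")
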