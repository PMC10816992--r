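#!/usr/bin/env Rscript

# Step 2 — derive the three positivity thresholds.
#
# Mixture cutoff: IQR outlier removal on the ratios of ALL participants
# (labeled or not), EM fit of a two-component unequal-variance Gaussian
# mixture, threshold at the crossing of the weighted component curves.
# Stump cutoff: depth-one Gini tree on the eligible labeled subset.
# Youden cutoff: maximises Sn + Sp - 1 on the eligible labeled subset
# without dementia, alongside the ROC AUC and its DeLong interval.

suppressPackageStartupMessages(library(abratio))

seed <- 1173
ann <- read_cohort("results/cohort_annotated.csv")
ann$eligible <- is_eligible(ann)
status <- call_amyloid(ann)$status
dementia <- has_dementia(ann)

out <- remove_outliers_iqr(ann$ratio)
cat(sprintf("IQR filter: %d of %d ratios removed (%.1f%%), fences [%.4f, %.4f]\n",
            length(out$removed), nrow(ann),
            100 * length(out$removed) / nrow(ann),
            out$fences[1], out$fences[2]))
fit <- fit_gmm_em(out$kept, seed = seed)
print(fit)
thr_gmm <- gaussian_intersection(fit)

lab <- ann$eligible & status != "unknown"
thr_stump <- fit_stump(ann$ratio[lab], status[lab])
nd <- lab & !dementia
roc <- roc_curve(ann$ratio[nd], status[nd])
ci <- auc_ci(ann$ratio[nd], status[nd], method = "delong")
thr_youden <- youden_threshold(roc)

cat(sprintf("mixture crossing: %.4f | stump: %.4f | Youden: %.4f\n",
            thr_gmm$value, thr_stump$value, thr_youden$value))
cat(sprintf("non-demented ROC: AUC %.3f (95%% CI %.3f-%.3f), n = %d\n",
            ci$auc, ci$lower, ci$upper, sum(nd)))

write.csv(roc$points, "results/roc_points.csv", row.names = FALSE)
thr <- data.frame(method = c("gmm", "stump", "youden"),
                  threshold = c(thr_gmm$value, thr_stump$value,
                                thr_youden$value))
write.csv(thr, "results/thresholds.csv", row.names = FALSE)
pdf("results/roc_curve.pdf", width = 5, height = 5)
plot(roc, thresholds = list(gmm = thr_gmm, stump = thr_stump,
                            youden = thr_youden))
dev.off()
cat("wrote results/thresholds.csv, results/roc_points.csv, results/roc_curve.pdf\n")
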