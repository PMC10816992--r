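#!/usr/bin/env Rscript

# Step 4 — posttest probabilities of brain amyloidosis.
#
# Converts each threshold's non-demented sensitivity/specificity into
# posttest probabilities at the published amyloid prevalences among
# clinically normal adults (15.8% at age 60, 32.6% at age 80): pretest
# odds times the likelihood ratio of the observed plasmatic result, then
# back to a probability.

suppressPackageStartupMessages(library(abratio))

perf <- read.csv("results/performance.csv")
perf <- perf[perf$subset == "non_demented", ]
prevalences <- c(age60 = 0.158, age80 = 0.326)

rows <- list()
for (i in seq_len(nrow(perf))) {
  for (a in names(prevalences)) {
    pt <- posttest(prevalences[[a]], perf$sensitivity[i],
                   perf$specificity[i])
    cat(sprintf("%-6s threshold %.4f at %s (prevalence %.1f%%): positive test -> %.1f%%, negative test -> %.1f%%\n",
                perf$method[i], perf$threshold[i], a,
                100 * pt$prevalence, 100 * pt$posttest_prob_pos,
                100 * pt$posttest_prob_neg))
    rows[[length(rows) + 1]] <- data.frame(
      method = perf$method[i], age = a, prevalence = pt$prevalence,
      pretest_odds = pt$pretest_odds, lr_pos = pt$lr_pos,
      lr_neg = pt$lr_neg, posttest_prob_pos = pt$posttest_prob_pos,
      posttest_prob_neg = pt$posttest_prob_neg)
  }
}
write.csv(do.call(rbind, rows), "results/posttest.csv", row.names = FALSE)
cat("wrote results/posttest.csv\n")
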