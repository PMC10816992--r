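#!/usr/bin/env Rscript

# Step 1 — simulate a study-shaped cohort.
#
# The participant-level data behind the published thresholds are not
# deposited, so the whole analysis runs on a synthetic cohort drawn from
# the calibrated study-shaped configuration: 277 volunteers, 70 AD and 18
# non-AD patients, a bimodal plasma Abeta42/Abeta40 ratio, and CSF/PET
# reference measurements for all patients and ~26% of volunteers at
# randomized delays from the blood draw.

suppressPackageStartupMessages(library(abratio))

seed <- 1173
dir.create("results", showWarnings = FALSE)

cfg <- paper_like_config()
cohort <- generate_cohort(cfg, seed = seed)
ann <- annotate_cohort(cohort)

write_cohort(cohort, "results/cohort.csv")
write_cohort(ann, "results/cohort_annotated.csv")

cat(sprintf("cohort: %d participants (%d volunteers, %d AD, %d non-AD)\n",
            nrow(ann), sum(ann$group == "volunteer"), sum(ann$group == "ad"),
            sum(ann$group == "non_ad")))
cat(sprintf("measured by CSF/PET: %d; eligible labeled set: %d (%d without dementia)\n",
            sum(ann$amyloid_status != "unknown"),
            sum(ann$eligible & ann$amyloid_status != "unknown"),
            sum(ann$eligible & ann$amyloid_status != "unknown" & !ann$dementia)))
cat(sprintf("latent amyloid-positive fraction: %.3f (analytic crossing of the generator: %.4f)\n",
            mean(ann$latent_amyloid), analytic_intersection(cfg)))
cat("wrote results/cohort.csv and results/cohort_annotated.csv\n")
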