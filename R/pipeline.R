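#' End-to-end threshold analysis of a cohort
#'
#' Reproduces the full analysis flow on a real or synthetic cohort:
#'
#' 1. annotate the cohort (amyloid calls, dementia, eligibility);
#' 2. remove interquartile-fence outliers from the ratios of *all*
#'    participants — labeled or not — and fit the two-component mixture
#'    there, extracting the intersection cutoff (the unsupervised stage
#'    deliberately uses everyone, which is its defining asymmetry versus
#'    the supervised stages);
#' 3. fit the Gini stump on the eligible labeled subset;
#' 4. build the ROC curve on the eligible labeled participants without
#'    dementia, with AUC, its confidence interval and the Youden cutoff;
#' 5. tabulate each threshold's performance on both labeled subgroups and
#'    convert the non-demented sensitivity/specificity into posttest
#'    probabilities at the configured prevalences.
#'
#' When the labeled subset is absent or single-class the supervised stages
#' are skipped with a warning and the mixture threshold is still reported.
#'
#' @param cohort a cohort `data.frame`; alternatively give `config` (a
#'   [generator_config()]) to generate one, or `path` (+ optional
#'   `mapping`) to read one.
#' @param config,path,mapping alternative cohort sources; see above.
#' @param window_days eligibility window for [is_eligible()].
#' @param seed seed for cohort generation (when `config` is given) and the
#'   EM restarts.
#' @param ci_method AUC confidence-interval method, `"delong"` or
#'   `"bootstrap"`.
#' @param intersection_weighted weight the mixture densities when
#'   intersecting (see [gaussian_intersection()]).
#' @param prevalences named vector of pretest prevalences for the posttest
#'   grid; the defaults are the published amyloid prevalences among
#'   clinically normal adults at ages 60 and 80.
#' @param verbose log per-stage participant counts.
#' @return an object of class `analysis_report`; see [render_report()].
#' @export
run_pipeline <- function(cohort = NULL, config = NULL, path = NULL,
                         mapping = NULL, window_days = 730, seed = NULL,
                         ci_method = c("delong", "bootstrap"),
                         intersection_weighted = TRUE,
                         prevalences = c(age60 = 0.158, age80 = 0.326),
                         verbose = TRUE) {
  ci_method <- match.arg(ci_method)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  if (is.null(cohort)) {
    if (!is.null(config)) {
      cohort <- generate_cohort(config, seed = if (is.null(seed)) config$seed
                                else seed)
      say("generated synthetic cohort: %d participants", nrow(cohort))
    } else if (!is.null(path)) {
      cohort <- read_cohort(path, mapping)
      say("read cohort from %s: %d participants", path, nrow(cohort))
    } else {
      stopf("provide one of `cohort`, `config` or `path`")
    }
  }
  cohort <- annotate_cohort(cohort, window_days = window_days)

  have_ratio <- !is.na(cohort$ratio)
  ratios_all <- cohort$ratio[have_ratio]
  ids_all <- cohort$id[have_ratio]
  outl <- remove_outliers_iqr(ratios_all)
  say("mixture stage: %d ratios, %d outlier(s) removed by the IQR rule",
      length(ratios_all), length(outl$removed))
  fit <- fit_gmm_em(outl$kept, seed = seed)
  gmm_thr <- tryCatch(
    gaussian_intersection(fit, weighted = intersection_weighted),
    abratio_no_intersection = function(e) {
      # unbalanced weights can push the weighted crossing outside the
      # component means; the unit-weight crossing still defines a usable
      # boundary there
      warning("weighted component densities do not cross between the means; falling back to the unweighted crossing",
              call. = FALSE)
      gaussian_intersection(fit, weighted = FALSE)
    })
  thresholds <- list(gmm = gmm_thr)

  known <- cohort$amyloid_status != "unknown"
  eligible <- cohort$eligible
  delay <- as.numeric(cohort$amyloid_date - cohort$blood_date)
  exception <- known & !is.na(delay) & delay < -window_days &
    cohort$amyloid_status == "positive"
  excluded_before <- known & !is.na(delay) & delay < -window_days &
    cohort$amyloid_status == "negative"
  excluded_after <- known & !is.na(delay) & delay > window_days
  say("eligibility: %d measured; %d retained by the prior-positive exception; %d excluded (negative measurement > %d days before blood); %d excluded (measurement > %d days after blood)",
      sum(known), sum(exception), sum(excluded_before), window_days,
      sum(excluded_after), window_days)

  labeled <- known & eligible & have_ratio
  lab_values <- cohort$ratio[labeled]
  lab_truth <- cohort$amyloid_status[labeled]
  nondem <- labeled & !is.na(cohort$dementia) & !cohort$dementia
  nd_values <- cohort$ratio[nondem]
  nd_truth <- cohort$amyloid_status[nondem]
  say("labeled analysis set: %d (of which %d without dementia)",
      sum(labeled), sum(nondem))

  roc <- NULL
  ci <- NULL
  supervised_ok <- sum(labeled) >= 2 &&
    length(unique(lab_truth)) == 2
  if (supervised_ok) {
    thresholds$stump <- fit_stump(lab_values, lab_truth)
    if (sum(nondem) >= 2 && length(unique(nd_truth)) == 2) {
      roc <- roc_curve(nd_values, nd_truth)
      ci <- auc_ci(nd_values, nd_truth, method = ci_method, seed = seed)
      thresholds$youden <- youden_threshold(roc)
    } else {
      warning("non-demented labeled subset degenerate: ROC/Youden skipped",
              call. = FALSE)
    }
  } else {
    warning("labeled subset absent or single-class: supervised stages skipped",
            call. = FALSE)
  }

  performance <- list()
  for (m in names(thresholds)) {
    performance[[m]] <- list()
    if (supervised_ok) {
      performance[[m]]$all_labeled <-
        diagnostic_performance(lab_values, lab_truth, thresholds[[m]])
      if (!is.null(roc)) {
        performance[[m]]$non_demented <-
          diagnostic_performance(nd_values, nd_truth, thresholds[[m]])
      }
    }
  }

  posttest_grid <- list()
  for (m in names(performance)) {
    perf <- performance[[m]]$non_demented
    if (is.null(perf)) next
    posttest_grid[[m]] <- lapply(prevalences, function(p) {
      posttest(p, perf$sensitivity, perf$specificity)
    })
  }

  report <- list(
    thresholds = thresholds,
    performance = performance,
    roc = roc,
    auc_ci = ci,
    posttest = posttest_grid,
    outliers = list(ids = ids_all[outl$removed_idx],
                    values = outl$removed, fences = outl$fences),
    counts = list(
      n_total = nrow(cohort),
      n_with_ratio = sum(have_ratio),
      n_outliers_removed = length(outl$removed),
      n_mixture = length(outl$kept),
      n_measured = sum(known),
      n_retained_exception = sum(exception),
      n_excluded_negative_before = sum(excluded_before),
      n_excluded_after = sum(excluded_after),
      n_labeled = sum(labeled),
      n_non_demented_labeled = sum(nondem)),
    provenance = list(
      seed = seed, window_days = window_days, ci_method = ci_method,
      intersection_weighted = intersection_weighted,
      prevalences = as.list(prevalences),
      package_version = as.character(utils::packageVersion("abratio"))))
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Plasma Abeta42/Abeta40 threshold analysis\n")
  for (m in names(x$thresholds)) {
    cat(sprintf("  %-6s threshold: %.5f\n", m, x$thresholds[[m]]$value))
  }
  if (!is.null(x$auc_ci)) {
    cat(sprintf("  AUC (non-demented): %.3f (%d%% CI %.3f-%.3f, %s)\n",
                x$auc_ci$auc, round(100 * x$auc_ci$level), x$auc_ci$lower,
                x$auc_ci$upper, x$auc_ci$method))
  }
  cat(sprintf("  labeled n = %d (non-demented %d); mixture n = %d\n",
              x$counts$n_labeled, x$counts$n_non_demented_labeled,
              x$counts$n_mixture))
  invisible(x)
}

perf_to_list <- function(p) {
  list(threshold = p$threshold, n = p$n,
       tp = p$cm$tp, fn = p$cm$fn, fp = p$cm$fp, tn = p$cm$tn,
       sensitivity = p$sensitivity, specificity = p$specificity,
       lr_pos = p$lr_pos, lr_neg = p$lr_neg)
}

report_to_list <- function(report) {
  list(
    thresholds = lapply(report$thresholds, function(t) {
      out <- list(value = t$value, method = t$method,
                  boundary_rule = t$boundary_rule)
      if (t$method == "gmm") {
        out$fit <- list(weights = t$fit$weights, means = t$fit$means,
                        sds = t$fit$sds, loglik = t$fit$loglik,
                        converged = t$fit$converged)
      }
      if (t$method == "stump") out$impurity <- t$impurity
      if (t$method == "youden") out$j <- t$j
      out
    }),
    performance = lapply(report$performance, function(by_sub) {
      lapply(by_sub, perf_to_list)
    }),
    auc = if (!is.null(report$auc_ci)) {
      list(auc = report$auc_ci$auc, lower = report$auc_ci$lower,
           upper = report$auc_ci$upper, method = report$auc_ci$method)
    },
    posttest = lapply(report$posttest, function(by_prev) {
      lapply(by_prev, function(p) unclass(p))
    }),
    outliers = list(ids = as.list(report$outliers$ids),
                    values = as.list(report$outliers$values)),
    counts = report$counts,
    provenance = report$provenance)
}

fmt_pct <- function(x) sprintf("%.1f%%", round_half_up(100 * x, 1))

#' Render an analysis report
#'
#' `"json"` gives a machine-readable document (byte-stable for identical
#' reports); `"markdown"` gives the human-readable summary, with the
#' per-threshold cross-tabulations laid out as plasmatic call against
#' CSF/PET status and percentages rounded half-up at one decimal.
#'
#' @param report an [run_pipeline()] result.
#' @param format `"json"` or `"markdown"`.
#' @return a character scalar (the document).
#' @export
render_report <- function(report, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(report_to_list(report),
                                         auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE, null = "null")))
  }
  lines <- c("# Plasma Abeta42/Abeta40 threshold analysis", "")
  lines <- c(lines, "## Thresholds", "")
  for (m in names(report$thresholds)) {
    lines <- c(lines, sprintf("- %s: %.5f", m, report$thresholds[[m]]$value))
  }
  if (!is.null(report$auc_ci)) {
    lines <- c(lines, "", sprintf(
      "AUC (non-demented labeled subset): %.3f (%d%% CI %.3f-%.3f, %s)",
      report$auc_ci$auc, round(100 * report$auc_ci$level),
      report$auc_ci$lower, report$auc_ci$upper, report$auc_ci$method))
  }
  if (!length(report$performance) ||
      all(vapply(report$performance, length, 0L) == 0)) {
    lines <- c(lines, "",
               "Supervised stages were skipped (no usable labeled subset).")
  }
  for (m in names(report$performance)) {
    for (sub in names(report$performance[[m]])) {
      p <- report$performance[[m]][[sub]]
      lines <- c(lines, "", sprintf("## %s threshold (%.5f), %s subset", m,
                                    p$threshold, gsub("_", " ", sub)), "",
                 "| | CSF/PET Abeta+ | CSF/PET Abeta- |",
                 "|---|---|---|",
                 sprintf("| Plasmatic Abeta+ | %d | %d |", p$cm$tp, p$cm$fp),
                 sprintf("| Plasmatic Abeta- | %d | %d |", p$cm$fn, p$cm$tn),
                 "",
                 sprintf("Sensitivity %s, specificity %s; LR+ %.2f, LR- %.2f",
                         fmt_pct(p$sensitivity), fmt_pct(p$specificity),
                         p$lr_pos, p$lr_neg))
    }
  }
  if (length(report$posttest)) {
    lines <- c(lines, "", "## Posttest probabilities (non-demented subset)",
               "", "| method | prevalence | positive test | negative test |",
               "|---|---|---|---|")
    for (m in names(report$posttest)) {
      for (pv in names(report$posttest[[m]])) {
        p <- report$posttest[[m]][[pv]]
        lines <- c(lines, sprintf("| %s | %s (%s) | %s | %s |", m, pv,
                                  fmt_pct(p$prevalence),
                                  fmt_pct(p$posttest_prob_pos),
                                  fmt_pct(p$posttest_prob_neg)))
      }
    }
  }
  paste(c(lines, ""), collapse = "\n")
}
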