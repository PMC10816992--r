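# Normalise amyloid labels to logical (TRUE = positive). Accepts logicals,
# or character/factor "positive"/"negative".
as_positive_logical <- function(x) {
  if (is.logical(x)) {
    if (anyNA(x)) stopf("labels must not contain NA")
    return(x)
  }
  x <- as.character(x)
  ok <- x %in% c("positive", "negative")
  if (!all(ok)) stopf("labels must be 'positive'/'negative' (or logical); offending value(s): %s",
                      paste(unique(x[!ok]), collapse = ", "))
  x == "positive"
}

#' Confusion matrix of plasmatic calls against reference amyloid status
#'
#' @param pred predicted labels (plasmatic call).
#' @param truth reference labels (CSF/PET amyloid status).
#' @return an object of class `confusion_matrix` with counts `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion <- function(pred, truth) {
  p <- as_positive_logical(pred)
  t <- as_positive_logical(truth)
  if (length(p) != length(t)) stopf("pred and truth differ in length")
  out <- list(tp = sum(p & t), fn = sum(!p & t),
              fp = sum(p & !t), tn = sum(!p & !t))
  class(out) <- "confusion_matrix"
  out
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("Plasmatic Abeta+", "Plasmatic Abeta-"),
                              c("CSF/PET Abeta+", "CSF/PET Abeta-")))
  print(m)
  invisible(x)
}

#' Sensitivity and specificity from a confusion matrix
#'
#' `Sn = tp / (tp + fn)`, `Sp = tn / (fp + tn)`; both margins must be
#' non-empty.
#'
#' @param cm a [confusion()] result (or a list with `tp`, `fn`, `fp`, `tn`).
#' @return named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sens_spec <- function(cm) {
  if (cm$tp + cm$fn == 0) stopf("no reference positives: sensitivity undefined")
  if (cm$fp + cm$tn == 0) stopf("no reference negatives: specificity undefined")
  c(sensitivity = cm$tp / (cm$tp + cm$fn),
    specificity = cm$tn / (cm$fp + cm$tn))
}

#' Positive and negative likelihood ratios
#'
#' `LR+ = Sn / (1 - Sp)` and `LR- = (1 - Sn) / Sp`. A specificity of 1
#' yields an infinite `LR+`; a specificity of 0 leaves `LR-` undefined and
#' raises an error.
#'
#' @param sensitivity,specificity proportions in [0, 1].
#' @return named numeric vector `c(lr_pos =, lr_neg =)`.
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  assert_prob(sensitivity, "sensitivity")
  assert_prob(specificity, "specificity")
  if (specificity == 0) stopf("specificity 0: negative likelihood ratio undefined")
  lr_pos <- if (specificity == 1) Inf else sensitivity / (1 - specificity)
  c(lr_pos = lr_pos, lr_neg = (1 - sensitivity) / specificity)
}

#' Pretest-to-posttest probability calculus
#'
#' Converts the pretest prevalence to odds (`p / (1 - p)`), multiplies by
#' the likelihood ratio of the observed test result, and converts the
#' posttest odds back to a probability (`odds / (1 + odds)`), for both a
#' positive and a negative plasmatic result.
#'
#' @param prevalence pretest probability of brain amyloidosis, in (0, 1).
#' @inheritParams likelihood_ratios
#' @return an object of class `posttest_result`: `prevalence`,
#'   `pretest_odds`, `lr_pos`, `lr_neg`, `posttest_odds_pos`,
#'   `posttest_odds_neg`, `posttest_prob_pos`, `posttest_prob_neg`.
#' @examples
#' # amyloid prevalence 15.8% at age 60; a cutoff with Sn 44/53, Sp 42/73
#' posttest(0.158, 44 / 53, 42 / 73)
#' @export
posttest <- function(prevalence, sensitivity, specificity) {
  assert_prob(prevalence, "prevalence")
  if (prevalence <= 0 || prevalence >= 1) {
    stopf("`prevalence` must lie strictly inside (0, 1)")
  }
  lr <- likelihood_ratios(sensitivity, specificity)
  pretest_odds <- prevalence / (1 - prevalence)
  odds_pos <- pretest_odds * lr[["lr_pos"]]
  odds_neg <- pretest_odds * lr[["lr_neg"]]
  out <- list(prevalence = prevalence,
              pretest_odds = pretest_odds,
              lr_pos = lr[["lr_pos"]], lr_neg = lr[["lr_neg"]],
              posttest_odds_pos = odds_pos,
              posttest_odds_neg = odds_neg,
              posttest_prob_pos = if (is.infinite(odds_pos)) 1
              else odds_pos / (1 + odds_pos),
              posttest_prob_neg = odds_neg / (1 + odds_neg))
  class(out) <- "posttest_result"
  out
}

#' @export
print.posttest_result <- function(x, ...) {
  cat(sprintf("Pretest prevalence %.1f%% (odds %.3f); LR+ %.2f, LR- %.2f\n",
              100 * x$prevalence, x$pretest_odds, x$lr_pos, x$lr_neg))
  cat(sprintf("  positive test -> %.1f%%; negative test -> %.1f%%\n",
              100 * x$posttest_prob_pos, 100 * x$posttest_prob_neg))
  invisible(x)
}

#' Full diagnostic performance of a threshold on labeled samples
#'
#' Applies the low-ratio-positive rule at the threshold, tabulates against
#' the reference status and derives sensitivity, specificity and the
#' likelihood ratios from the exact count fractions (rounding is left to
#' report time).
#'
#' @inheritParams fit_stump
#' @param threshold a `threshold_result` or bare number.
#' @return an object of class `diagnostic_performance`: `cm`,
#'   `sensitivity`, `specificity`, `lr_pos`, `lr_neg`, `threshold`, `n`.
#' @export
diagnostic_performance <- function(values, truth, threshold) {
  pred <- classify_plasmatic(values, threshold)
  cm <- confusion(pred, truth)
  ss <- sens_spec(cm)
  lr <- likelihood_ratios(ss[["sensitivity"]], ss[["specificity"]])
  out <- list(cm = cm,
              sensitivity = ss[["sensitivity"]],
              specificity = ss[["specificity"]],
              lr_pos = lr[["lr_pos"]], lr_neg = lr[["lr_neg"]],
              threshold = if (inherits(threshold, "threshold_result"))
                threshold$value else threshold,
              n = length(values))
  class(out) <- "diagnostic_performance"
  out
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  cat(sprintf("Threshold %.6g on %d labeled samples\n", x$threshold, x$n))
  print(x$cm)
  cat(sprintf("Sensitivity %.1f%%, specificity %.1f%%; LR+ %.2f, LR- %.2f\n",
              100 * x$sensitivity, 100 * x$specificity, x$lr_pos, x$lr_neg))
  invisible(x)
}
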