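#' Depth-one decision tree on the Gini diversity index
#'
#' Exhaustively scans every candidate cutpoint — the midpoints between
#' consecutive distinct sorted values — and returns the one minimising the
#' size-weighted Gini impurity `nL/n * G(L) + nR/n * G(R)`, with
#' `G = 1 - sum(p_c^2)`. The left branch (values at or below the cutpoint)
#' predicts plasmatic amyloid-positive. When several cutpoints tie, the
#' smallest is returned.
#'
#' @param values numeric vector of ratios.
#' @param truth matching amyloid status: logical (`TRUE` = positive) or
#'   `"positive"`/`"negative"`.
#' @return a `threshold_result` with `method = "stump"` and extras:
#'   `impurity` (the minimised weighted Gini), `gini_left`, `gini_right`
#'   and the per-leaf class counts.
#' @export
fit_stump <- function(values, truth) {
  pos <- as_positive_logical(truth)
  if (length(values) != length(pos)) stopf("values and truth differ in length")
  if (length(values) < 2) stopf("need at least 2 samples")
  if (any(!is.finite(values))) stopf("values must be finite")
  if (!any(pos) || all(pos)) stopf("both classes must be present to fit a stump")
  ord <- order(values)
  xs <- values[ord]
  ps <- pos[ord]
  n <- length(xs)
  distinct <- which(diff(xs) > 0)
  if (!length(distinct)) stopf("all values identical: no valid split exists")
  cuts <- (xs[distinct] + xs[distinct + 1]) / 2
  cum_pos <- cumsum(ps)
  n_l <- distinct
  pos_l <- cum_pos[distinct]
  n_r <- n - n_l
  pos_r <- sum(ps) - pos_l
  gini <- function(k, size) {
    p <- k / size
    1 - p^2 - (1 - p)^2
  }
  g_l <- gini(pos_l, n_l)
  g_r <- gini(pos_r, n_r)
  impurity <- (n_l * g_l + n_r * g_r) / n
  best <- which(impurity <= min(impurity) + 1e-15)[1]
  new_threshold_result(cuts[best], "stump", list(
    impurity = impurity[best],
    gini_left = g_l[best], gini_right = g_r[best],
    counts = list(
      left = c(positive = pos_l[best], negative = n_l[best] - pos_l[best]),
      right = c(positive = pos_r[best], negative = n_r[best] - pos_r[best]))))
}

#' Diagnostic performance of a stump threshold
#'
#' Classifies the samples with the low-ratio-positive rule at the given (or
#' freshly fitted) stump threshold and tabulates them against the reference
#' amyloid status.
#'
#' @inheritParams fit_stump
#' @param threshold a `threshold_result` (defaults to fitting the stump on
#'   the same samples, as in training on all data).
#' @return a `diagnostic_performance` (see [diagnostic_performance()]).
#' @export
stump_performance <- function(values, truth, threshold = NULL) {
  if (is.null(threshold)) threshold <- fit_stump(values, truth)
  diagnostic_performance(values, truth, threshold)
}

#' K-fold cross-validated stump performance
#'
#' An extension beyond the headline analysis (which trains on all data):
#' refits the stump on each training fold and evaluates sensitivity and
#' specificity on the held-out fold.
#'
#' @inheritParams fit_stump
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @return a data.frame with one row per fold: `threshold`, `sensitivity`,
#'   `specificity` (`NA` where a fold margin is empty).
#' @export
cv_stump <- function(values, truth, k = 5, seed = NULL) {
  pos <- as_positive_logical(truth)
  n <- length(values)
  if (k < 2 || k > n) stopf("`k` must be between 2 and the sample size")
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(k), n))
    out <- lapply(seq_len(k), function(f) {
      thr <- fit_stump(values[fold != f], pos[fold != f])
      pred <- classify_plasmatic(values[fold == f], thr) == "positive"
      truth_f <- pos[fold == f]
      sn <- if (any(truth_f)) mean(pred[truth_f]) else NA_real_
      sp <- if (any(!truth_f)) mean(!pred[!truth_f]) else NA_real_
      data.frame(fold = f, threshold = thr$value, sensitivity = sn,
                 specificity = sp)
    })
    do.call(rbind, out)
  })
}
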