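#' Empirical ROC curve for a low-positive marker
#'
#' The positivity direction is fixed a priori: a value at or below the
#' cutoff tests positive (low plasma Abeta42/Abeta40 indicates brain
#' amyloid). One curve point per distinct observed value, plus the two
#' trivial endpoints at -Inf (sensitivity 0, specificity 1) and +Inf
#' (sensitivity 1, specificity 0). The AUC is the trapezoidal area, which
#' equals the Mann-Whitney probability `P(X+ < X-) + 0.5 P(X+ = X-)`.
#'
#' @inheritParams fit_stump
#' @return an object of class `roc_curve`: `points` (data.frame with
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(values, truth) {
  pos <- as_positive_logical(truth)
  if (length(values) != length(pos)) stopf("values and truth differ in length")
  if (any(!is.finite(values))) stopf("values must be finite")
  if (!any(pos) || all(pos)) stopf("both classes must be present")
  xp <- values[pos]
  xn <- values[!pos]
  cuts <- sort(unique(values))
  sn <- vapply(cuts, function(t) mean(xp <= t), numeric(1))
  sp <- vapply(cuts, function(t) mean(xn > t), numeric(1))
  points <- data.frame(
    threshold = c(-Inf, cuts, Inf),
    sensitivity = c(0, sn, 1),
    specificity = c(1, sp, 0))
  fpr <- 1 - points$specificity
  tpr <- points$sensitivity
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- list(points = points, auc = auc,
              n_pos = length(xp), n_neg = length(xn))
  class(out) <- "roc_curve"
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, AUC %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

# AUC (positive class lower) via the rank form of the Mann-Whitney U:
# counts pairs with x_neg > x_pos, ties at 1/2.
auc_stat <- function(xp, xn) {
  r <- rank(c(xn, xp))
  nn <- length(xn)
  u <- sum(r[seq_len(nn)]) - nn * (nn + 1) / 2
  u / (nn * length(xp))
}

#' Confidence interval for the AUC
#'
#' Default is the DeLong interval from the variance of placement values;
#' `"bootstrap"` draws stratified resamples of each class and takes
#' percentile limits. Both are clipped to [0, 1].
#'
#' @inheritParams fit_stump
#' @param method `"delong"` or `"bootstrap"`.
#' @param level confidence level.
#' @param B bootstrap resamples.
#' @param seed bootstrap seed.
#' @return a list: `auc`, `lower`, `upper`, `method`, `level`.
#' @export
auc_ci <- function(values, truth, method = c("delong", "bootstrap"),
                   level = 0.95, B = 2000L, seed = NULL) {
  method <- match.arg(method)
  pos <- as_positive_logical(truth)
  xp <- values[pos]
  xn <- values[!pos]
  if (length(xp) < 2 || length(xn) < 2) {
    stopf("need at least 2 samples in each class")
  }
  auc <- auc_stat(xp, xn)
  if (method == "delong") {
    # placement of each positive among the negatives, and vice versa
    v10 <- vapply(xp, function(v) mean(xn > v) + 0.5 * mean(xn == v),
                  numeric(1))
    v01 <- vapply(xn, function(v) mean(xp < v) + 0.5 * mean(xp == v),
                  numeric(1))
    var_auc <- stats::var(v10) / length(xp) + stats::var(v01) / length(xn)
    if (var_auc == 0 && auc > 0 && auc < 1) {
      stopf("degenerate DeLong variance (ties-only data)")
    }
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- auc - z * sqrt(var_auc)
    hi <- auc + z * sqrt(var_auc)
  } else {
    bs <- with_seed(seed, replicate(B, {
      auc_stat(sample(xp, replace = TRUE), sample(xn, replace = TRUE))
    }))
    qs <- stats::quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    lo <- qs[1]
    hi <- qs[2]
  }
  list(auc = auc, lower = max(0, lo), upper = min(1, hi),
       method = method, level = level)
}

#' Youden-index cutoff
#'
#' The observed cutoff maximising `J = sensitivity + specificity - 1`.
#' Among ties the cutoff with the higher specificity (the smaller
#' threshold) wins, favouring fewer false positives in a
#' screening-then-confirmation chain. The threshold is reported as an
#' observed value, not a midpoint.
#'
#' @param roc a [roc_curve()].
#' @return a `threshold_result` with `method = "youden"` and extras
#'   `sensitivity`, `specificity`, `j`.
#' @export
youden_threshold <- function(roc) {
  pts <- roc$points[is.finite(roc$points$threshold), ]
  if (!nrow(pts)) stopf("degenerate ROC curve")
  j <- pts$sensitivity + pts$specificity - 1
  cand <- which(j >= max(j) - 1e-12)
  best <- cand[which.max(pts$specificity[cand])]
  new_threshold_result(pts$threshold[best], "youden", list(
    sensitivity = pts$sensitivity[best],
    specificity = pts$specificity[best],
    j = j[best]))
}

#' Plot an ROC curve with annotated cutoffs
#'
#' @param x a [roc_curve()].
#' @param thresholds optional named list of `threshold_result`s (or bare
#'   numbers) marked on the curve.
#' @param ... passed to [plot()].
#' @export
plot.roc_curve <- function(x, thresholds = NULL, ...) {
  fpr <- 1 - x$points$specificity
  plot(fpr, x$points$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  if (!is.null(thresholds)) {
    for (nm in names(thresholds)) {
      thr <- thresholds[[nm]]
      v <- if (inherits(thr, "threshold_result")) thr$value else thr
      i <- which.min(abs(x$points$threshold - v))
      graphics::points(fpr[i], x$points$sensitivity[i], pch = 19)
      graphics::text(fpr[i], x$points$sensitivity[i],
                     sprintf("%s (%.4g)", nm, v), pos = 4, cex = 0.8)
    }
  }
  invisible(x)
}
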