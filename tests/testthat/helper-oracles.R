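# Independent oracles used to freeze expected values; deliberately naive
# implementations kept separate from the code paths they check.

# Bisection root of w1*phi(x;m1,s1) - w2*phi(x;m2,s2) on (lo, hi).
bisect_intersection <- function(w1, m1, s1, w2, m2, s2, lo, hi,
                                tol = 1e-14, max_iter = 200) {
  f <- function(x) w1 * dnorm(x, m1, s1) - w2 * dnorm(x, m2, s2)
  stopifnot(sign(f(lo)) != sign(f(hi)))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) break
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Exhaustive scan of every midpoint cutpoint, minimising weighted Gini.
brute_gini_stump <- function(values, positive) {
  ord <- order(values)
  xs <- values[ord]
  ps <- positive[ord]
  n <- length(xs)
  best_cut <- NA_real_
  best_imp <- Inf
  for (i in seq_len(n - 1)) {
    if (xs[i] == xs[i + 1]) next
    cut <- (xs[i] + xs[i + 1]) / 2
    left <- values <= cut
    gini <- function(sel) {
      p <- mean(positive[sel])
      1 - p^2 - (1 - p)^2
    }
    imp <- sum(left) / n * gini(left) + sum(!left) / n * gini(!left)
    if (imp < best_imp - 1e-15) {
      best_imp <- imp
      best_cut <- cut
    }
  }
  list(cut = best_cut, impurity = best_imp)
}

# AUC by counting every (positive, negative) pair; positives expected lower.
pair_count_auc <- function(xp, xn) {
  total <- 0
  for (p in xp) {
    total <- total + sum(p < xn) + 0.5 * sum(p == xn)
  }
  total / (length(xp) * length(xn))
}

# Exhaustive Youden scan over all observed cutoffs (ties broken toward the
# higher-specificity, i.e. smaller, cutoff).
brute_youden <- function(values, positive) {
  cuts <- sort(unique(values))
  best <- list(j = -Inf)
  for (t in cuts) {
    sn <- mean(values[positive] <= t)
    sp <- mean(values[!positive] > t)
    j <- sn + sp - 1
    if (j > best$j + 1e-12) best <- list(cut = t, j = j, sn = sn, sp = sp)
  }
  best
}

# A labeled binormal sample with positives shifted low.
make_labeled <- function(n_pos, n_neg, seed, mu = c(0.0450, 0.0495),
                         sd = c(0.0030, 0.0070), digits = NULL) {
  set.seed(seed)
  values <- c(rnorm(n_pos, mu[1], sd[1]), rnorm(n_neg, mu[2], sd[2]))
  if (!is.null(digits)) values <- round(values, digits)
  list(values = values,
       truth = rep(c("positive", "negative"), c(n_pos, n_neg)),
       positive = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
}

# Rebuild per-participant labels from a printed 2x2 table; the two value
# groups sit on either side of the stated threshold.
samples_from_counts <- function(tp, fp, fn, tn, thr = 0.0465) {
  list(values = c(rep(thr - 0.001, tp + fp), rep(thr + 0.001, fn + tn)),
       truth = c(rep("positive", tp), rep("negative", fp),
                 rep("positive", fn), rep("negative", tn)))
}
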