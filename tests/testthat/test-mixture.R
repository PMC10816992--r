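test_that("interquartile fences match hand-computed quartiles", {
  out <- remove_outliers_iqr(c(1, 2, 3, 4, 100))
  # type-7 quartiles of the 5 values: q25 = 2, q75 = 4, IQR = 2,
  # fences [-1, 7]
  expect_equal(unname(out$fences), c(-1, 7))
  expect_equal(out$removed, 100)
  expect_equal(out$kept, c(1, 2, 3, 4))
  expect_equal(out$removed_idx, 5L)
})

test_that("degenerate and small inputs are handled", {
  allsame <- remove_outliers_iqr(rep(0.05, 10))
  expect_length(allsame$removed, 0)
  expect_error(remove_outliers_iqr(c(1, 2, 3)), "at least 4")
  expect_error(remove_outliers_iqr(c(1, 2, 3, NA)), "at least 4")
})

test_that("outlier removal partitions the input and matches a fence oracle", {
  co <- generate_cohort(generator_config(n_outliers = 8), seed = 13)
  out <- remove_outliers_iqr(co$ratio)
  expect_equal(sort(c(out$kept, out$removed)), sort(co$ratio))
  q <- quantile(co$ratio, c(0.25, 0.75), names = FALSE)
  oracle <- which(co$ratio < q[1] - 1.5 * (q[2] - q[1]) |
                    co$ratio > q[2] + 1.5 * (q[2] - q[1]))
  expect_equal(out$removed_idx, oracle)
  expect_gte(length(oracle), 8)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  lab <- make_labeled(150, 250, seed = 31)
  fit <- fit_gmm_em(lab$values, keep_trace = TRUE)
  expect_true(all(diff(fit$trace) >= -1e-9))
  expect_true(fit$converged)
  expect_lt(fit$means[1], fit$means[2])
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
})

test_that("well-separated point masses are recovered exactly", {
  fit <- fit_gmm_em(c(rep(0.03, 50), rep(0.06, 50)))
  expect_equal(fit$means, c(0.03, 0.06), tolerance = 1e-8)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-8)
})

test_that("EM recovers generating parameters within simulation error", {
  truth <- list(w = 0.4, mu = c(0.042, 0.052), sd = c(0.004, 0.005))
  ests <- vapply(1:8, function(r) {
    set.seed(100 + r)
    n <- 3000
    pos <- runif(n) < truth$w
    x <- ifelse(pos, rnorm(n, truth$mu[1], truth$sd[1]),
                rnorm(n, truth$mu[2], truth$sd[2]))
    f <- fit_gmm_em(x)
    c(f$weights[1], f$means, f$sds)
  }, numeric(5))
  target <- c(truth$w, truth$mu, truth$sd)
  for (i in 1:5) {
    se <- sd(ests[i, ]) / sqrt(ncol(ests))
    expect_lt(abs(mean(ests[i, ]) - target[i]), 3 * se)
  }
})

test_that("a single Gaussian is represented without density distortion", {
  set.seed(7)
  x <- rnorm(2000, 0.05, 0.005)
  fit <- fit_gmm_em(x)
  grid <- seq(0.05 - 6 * 0.005, 0.05 + 6 * 0.005, length.out = 4001)
  f_mix <- fit$weights[1] * dnorm(grid, fit$means[1], fit$sds[1]) +
    fit$weights[2] * dnorm(grid, fit$means[2], fit$sds[2])
  f_one <- dnorm(grid, mean(x), sd(x))
  tv <- 0.5 * sum(abs(f_mix - f_one)) * (grid[2] - grid[1])
  expect_lt(tv, 0.02)
})

test_that("EM input validation rejects unusable data", {
  expect_error(fit_gmm_em(rnorm(5)), "at least 10")
  expect_error(fit_gmm_em(c(rnorm(10), Inf)), "finite")
  expect_error(fit_gmm_em(rep(0.05, 20)), "identical")
})

manual_fit <- function(w, mu, sd) {
  structure(list(weights = w, means = mu, sds = sd, loglik = 0,
                 n_iter = 0L, converged = TRUE, n = 0L),
            class = "mixture_fit")
}

test_that("equal-variance symmetric components cross at the midpoint", {
  thr <- gaussian_intersection(manual_fit(c(0.5, 0.5), c(0, 2), c(1, 1)))
  expect_equal(thr$value, 1)
  expect_equal(thr$method, "gmm")
})

test_that("the closed-form crossing matches a bisection oracle", {
  cases <- list(
    list(w = c(0.5, 0.5), mu = c(0, 3), sd = c(1, 2), tol = 1e-10),
    list(w = c(0.3, 0.7), mu = c(0.042, 0.052), sd = c(0.004, 0.005),
         tol = 1e-12),
    list(w = c(0.62, 0.38), mu = c(0.040, 0.055), sd = c(0.006, 0.003),
         tol = 1e-12))
  for (cs in cases) {
    got <- gaussian_intersection(manual_fit(cs$w, cs$mu, cs$sd))$value
    oracle <- bisect_intersection(cs$w[1], cs$mu[1], cs$sd[1],
                                  cs$w[2], cs$mu[2], cs$sd[2],
                                  cs$mu[1], cs$mu[2])
    expect_equal(got, oracle, tolerance = cs$tol)
  }
})

test_that("the crossing is invariant to which component is labeled first", {
  r1 <- abratio:::intersection_roots(0.3, 0.042, 0.004, 0.7, 0.052, 0.005)
  r2 <- abratio:::intersection_roots(0.7, 0.052, 0.005, 0.3, 0.042, 0.004)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("weighted and unweighted crossings differ as the weights skew", {
  fit <- manual_fit(c(0.25, 0.75), c(0.042, 0.052), c(0.004, 0.004))
  w <- gaussian_intersection(fit, weighted = TRUE)$value
  u <- gaussian_intersection(fit, weighted = FALSE)$value
  expect_equal(u, 0.047)  # equal-variance unweighted crossing = midpoint
  expect_lt(w, u)  # small positive weight pulls the boundary down
})

test_that("a crossing outside the means raises an error carrying the roots", {
  fit <- manual_fit(c(0.999, 0.001), c(0, 0.1), c(1, 1.001))
  err <- tryCatch(gaussian_intersection(fit), error = identity)
  expect_s3_class(err, "abratio_no_intersection")
  expect_true(length(err$roots) >= 1)
})

test_that("classification at the boundary is positive (<=)", {
  thr <- abratio:::new_threshold_result(0.0472, "gmm")
  expect_equal(classify_plasmatic(c(0.0472, 0.0473), thr),
               c("positive", "negative"))
  expect_equal(classify_plasmatic(numeric(0), thr), character(0))
  expect_equal(classify_plasmatic(0.04, 0.0472), "positive")
})
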