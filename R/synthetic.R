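#' Configuration for the synthetic cohort generator
#'
#' Returns a validated configuration describing the statistical structure
#' the analysis assumes: a bimodal plasma Abeta42/Abeta40 ratio (the
#' amyloid-positive component sits lower), group-dependent amyloid
#' probability for patients and an age-anchored prevalence curve for
#' volunteers, APOE epsilon-4 enrichment among the amyloid positives, MMSE
#' depending on dementia status, CSF/Centiloid reference values consistent
#' with the latent status, and randomized blood-to-amyloid measurement
#' delays that exercise the eligibility filter.
#'
#' The mixture defaults were calibrated once so that a two-component
#' unequal-variance Gaussian mixture fitted to a large generated cohort
#' crosses near 0.047, with between-component overlap comparable to the
#' published discrimination of the plasma ratio (binormal AUC about 0.72).
#' They are a stand-in for the study's unpublished component estimates, not
#' a reproduction of them.
#'
#' @param n_volunteers,n_ad,n_nonad group sizes.
#' @param mu_pos,sigma_pos ratio mean/SD for latent amyloid positives.
#' @param mu_neg,sigma_neg ratio mean/SD for latent amyloid negatives
#'   (`mu_pos < mu_neg`: the positive component is the lower one).
#' @param p_amyloid_by_group named probabilities of latent positivity for
#'   `ad` and `non_ad`; the `volunteer` entry may be `NA`, in which case the
#'   age-prevalence curve is used.
#' @param prevalence_by_age two-column data.frame (`age`, `prevalence`);
#'   linear interpolation between anchors, flat outside.
#' @param p_e4_given_pos,p_e4_given_neg APOE epsilon-4 carrier probability
#'   conditional on latent status.
#' @param p_apoe_missing fraction with missing genotype.
#' @param p_dementia_by_group named probabilities of dementia per group.
#' @param mmse_params list with `nondem` and `dem`, each `c(mean, sd)`;
#'   scores are rounded and clamped to [24, 30] / [0, 23].
#' @param p_measured_by_group named probabilities that a participant has a
#'   CSF/PET amyloid measurement at all.
#' @param p_csf_modality probability that a measured participant was
#'   measured by CSF rather than PET.
#' @param delay list describing the signed blood-to-amyloid delay in days:
#'   `p_long` (fraction beyond the window), `short_max`, `long_max`,
#'   `p_before_short`, `p_before_long` (probability the amyloid measurement
#'   precedes the blood draw).
#' @param label_noise probability that the CSF/PET values contradict the
#'   latent component the ratio was drawn from (default 0: labels agree
#'   with the generating component).
#' @param n_outliers number of participants whose ratio is replaced by an
#'   extreme value far outside the interquartile fences (default 0; the
#'   calibrated tails already produce realistic outlier rates).
#' @param age_by_group,p_female_by_group per-group age `c(mean, sd)`
#'   (truncated at 50) and probability of being female.
#' @param ab40_mean,ab40_sd plasma Abeta40 level used to decompose the
#'   ratio into the two concentrations.
#' @param seed default seed used by [generate_cohort()].
#' @return an object of class `generator_config` (a named list).
#' @seealso [generate_cohort()], [paper_like_config()],
#'   [analytic_intersection()]
#' @export
generator_config <- function(
    n_volunteers = 277, n_ad = 70, n_nonad = 18,
    mu_pos = 0.0450, sigma_pos = 0.0030,
    mu_neg = 0.0495, sigma_neg = 0.0070,
    p_amyloid_by_group = c(volunteer = NA, ad = 60 / 69, non_ad = 1 / 16),
    prevalence_by_age = data.frame(age = c(60, 80),
                                   prevalence = c(0.158, 0.326)),
    p_e4_given_pos = 0.70, p_e4_given_neg = 0.30,
    p_apoe_missing = 0.03,
    p_dementia_by_group = c(volunteer = 0, ad = 23 / 70, non_ad = 2 / 18),
    mmse_params = list(nondem = c(mean = 28.4, sd = 1.3),
                       dem = c(mean = 19, sd = 3)),
    p_measured_by_group = c(volunteer = 73 / 277, ad = 1, non_ad = 1),
    p_csf_modality = 0.5,
    delay = list(p_long = 0.15, short_max = 730, long_max = 1460,
                 p_before_short = 0.5, p_before_long = 0.85),
    label_noise = 0,
    n_outliers = 0,
    age_by_group = list(volunteer = c(mean = 66.5, sd = 7.78),
                        ad = c(mean = 71.1, sd = 8.05),
                        non_ad = c(mean = 65.6, sd = 9.55)),
    p_female_by_group = c(volunteer = 179 / 277, ad = 38 / 70,
                          non_ad = 11 / 18),
    ab40_mean = 250, ab40_sd = 40,
    seed = 1L) {
  cfg <- list(
    n_volunteers = n_volunteers, n_ad = n_ad, n_nonad = n_nonad,
    mu_pos = mu_pos, sigma_pos = sigma_pos,
    mu_neg = mu_neg, sigma_neg = sigma_neg,
    p_amyloid_by_group = p_amyloid_by_group,
    prevalence_by_age = prevalence_by_age,
    p_e4_given_pos = p_e4_given_pos, p_e4_given_neg = p_e4_given_neg,
    p_apoe_missing = p_apoe_missing,
    p_dementia_by_group = p_dementia_by_group,
    mmse_params = mmse_params,
    p_measured_by_group = p_measured_by_group,
    p_csf_modality = p_csf_modality,
    delay = delay,
    label_noise = label_noise,
    n_outliers = n_outliers,
    age_by_group = age_by_group,
    p_female_by_group = p_female_by_group,
    ab40_mean = ab40_mean, ab40_sd = ab40_sd,
    seed = seed)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  for (n in c("n_volunteers", "n_ad", "n_nonad")) {
    if (!is_scalar_number(cfg[[n]]) || cfg[[n]] < 0 || cfg[[n]] != round(cfg[[n]])) {
      stopf("`%s` must be a non-negative integer count", n)
    }
  }
  for (n in c("sigma_pos", "sigma_neg")) {
    if (!is_scalar_number(cfg[[n]]) || cfg[[n]] <= 0) stopf("`%s` must be > 0", n)
  }
  if (!is_scalar_number(cfg$mu_pos) || !is_scalar_number(cfg$mu_neg) ||
      cfg$mu_pos >= cfg$mu_neg) {
    stopf("`mu_pos` must be smaller than `mu_neg` (the amyloid-positive component is the lower-ratio one)")
  }
  probs <- c(cfg$p_amyloid_by_group[c("ad", "non_ad")],
             p_e4_given_pos = cfg$p_e4_given_pos,
             p_e4_given_neg = cfg$p_e4_given_neg,
             p_apoe_missing = cfg$p_apoe_missing,
             cfg$p_dementia_by_group, cfg$p_measured_by_group,
             p_csf_modality = cfg$p_csf_modality,
             label_noise = cfg$label_noise,
             cfg$p_female_by_group,
             p_long = cfg$delay$p_long,
             p_before_short = cfg$delay$p_before_short,
             p_before_long = cfg$delay$p_before_long,
             cfg$prevalence_by_age$prevalence)
  bad <- !is.finite(probs) | probs < 0 | probs > 1
  if (any(bad)) stopf("probabilities outside [0, 1]: %s",
                      paste(names(probs)[bad], collapse = ", "))
  if (cfg$n_outliers < 0 || cfg$n_outliers != round(cfg$n_outliers)) {
    stopf("`n_outliers` must be a non-negative integer")
  }
  cfg
}

#' Cohort configuration matching the study's design
#'
#' Group sizes 277 volunteers, 70 AD patients and 18 non-AD patients, with
#' 73 of the volunteers and all patients holding a CSF or PET amyloid
#' measurement, so the labeled analysis set lands near the study's 151
#' (126 without dementia) once the eligibility filter runs.
#'
#' @return a `generator_config`.
#' @export
paper_like_config <- function() generator_config()

#' Amyloid prevalence at a given age
#'
#' Linear interpolation between the configured anchors (defaults 15.8% at
#' age 60 and 32.6% at age 80), held flat outside their range.
#'
#' @param age numeric vector of ages.
#' @param anchors two-column data.frame (`age`, `prevalence`).
#' @return prevalence in [0, 1].
#' @export
prevalence_at_age <- function(age,
                              anchors = data.frame(age = c(60, 80),
                                                   prevalence = c(0.158, 0.326))) {
  stats::approx(anchors$age, anchors$prevalence, xout = age, rule = 2)$y
}

# Expected latent amyloid-positive fraction under a config: patients use
# their group probabilities; volunteers integrate the age-prevalence curve
# over the (truncated normal) volunteer age distribution.
expected_positive_weight <- function(cfg) {
  p_vol <- cfg$p_amyloid_by_group[["volunteer"]]
  if (is.na(p_vol)) {
    a <- cfg$age_by_group$volunteer
    norm <- 1 - stats::pnorm(50, a[["mean"]], a[["sd"]])
    p_vol <- stats::integrate(function(x) {
      prevalence_at_age(x, cfg$prevalence_by_age) *
        stats::dnorm(x, a[["mean"]], a[["sd"]]) / norm
    }, lower = 50, upper = a[["mean"]] + 10 * a[["sd"]])$value
  }
  n <- c(cfg$n_volunteers, cfg$n_ad, cfg$n_nonad)
  p <- c(p_vol, cfg$p_amyloid_by_group[["ad"]],
         cfg$p_amyloid_by_group[["non_ad"]])
  sum(n * p) / sum(n)
}

#' Analytic mixture intersection implied by a generator configuration
#'
#' The closed-form crossing of the two generating Gaussian components,
#' weighted by the expected latent amyloid-positive fraction. This is the
#' population-level target that a mixture fitted to a generated cohort
#' should recover.
#'
#' @param cfg a `generator_config`.
#' @param weighted weight the component densities by the mixing
#'   proportions (the classification boundary of the mixture); `FALSE`
#'   intersects the unit-weight densities.
#' @return the crossing point between the two component means.
#' @export
analytic_intersection <- function(cfg, weighted = TRUE) {
  w <- if (weighted) expected_positive_weight(cfg) else 0.5
  r <- intersection_roots(w, cfg$mu_pos, cfg$sigma_pos,
                          1 - w, cfg$mu_neg, cfg$sigma_neg)
  r <- r[r > cfg$mu_pos & r < cfg$mu_neg]
  if (!length(r)) stopf("no crossing between the component means")
  r[1]
}

rnorm_trunc <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= lower)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws a cohort with the structure described in [generator_config()]:
#' each participant gets a latent amyloid status, a ratio from the matching
#' Gaussian component (truncated at zero), plasma Abeta40/Abeta42
#' concentrations decomposing that ratio, and — when measured — a CSF or
#' Centiloid value consistent with the latent status and an amyloid
#' measurement date at a configurable delay from the blood draw.
#' Reproducible given the seed.
#'
#' @param cfg a `generator_config`.
#' @param seed overrides `cfg$seed`.
#' @return a cohort `data.frame` (see [cohort]) with two extra generator
#'   columns: `latent_amyloid` (logical ground truth) and `delay_days`
#'   (signed amyloid-minus-blood delay; `NA` when unmeasured).
#' @export
generate_cohort <- function(cfg = generator_config(), seed = cfg$seed) {
  validate_generator_config(cfg)
  with_seed(seed, {
    n <- cfg$n_volunteers + cfg$n_ad + cfg$n_nonad
    if (n == 0L) stopf("empty cohort configuration")
    group <- rep(c("volunteer", "ad", "non_ad"),
                 times = c(cfg$n_volunteers, cfg$n_ad, cfg$n_nonad))

    age <- numeric(n)
    for (g in unique(group)) {
      a <- cfg$age_by_group[[g]]
      age[group == g] <- rnorm_trunc(sum(group == g), a[["mean"]], a[["sd"]], 50)
    }
    sex <- ifelse(stats::runif(n) < cfg$p_female_by_group[group],
                  "female", "male")

    p_pos <- ifelse(group == "volunteer" &
                      is.na(cfg$p_amyloid_by_group[["volunteer"]]),
                    prevalence_at_age(age, cfg$prevalence_by_age),
                    cfg$p_amyloid_by_group[group])
    latent <- stats::runif(n) < p_pos

    ratio <- numeric(n)
    ratio[latent] <- rnorm_trunc(sum(latent), cfg$mu_pos, cfg$sigma_pos, 0)
    ratio[!latent] <- rnorm_trunc(sum(!latent), cfg$mu_neg, cfg$sigma_neg, 0)
    if (cfg$n_outliers > 0) {
      idx <- sample.int(n, min(cfg$n_outliers, n))
      hi <- seq_along(idx) %% 2 == 1
      ratio[idx[hi]] <- stats::runif(sum(hi),
                                     cfg$mu_neg + 10 * cfg$sigma_neg,
                                     cfg$mu_neg + 14 * cfg$sigma_neg)
      ratio[idx[!hi]] <- stats::runif(sum(!hi),
                                      pmax(cfg$mu_pos - 14 * cfg$sigma_pos, 1e-4),
                                      pmax(cfg$mu_pos - 10 * cfg$sigma_pos, 2e-4))
    }
    ab40 <- rnorm_trunc(n, cfg$ab40_mean, cfg$ab40_sd, 0)
    ab42 <- ratio * ab40

    dementia <- stats::runif(n) < cfg$p_dementia_by_group[group]
    mmse <- integer(n)
    nd <- cfg$mmse_params$nondem
    dm <- cfg$mmse_params$dem
    mmse[!dementia] <- pmin(30, pmax(24, round(stats::rnorm(
      sum(!dementia), nd[["mean"]], nd[["sd"]]))))
    mmse[dementia] <- pmin(23, pmax(0, round(stats::rnorm(
      sum(dementia), dm[["mean"]], dm[["sd"]]))))

    carrier <- stats::runif(n) < ifelse(latent, cfg$p_e4_given_pos,
                                        cfg$p_e4_given_neg)
    apoe <- ifelse(carrier,
                   sample(c("e3e4", "e4e4", "e2e4"), n, replace = TRUE,
                          prob = c(0.85, 0.12, 0.03)),
                   sample(c("e3e3", "e2e3", "e2e2"), n, replace = TRUE,
                          prob = c(0.80, 0.18, 0.02)))
    apoe[stats::runif(n) < cfg$p_apoe_missing] <- NA_character_

    measured <- stats::runif(n) < cfg$p_measured_by_group[group]
    observed <- latent
    flip <- measured & stats::runif(n) < cfg$label_noise
    observed[flip] <- !observed[flip]
    use_csf <- stats::runif(n) < cfg$p_csf_modality
    csf <- ifelse(measured & use_csf,
                  ifelse(observed, stats::runif(n, 150, CSF_AB42_CUTOFF - 1),
                         stats::runif(n, CSF_AB42_CUTOFF + 1, 1300)),
                  NA_real_)
    centiloid <- ifelse(measured & !use_csf,
                        ifelse(observed,
                               stats::runif(n, CENTILOID_CUTOFF + 1, 130),
                               stats::runif(n, -15, CENTILOID_CUTOFF)),
                        NA_real_)

    blood_date <- as.Date("2020-01-01") + sample.int(730, n, replace = TRUE)
    long <- stats::runif(n) < cfg$delay$p_long
    mag <- ifelse(long,
                  stats::runif(n, cfg$delay$short_max + 1, cfg$delay$long_max),
                  stats::runif(n, 0, cfg$delay$short_max))
    before <- stats::runif(n) < ifelse(long, cfg$delay$p_before_long,
                                       cfg$delay$p_before_short)
    delay_days <- round(ifelse(before, -mag, mag))
    delay_days[!measured] <- NA_real_
    amyloid_date <- blood_date + delay_days

    cohort <- data.frame(
      id = sprintf("S%04d", seq_len(n)),
      group = group, age = age, sex = sex, mmse = mmse, apoe = apoe,
      ab42_plasma = ab42, ab40_plasma = ab40, ratio = ratio,
      csf_ab42 = csf, centiloid = centiloid,
      blood_date = blood_date, amyloid_date = amyloid_date,
      latent_amyloid = latent, delay_days = delay_days,
      stringsAsFactors = FALSE)
    validate_cohort(cohort)
    cohort
  })
}
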