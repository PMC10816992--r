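#' Cohort data model and classification rules
#'
#' A cohort is a plain `data.frame` with one row per participant and the
#' columns listed below. Missing measurements are `NA`; dates are `Date`.
#'
#' \describe{
#'   \item{id}{unique participant identifier (character)}
#'   \item{group}{`"volunteer"`, `"ad"` or `"non_ad"`}
#'   \item{age}{years}
#'   \item{sex}{`"male"` or `"female"`}
#'   \item{mmse}{Mini-Mental State Examination score, integer 0--30}
#'   \item{apoe}{APOE genotype: `"e2e2"`, `"e2e3"`, `"e3e3"`, `"e2e4"`,
#'     `"e3e4"` or `"e4e4"`}
#'   \item{ab42_plasma, ab40_plasma}{plasma amyloid-beta concentrations, pg/mL}
#'   \item{ratio}{plasma Abeta42/Abeta40 ratio (dimensionless)}
#'   \item{csf_ab42}{CSF Abeta42 concentration, pg/mL}
#'   \item{centiloid}{amyloid-PET Centiloid value}
#'   \item{blood_date, amyloid_date}{dates of the blood draw and of the
#'     CSF/PET amyloid measurement}
#' }
#'
#' @name cohort
NULL

COHORT_FIELDS <- c(
  "id", "group", "age", "sex", "mmse", "apoe",
  "ab42_plasma", "ab40_plasma", "ratio",
  "csf_ab42", "centiloid", "blood_date", "amyloid_date"
)

GROUP_LEVELS <- c("volunteer", "ad", "non_ad")
SEX_LEVELS <- c("male", "female")
APOE_LEVELS <- c("e2e2", "e2e3", "e3e3", "e2e4", "e3e4", "e4e4")
E4_GENOTYPES <- c("e2e4", "e3e4", "e4e4")

#' Default CSF and Centiloid positivity cutoffs
#'
#' CSF Abeta42 below 438 pg/mL, or a Centiloid value above 26, defines
#' amyloid positivity.
#' @export
CSF_AB42_CUTOFF <- 438

#' @rdname CSF_AB42_CUTOFF
#' @export
CENTILOID_CUTOFF <- 26

validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stopf("a cohort must be a data.frame")
  missing_cols <- setdiff(COHORT_FIELDS, names(cohort))
  if (length(missing_cols)) {
    stopf("cohort is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cohort$id)) {
    dup <- unique(cohort$id[duplicated(cohort$id)])
    stopf("duplicate participant id(s): %s", paste(dup, collapse = ", "))
  }
  bad_group <- !is.na(cohort$group) & !cohort$group %in% GROUP_LEVELS
  if (any(bad_group)) stopf("unknown group value(s) in rows: %s",
                            paste(which(bad_group), collapse = ", "))
  bad_apoe <- !is.na(cohort$apoe) & !cohort$apoe %in% APOE_LEVELS
  if (any(bad_apoe)) stopf("unknown APOE genotype in rows: %s",
                           paste(which(bad_apoe), collapse = ", "))
  bad_mmse <- !is.na(cohort$mmse) & (cohort$mmse < 0 | cohort$mmse > 30)
  if (any(bad_mmse)) stopf("MMSE outside [0, 30] in rows: %s",
                           paste(which(bad_mmse), collapse = ", "))
  invisible(cohort)
}

# Fill `ratio` from the two plasma concentrations where it is missing but
# computable.
complete_ratio <- function(cohort) {
  fill <- is.na(cohort$ratio) &
    !is.na(cohort$ab42_plasma) & !is.na(cohort$ab40_plasma)
  cohort$ratio[fill] <- cohort$ab42_plasma[fill] / cohort$ab40_plasma[fill]
  cohort
}

#' Read a cohort table from CSV
#'
#' Column names are mapped onto the canonical fields of [cohort] either
#' directly (when the header already uses the canonical names) or through a
#' mapping `list(field = "column in file", ...)`, which may also be given as
#' a YAML file path. The ratio is computed from the two plasma
#' concentrations wherever it is absent but computable. Numeric cells that
#' fail to parse are reported with their row index.
#'
#' @param path path to a CSV file.
#' @param mapping optional named list or YAML file path mapping canonical
#'   field names to the column names used in the file.
#' @return a cohort `data.frame` (see [cohort]).
#' @examples
#' path <- system.file("extdata", "example_cohort.csv", package = "abratio")
#' cohort <- read_cohort(path)
#' annotate_cohort(cohort)[, c("id", "ratio", "amyloid_status", "eligible")]
#' @export
read_cohort <- function(path, mapping = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- yaml::read_yaml(mapping)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(mapping)) {
    unknown <- setdiff(names(mapping), COHORT_FIELDS)
    if (length(unknown)) stopf("mapping refers to unknown field(s): %s",
                               paste(unknown, collapse = ", "))
    for (field in names(mapping)) {
      col <- mapping[[field]]
      if (!col %in% names(raw)) stopf("mapped column '%s' not in file", col)
      names(raw)[names(raw) == col] <- field
    }
  }
  out <- data.frame(id = character(nrow(raw)), stringsAsFactors = FALSE)
  get_col <- function(field) if (field %in% names(raw)) raw[[field]] else
    rep(NA_character_, nrow(raw))
  parse_num <- function(field) {
    x <- trimws(get_col(field))
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) stopf("malformed numeric value for '%s' in row(s): %s",
                           field, paste(bad, collapse = ", "))
    out
  }
  parse_date <- function(field) {
    x <- trimws(get_col(field))
    x[x == ""] <- NA_character_
    out <- as.Date(x, format = "%Y-%m-%d")
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) stopf("malformed date for '%s' in row(s): %s (expected YYYY-MM-DD)",
                           field, paste(bad, collapse = ", "))
    out
  }
  parse_chr <- function(field) {
    x <- trimws(get_col(field))
    x[x == ""] <- NA_character_
    x
  }
  out$id <- parse_chr("id")
  out$group <- parse_chr("group")
  out$age <- parse_num("age")
  out$sex <- parse_chr("sex")
  out$mmse <- parse_num("mmse")
  out$apoe <- parse_chr("apoe")
  out$ab42_plasma <- parse_num("ab42_plasma")
  out$ab40_plasma <- parse_num("ab40_plasma")
  out$ratio <- parse_num("ratio")
  out$csf_ab42 <- parse_num("csf_ab42")
  out$centiloid <- parse_num("centiloid")
  out$blood_date <- parse_date("blood_date")
  out$amyloid_date <- parse_date("amyloid_date")
  out <- complete_ratio(out)
  validate_cohort(out)
  out
}

#' Write a cohort table to CSV
#'
#' Round-trips through [read_cohort()] without loss: all fields, including
#' any appended annotation columns, are written as plain text.
#'
#' @param cohort a cohort `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Ground-truth amyloid call from CSF or PET
#'
#' CSF Abeta42 below 438 pg/mL, or Centiloid above 26, is amyloid positive;
#' a measured value on the other side of its cutoff is negative; with
#' neither measurement the status is unknown. When both modalities are
#' present the `precedence` modality decides (CSF by default); a
#' disagreement between the two is flagged in the `discordant` column.
#'
#' @param cohort a cohort `data.frame` (or any data.frame with `csf_ab42`
#'   and `centiloid` columns).
#' @param precedence which modality decides when both are measured.
#' @param csf_cutoff,centiloid_cutoff positivity cutoffs.
#' @return a `data.frame` with columns `status` (`"positive"`, `"negative"`,
#'   `"unknown"`), `modality` (`"csf"`, `"pet"`, `"none"`) and `discordant`.
#' @export
call_amyloid <- function(cohort, precedence = c("csf", "pet"),
                         csf_cutoff = CSF_AB42_CUTOFF,
                         centiloid_cutoff = CENTILOID_CUTOFF) {
  precedence <- match.arg(precedence)
  csf <- cohort$csf_ab42
  cl <- cohort$centiloid
  csf_status <- ifelse(is.na(csf), NA_character_,
                       ifelse(csf < csf_cutoff, "positive", "negative"))
  pet_status <- ifelse(is.na(cl), NA_character_,
                       ifelse(cl > centiloid_cutoff, "positive", "negative"))
  first <- if (precedence == "csf") csf_status else pet_status
  second <- if (precedence == "csf") pet_status else csf_status
  status <- ifelse(!is.na(first), first,
                   ifelse(!is.na(second), second, "unknown"))
  modality <- ifelse(!is.na(first), precedence,
                     ifelse(!is.na(second),
                            setdiff(c("csf", "pet"), precedence), "none"))
  discordant <- !is.na(csf_status) & !is.na(pet_status) &
    csf_status != pet_status
  data.frame(status = status, modality = modality, discordant = discordant,
             stringsAsFactors = FALSE)
}

na_or_error <- function(x, missing, what, na_action) {
  na_action <- match.arg(na_action, c("error", "na"))
  if (any(missing) && na_action == "error") {
    stopf("missing %s in row(s): %s -- status undecidable",
          what, paste(utils::head(which(missing), 10), collapse = ", "))
  }
  x[missing] <- NA
  x
}

#' Dementia classification from the MMSE
#'
#' A participant is classified as having dementia when the MMSE score is
#' below 24/30, and as without dementia at 24 or above.
#'
#' @param cohort a cohort `data.frame` (needs an `mmse` column).
#' @param na_action `"error"` (default) raises on missing MMSE because the
#'   subgrouping downstream depends on it; `"na"` propagates `NA`.
#' @return logical vector, `TRUE` = dementia.
#' @export
has_dementia <- function(cohort, na_action = c("error", "na")) {
  na_or_error(cohort$mmse < 24, is.na(cohort$mmse), "MMSE", na_action)
}

#' APOE epsilon-4 carrier status
#'
#' Carriers hold at least one epsilon-4 allele (genotypes e2e4, e3e4, e4e4);
#' noncarriers are e2e2, e2e3 and e3e3.
#'
#' @inheritParams has_dementia
#' @return logical vector, `TRUE` = epsilon-4 carrier.
#' @export
is_e4_carrier <- function(cohort, na_action = c("error", "na")) {
  bad <- !is.na(cohort$apoe) & !cohort$apoe %in% APOE_LEVELS
  if (any(bad)) stopf("unknown APOE genotype in row(s): %s",
                      paste(which(bad), collapse = ", "))
  na_or_error(cohort$apoe %in% E4_GENOTYPES, is.na(cohort$apoe),
              "APOE genotype", na_action)
}

#' Eligibility of the amyloid reference measurement
#'
#' A participant with a known amyloid status is eligible for the supervised
#' analyses when at most `window_days` separate the blood draw and the
#' CSF/PET measurement, in either direction. One exception: a positive
#' amyloid measurement performed *before* the blood draw remains valid at
#' any delay, since an amyloid-positive individual stays positive.
#' Participants with unknown status are ineligible.
#'
#' @param cohort a cohort `data.frame`.
#' @param window_days maximum absolute delay in days (default 730, i.e. two
#'   365-day years).
#' @param amyloid optional precomputed result of [call_amyloid()].
#' @return logical vector, `TRUE` = eligible.
#' @export
is_eligible <- function(cohort, window_days = 730, amyloid = NULL) {
  if (is.null(amyloid)) amyloid <- call_amyloid(cohort)
  status <- amyloid$status
  known <- status != "unknown"
  miss_date <- known & (is.na(cohort$blood_date) | is.na(cohort$amyloid_date))
  if (any(miss_date)) {
    stopf("amyloid status known but date(s) missing in row(s): %s",
          paste(which(miss_date), collapse = ", "))
  }
  delay <- as.numeric(cohort$amyloid_date - cohort$blood_date)
  within <- known & abs(delay) <= window_days
  exception <- known & delay < 0 & status == "positive"
  out <- within | exception
  out[!known] <- FALSE
  out
}

#' Annotate a cohort with derived classification columns
#'
#' Appends `amyloid_status`, `modality`, `dementia`, `e4_carrier` and
#' `eligible` to the cohort, using [call_amyloid()], [has_dementia()],
#' [is_e4_carrier()] and [is_eligible()]. Missing MMSE or APOE propagate as
#' `NA` here (the strict per-participant rules are available through the
#' individual functions).
#'
#' @inheritParams is_eligible
#' @inheritParams call_amyloid
#' @return the cohort with the five columns appended.
#' @export
annotate_cohort <- function(cohort, window_days = 730,
                            precedence = c("csf", "pet")) {
  validate_cohort(complete_ratio(cohort))
  amyloid <- call_amyloid(cohort, precedence = precedence)
  cohort <- complete_ratio(cohort)
  cohort$amyloid_status <- amyloid$status
  cohort$modality <- amyloid$modality
  cohort$dementia <- has_dementia(cohort, na_action = "na")
  cohort$e4_carrier <- is_e4_carrier(cohort, na_action = "na")
  cohort$eligible <- is_eligible(cohort, window_days, amyloid = amyloid)
  if (any(amyloid$discordant)) {
    warning(sprintf("CSF and PET disagree for %d participant(s); '%s' took precedence",
                    sum(amyloid$discordant), match.arg(precedence)),
            call. = FALSE)
  }
  cohort
}
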