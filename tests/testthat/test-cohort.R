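write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("reading a cohort fills the ratio and maps columns", {
  path <- write_fixture_csv(c(
    "id,group,age,sex,mmse,apoe,ab42_plasma,ab40_plasma,ratio,csf_ab42,centiloid,blood_date,amyloid_date",
    "P001,volunteer,62,female,29,e3e3,18.9,400,,,,2021-03-01,",
    "P002,ad,75,male,21,e3e4,15.2,380,0.04,300,,2021-04-01,2021-05-01",
    "P003,non_ad,68,male,26,,,,0.051,,12,2021-05-01,2021-06-01"))
  co <- read_cohort(path)
  expect_equal(nrow(co), 3L)
  expect_equal(co$ratio[1], 18.9 / 400)
  expect_equal(co$ratio[1], 0.04725)
  expect_equal(co$ratio[2], 0.04)  # explicit ratio wins over recomputation
  expect_true(is.na(co$apoe[3]))
  expect_s3_class(co$blood_date, "Date")
})

test_that("a column mapping renames file headers onto canonical fields", {
  path <- write_fixture_csv(c(
    "subject,cohort_arm,AB42,AB40",
    "P001,volunteer,18.9,400"))
  co <- read_cohort(path, mapping = list(id = "subject", group = "cohort_arm",
                                         ab42_plasma = "AB42",
                                         ab40_plasma = "AB40"))
  expect_equal(co$id, "P001")
  expect_equal(co$ratio, 0.04725)
  expect_error(read_cohort(path, mapping = list(nonsense = "subject")),
               "unknown field")
})

test_that("malformed and degenerate inputs are rejected with row context", {
  dup <- write_fixture_csv(c("id,group", "P001,volunteer", "P001,ad"))
  expect_error(read_cohort(dup), "duplicate participant id")
  bad <- write_fixture_csv(c("id,mmse", "P001,high"))
  expect_error(read_cohort(bad), "malformed numeric.*row")
  empty <- write_fixture_csv("id,group,age")
  expect_equal(nrow(read_cohort(empty)), 0L)
})

test_that("cohorts round-trip through CSV without loss", {
  co <- generate_cohort(paper_like_config(), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  for (f in setdiff(names(back), c("blood_date", "amyloid_date"))) {
    expect_equal(back[[f]], co[[f]], info = f)
  }
  expect_equal(as.character(back$blood_date), as.character(co$blood_date))
  expect_equal(as.character(back$amyloid_date), as.character(co$amyloid_date))
})

test_that("amyloid calls follow the CSF and Centiloid cutoffs exactly", {
  co <- data.frame(csf_ab42 = c(437, 438, NA, NA, NA, 300),
                   centiloid = c(NA, NA, 26, 26.01, NA, 40))
  call <- call_amyloid(co)
  expect_equal(call$status,
               c("positive", "negative", "negative", "positive", "unknown",
                 "positive"))
  expect_equal(call$modality, c("csf", "csf", "pet", "pet", "none", "csf"))
  expect_false(any(call$discordant[1:5]))
})

test_that("modality precedence is configurable and discordance is flagged", {
  co <- data.frame(csf_ab42 = 400, centiloid = 10)  # CSF says +, PET says -
  expect_equal(call_amyloid(co, precedence = "csf")$status, "positive")
  expect_equal(call_amyloid(co, precedence = "pet")$status, "negative")
  expect_true(call_amyloid(co)$discordant)
})

test_that("dementia and APOE-e4 rules match their boundaries", {
  co <- data.frame(mmse = c(23, 24, 30, NA),
                   apoe = c("e2e4", "e3e3", "e4e4", NA))
  expect_equal(has_dementia(co, na_action = "na"),
               c(TRUE, FALSE, FALSE, NA))
  expect_equal(is_e4_carrier(co, na_action = "na"),
               c(TRUE, FALSE, TRUE, NA))
  expect_error(has_dementia(co), "missing MMSE")
  expect_error(is_e4_carrier(co), "missing APOE")
  expect_error(is_e4_carrier(data.frame(apoe = "e5e5")), "unknown APOE")
})

test_that("eligibility honours the window and the prior-positive exception", {
  blood <- as.Date("2022-01-01")
  co <- data.frame(
    csf_ab42 = c(300, 500, 300, 300, 500),
    centiloid = NA_real_,
    blood_date = blood,
    amyloid_date = blood + c(-1095, -1095, 0, 1095, 365))
  elig <- is_eligible(co)
  # 3y-old positive kept by exception; 3y-old negative dropped; same-day
  # kept; positive 3y after blood dropped; negative within window kept.
  expect_equal(elig, c(TRUE, FALSE, TRUE, FALSE, TRUE))
})

test_that("eligibility errors when a labeled participant has no dates", {
  co <- data.frame(csf_ab42 = 300, centiloid = NA_real_,
                   blood_date = as.Date(NA), amyloid_date = as.Date(NA))
  expect_error(is_eligible(co), "date")
  unk <- data.frame(csf_ab42 = NA_real_, centiloid = NA_real_,
                    blood_date = as.Date(NA), amyloid_date = as.Date(NA))
  expect_false(is_eligible(unk))
})

test_that("the eligibility filter retains exactly the brute-force subset", {
  co <- generate_cohort(paper_like_config(), seed = 17)
  call <- call_amyloid(co)
  got <- is_eligible(co, window_days = 730, amyloid = call)
  expected <- vapply(seq_len(nrow(co)), function(i) {
    if (call$status[i] == "unknown") return(FALSE)
    d <- as.numeric(co$amyloid_date[i] - co$blood_date[i])
    abs(d) <= 730 || (d < 0 && call$status[i] == "positive")
  }, logical(1))
  expect_equal(got, expected)
  expect_gt(sum(got), 0)
})

test_that("annotation appends derived columns consistent with the rules", {
  co <- generate_cohort(paper_like_config(), seed = 5)
  ann <- annotate_cohort(co)
  expect_true(all(c("amyloid_status", "modality", "dementia", "e4_carrier",
                    "eligible") %in% names(ann)))
  known <- ann$amyloid_status != "unknown"
  # generator draws reference values consistent with the latent status
  expect_equal(ann$amyloid_status[known],
               ifelse(co$latent_amyloid[known], "positive", "negative"))
  expect_equal(ann$dementia, co$mmse < 24)
})
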