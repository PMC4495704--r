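test_that("load_cohort parses well-formed admission and event files", {
  adm <- make_admissions(3L)
  ev <- make_events(c("A001", "A001", "A002"),
                    c("radiography", "dopamine", "sputum_suction"),
                    c(0L, 0L, 1L), c("procedure", "drug", "procedure"))
  af <- withr::local_tempfile(fileext = ".csv")
  ef <- withr::local_tempfile(fileext = ".csv")
  write.csv(adm, af, row.names = FALSE)
  write.csv(ev, ef, row.names = FALSE)

  cohort <- load_cohort(af, ef)
  expect_s3_class(cohort, "si_cohort")
  expect_equal(nrow(cohort$admissions), 3L)
  expect_equal(nrow(cohort$events), 3L)
  expect_equal(cohort$admissions$age_years, adm$age_years)
  expect_equal(cohort$admissions$death, adm$death)
})

test_that("load_cohort applies a column-mapping schema and packed events", {
  adm <- make_admissions(2L)
  names(adm)[names(adm) == "death"] <- "died"
  adm$evts <- c("radiography|0|procedure;dopamine|0|drug", "")
  af <- withr::local_tempfile(fileext = ".csv")
  write.csv(adm, af, row.names = FALSE)

  cohort <- load_cohort(af, schema = list(
    admissions = c(death = "died"), packed_events = "evts"))
  expect_equal(nrow(cohort$events), 2L)
  expect_equal(cohort$events$code, c("radiography", "dopamine"))
  expect_true(all(cohort$events$day == 0L))
})

test_that("load_cohort rejects schema and row-level defects informatively", {
  adm <- make_admissions(3L)
  af <- withr::local_tempfile(fileext = ".csv")
  write.csv(adm[, setdiff(names(adm), "death")], af, row.names = FALSE)
  expect_error(load_cohort(af), "death")

  write.csv(adm, af, row.names = FALSE)
  ev <- make_events("A001", c("radiography", "ecg"), c(0L, 0L))
  ev$day <- c("0", "x")
  ef <- withr::local_tempfile(fileext = ".csv")
  write.csv(ev, ef, row.names = FALSE)
  expect_error(load_cohort(af, ef), "line 3.*'x'")

  adm$age_years[2] <- "unknown"
  write.csv(adm, af, row.names = FALSE)
  expect_error(load_cohort(af), "line 3.*unknown")
})

test_that("exclusion rules remove ICU, life-support and under-18 records
           with a disjoint tally", {
  adm <- make_admissions(10L)
  adm$age_years <- rep(74L, 10L)
  adm$icu_day0 <- c(TRUE, TRUE, rep(FALSE, 8L))
  adm$life_support_day0 <- c(TRUE, FALSE, TRUE, rep(FALSE, 7L))
  cohort <- si_cohort(adm)

  res <- apply_exclusions(cohort)
  expect_equal(nrow(res$cohort$admissions), 7L)
  # ICU takes precedence when both flags are set
  expect_equal(res$tally,
               c(icu = 2L, life_support = 1L, under_18 = 0L))
  expect_equal(sum(res$tally) + nrow(res$cohort$admissions), 10L)

  # kept record: both flags false, age 74
  expect_true("A004" %in% res$cohort$admissions$admission_id)

  # applying exclusions again is a fixed point
  res2 <- apply_exclusions(res$cohort)
  expect_equal(res2$cohort$admissions, res$cohort$admissions)
  expect_equal(sum(res2$tally), 0L)

  adm$icu_day0 <- FALSE
  adm$life_support_day0 <- FALSE
  adm$age_years[1] <- 17L
  res3 <- apply_exclusions(si_cohort(adm))
  expect_equal(res3$tally[["under_18"]], 1L)
})

test_that("age bands close on the left and match the printed labels", {
  expect_equal(as.character(age_category(c(18, 59, 60, 69, 70, 79, 80,
                                           89, 90, 101))),
               c("<60", "<60", "60-69", "60-69", "70-79", "70-79",
                 "80-89", "80-89", ">=90", ">=90"))
})

test_that("feature extraction honours the day-0 rule and composites", {
  adm <- make_admissions(3L)
  ev <- make_events(
    c("A001", "A001", "A002", "A003"),
    c("dopamine", "radiography", "dopamine", "vasopressin"),
    c(0L, 0L, 2L, 0L),
    c("drug", "procedure", "drug", "drug"))
  feats <- extract_features(si_cohort(adm, ev))

  # day-0 dopamine counts for the catecholamine composite; day-2 does not
  expect_equal(feats$catecholamines_or_vasopressin, c(1L, 0L, 1L))
  expect_equal(feats$radiography, c(1L, 0L, 0L))
  expect_equal(feats$sputum_suction, c(0L, 0L, 0L))
  expect_equal(as.character(feats$cci_category), c("0", "2", ">=3"))
  expect_equal(feats$death, adm$death)
})

test_that("feature extraction is idempotent and event-order insensitive", {
  adm <- make_admissions(4L)
  ev <- make_events(
    c("A001", "A001", "A002", "A004", "A004"),
    c("radiography", "dopamine", "sputum_suction", "radiography",
      "radiography"),
    c(0L, 0L, 0L, 0L, 0L))
  a <- extract_features(si_cohort(adm, ev))
  b <- extract_features(si_cohort(adm, ev[rev(seq_len(nrow(ev))), ]))
  expect_equal(a, b)
  # duplicated events do not change the indicator
  expect_equal(a$radiography[4], 1L)
})

test_that("unknown diagnosis labels are rejected", {
  adm <- make_admissions(2L)
  adm$diagnosis[2] <- "appendicitis"
  expect_error(extract_features(si_cohort(adm)), "appendicitis")
})

test_that("a cohort without any CCI source is rejected", {
  adm <- make_admissions(2L)
  adm$cci <- NULL
  expect_error(extract_features(si_cohort(adm)), "CCI")
  # explicit cci vector works
  feats <- extract_features(si_cohort(adm), cci = c(1, 3))
  expect_equal(as.character(feats$cci_category), c("1", ">=3"))
})
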