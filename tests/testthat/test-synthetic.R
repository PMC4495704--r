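test_that("the same seed reproduces the cohort exactly", {
  cfg <- synthetic_config(n = 2000L)
  a <- generate_cohort(cfg, seed = 5L)
  b <- generate_cohort(cfg, seed = 5L)
  expect_equal(a$admissions, b$admissions)
  expect_equal(a$events, b$events)
  c_ <- generate_cohort(cfg, seed = 6L)
  expect_false(identical(a$admissions$death, c_$admissions$death))
})

test_that("marginal prevalences and mortality match the configuration", {
  cohort <- shared_synth()  # n = 50000, fixed seed
  cfg <- synthetic_config(n = 50000L)
  n <- nrow(cohort$admissions)

  # overall mortality close to the 9.5% target
  expect_lt(abs(mean(cohort$admissions$death) - 0.095), 0.01)

  feats <- extract_features(cohort)
  for (j in seq_len(nrow(cfg$procedures))) {
    p <- cfg$procedures$prevalence[j]
    emp <- mean(feats[[cfg$procedures$name[j]]])
    expect_lt(abs(emp - p), 4 * sqrt(p * (1 - p) / n))
  }

  # demographic marginals
  expect_lt(abs(mean(cohort$admissions$sex == "male") - 0.575), 0.01)
  expect_lt(max(abs(prop.table(table(feats$diagnosis)) -
                      cfg$diagnosis_probs)), 0.01)
})

test_that("co-occurrence blocks induce the intended phi structure", {
  cohort <- shared_synth()
  cfg <- synthetic_config()
  feats <- extract_features(cohort)
  pr <- cfg$procedures
  members <- split(pr$name, pr$block)
  phi <- phi_matrix(feats[, pr$name[!is.na(pr$block)]])
  for (b in names(members)) {
    within <- phi[members[[b]], members[[b]]]
    expect_gt(min(within[upper.tri(within)]), 0.6)
  }
  cross <- phi
  for (b in names(members)) cross[members[[b]], members[[b]]] <- 0
  expect_lt(max(cross), 0.3)
})

test_that("events round-trip through the CSV interface", {
  cfg <- synthetic_config(n = 400L)
  cohort <- generate_cohort(cfg, seed = 12L)
  af <- withr::local_tempfile(fileext = ".csv")
  ef <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, af, ef)
  back <- load_cohort(af, ef)
  f1 <- extract_features(cohort)
  f2 <- extract_features(back)
  cols <- c("admission_id", "diagnosis", "sex", "age_category",
            "cci_category", "death", attr(f1, "feature_names"))
  expect_equal(f2[cols], f1[cols])
})

test_that("later-day noise events never reach the day-0 indicators", {
  cfg <- synthetic_config(n = 1500L)
  cohort <- generate_cohort(cfg, seed = 21L)
  expect_gt(sum(cohort$events$day > 0L), 0L)
  feats <- extract_features(cohort)
  trimmed <- cohort
  trimmed$events <- trimmed$events[trimmed$events$day == 0L, ]
  expect_equal(extract_features(trimmed), feats)
})

test_that("the drug composite is emitted as individual drug codes", {
  cfg <- synthetic_config(n = 3000L)
  cohort <- generate_cohort(cfg, seed = 31L)
  expect_false("catecholamines_or_vasopressin" %in% cohort$events$code)
  expect_gt(sum(cohort$events$code %in% cfg$drug_codes), 0L)
  feats <- extract_features(cohort)
  expect_gt(mean(feats$catecholamines_or_vasopressin), 0.02)
})

test_that("the configuration validates probabilities and round-trips
           through JSON", {
  cfg <- synthetic_config(n = 1000L)
  bad <- cfg
  bad$diagnosis_probs[1] <- 2
  expect_error(generate_cohort(bad, seed = 1L), "summing to 1")

  path <- withr::local_tempfile(fileext = ".json")
  write_synth_config(cfg, path)
  back <- read_synth_config(path)
  expect_equal(back$procedures, cfg$procedures, tolerance = 1e-12)
  expect_equal(back$truth, cfg$truth, tolerance = 1e-12)
  expect_equal(back$diagnosis_probs, cfg$diagnosis_probs,
               tolerance = 1e-12)
  # a round-tripped configuration drives the generator identically
  expect_equal(generate_cohort(back, seed = 3L)$admissions,
               generate_cohort(cfg, seed = 3L)$admissions)
})

test_that("a null procedure model earns (almost) no points", {
  cfg <- synthetic_config(n = 20000L)
  cfg$truth$procedures <- lapply(cfg$truth$procedures, function(x) 0)
  cohort <- generate_cohort(cfg, seed = 55L)
  fit <- suppressWarnings(suppressMessages(derive_index(cohort)))
  # each candidate clears the 0.05 gate with probability ~0.05 under the
  # null, so more than a handful of scored procedures would be surprising
  expect_lte(length(fit$points), 5L)
})

test_that("exclusion flags appear at the configured rates", {
  cfg <- synthetic_config(n = 20000L, p_icu = 0.05,
                          p_life_support = 0.02)
  cohort <- generate_cohort(cfg, seed = 61L)
  res <- apply_exclusions(cohort)
  expect_lt(abs(res$tally[["icu"]] / 20000 - 0.05), 0.01)
  expect_gt(res$tally[["life_support"]], 0L)
  expect_equal(sum(res$tally) + nrow(res$cohort$admissions), 20000L)
})
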