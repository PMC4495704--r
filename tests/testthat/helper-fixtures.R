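# Small hand-built fixtures shared across test files.

make_admissions <- function(n = 6L) {
  data.frame(
    admission_id = sprintf("A%03d", seq_len(n)),
    diagnosis = rep(c("pneumonia", "septicemia",
                      "congestive_heart_failure"), length.out = n),
    age_years = rep(c(74L, 45L, 90L), length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    cci = rep(c(0, 2, 5), length.out = n),
    death = rep(c(0L, 1L), length.out = n),
    stringsAsFactors = FALSE)
}

make_events <- function(ids, codes, days, kinds = "procedure") {
  data.frame(admission_id = ids, code = codes, day = as.integer(days),
             kind = kinds, stringsAsFactors = FALSE)
}

make_cohort <- function(n = 6L, events = NULL) {
  si_cohort(make_admissions(n), events)
}

# a small feature table with known indicator columns
make_features <- function(n = 200L, p = c(f1 = 0.5, f2 = 0.3, f3 = 0.2),
                          seed = 42L) {
  set.seed(seed)
  out <- data.frame(
    admission_id = sprintf("A%04d", seq_len(n)),
    diagnosis = factor(sample(default_diagnoses_test(), n,
                              replace = TRUE),
                       levels = default_diagnoses_test()),
    sex = factor(sample(c("male", "female"), n, replace = TRUE),
                 levels = c("male", "female")),
    age_category = age_category(sample(30:95, n, replace = TRUE)),
    cci_category = cci_category(sample(0:4, n, replace = TRUE)),
    death = rbinom(n, 1L, 0.3),
    stringsAsFactors = FALSE)
  for (nm in names(p)) out[[nm]] <- rbinom(n, 1L, p[[nm]])
  attr(out, "feature_names") <- names(p)
  attr(out, "strata_names") <- character()
  out
}

default_diagnoses_test <- function() {
  c("acute_myocardial_infarction", "congestive_heart_failure",
    "acute_cerebrovascular_disease", "gastrointestinal_hemorrhage",
    "pneumonia", "septicemia")
}

# minimal mortality_fit stand-in for testing the point-assignment rules
fake_fit <- function(terms, estimates, ps) {
  structure(list(coefficients = data.frame(
    term = terms, estimate = estimates, se = NA_real_, z = NA_real_,
    p = ps, stringsAsFactors = FALSE)), class = "mortality_fit")
}

# one shared mid-size synthetic cohort for the heavier structure checks
shared_synth <- local({
  cache <- NULL
  function(n = 50000L, seed = 2024L) {
    if (is.null(cache)) {
      cache <<- generate_cohort(synthetic_config(n = n), seed = seed)
    }
    cache
  }
})

# brute-force c-statistic: all event/non-event pairs
bruteforce_auc <- function(p, y) {
  ev <- p[y == 1]
  ne <- p[y == 0]
  tot <- 0
  for (e in ev) tot <- tot + sum(e > ne) + 0.5 * sum(e == ne)
  tot / (length(ev) * length(ne))
}
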