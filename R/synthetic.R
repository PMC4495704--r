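#' Synthetic administrative cohort configuration
#'
#' Builds the configuration for the seeded cohort generator.  The defaults
#' emulate the derivation study's eligible cohort: six
#' admission-precipitating diagnoses, five age bands, sex and CCI-category
#' marginals at the published proportions; 40 admission-day procedure
#' indicators at the published prevalences (38 screened procedures plus two
#' deliberately rare ones); five co-occurrence blocks driven by shared
#' latent binary causes, producing within-block phi coefficients above the
#' 0.6 grouping threshold; and in-hospital death drawn from a logistic
#' model whose coefficients are the published ones
#' ([published_coefficients()]).
#'
#' Marginal (screening-stage) procedure-death associations are induced by a
#' standard-normal per-admission severity factor: each procedure loads on
#' it with `loading = (published marginal log-odds ratio - true conditional
#' coefficient) / confounding_scale`, so routinely performed procedures
#' with protective conditional coefficients still show the positive
#' marginal association that carries them through the screen, exactly as
#' in the source data.  `confounding_scale` is the marginal log-odds shift
#' induced per unit loading; its default was calibrated once against the
#' generator itself, as was the model intercept (targeting the published
#' 9.5 percent in-hospital mortality).
#'
#' @param n Cohort size.
#' @param confounding_scale Marginal log-odds shift per unit severity
#'   loading.
#' @param intercept True-model intercept; the default reproduces ~9.5%
#'   mortality under the default marginals (see [calibrate_intercept()]).
#' @param block_log_odds Within-block log-odds bump while the block latent
#'   is on.
#' @param p_icu,p_life_support,p_under_18 Fractions of admissions flagged
#'   for the three exclusion rules (defaults 0: the generator emulates the
#'   post-exclusion eligible cohort).
#' @param extra_event_rate Fraction of admissions receiving 1-3 additional
#'   later-day (day 1-5) events, which feature extraction must ignore.
#' @param seed Default seed used by [generate_cohort()] when none is given.
#' @return An object of class `si_synth_config`.
#' @export
synthetic_config <- function(n = 200000L,
                             confounding_scale = 0.33,
                             max_loading = 1.5,
                             intercept = -3.43,
                             block_log_odds = 9,
                             p_icu = 0, p_life_support = 0,
                             p_under_18 = 0,
                             extra_event_rate = 0.3,
                             seed = 1L) {
  stopifnot(n > 0)
  counts <- published_screen_counts()
  n_der <- attr(counts, "n_surviving") + attr(counts, "n_deceased")
  pub <- published_coefficients()

  blocks_of <- c(
    blood_chemistry_tests = "blood", hematology_tests = "blood",
    plasma_protein_immunology_tests = "blood",
    urine_tests_general = "urine", urine_microscopy = "urine",
    bacterial_microscopy = "microbio", bacterial_culture = "microbio",
    central_venous_infusion = "cv",
    central_venous_catheter_insertion = "cv",
    oxygen_administration = "oxygen", pulse_oximetry = "oxygen")

  # effective conditional log-odds per raw procedure: the coefficient of
  # the consolidated variable it feeds (0 for null procedures)
  proc_beta <- stats::setNames(pub$beta[pub$type == "procedure"],
                               pub$term[pub$type == "procedure"])
  member_of <- c(
    blood_chemistry_tests = "blood_tests_excl_coagulation",
    hematology_tests = "blood_tests_excl_coagulation",
    plasma_protein_immunology_tests = "blood_tests_excl_coagulation",
    urine_tests_general = "urinalyses_excl_chemistry",
    urine_microscopy = "urinalyses_excl_chemistry",
    bacterial_microscopy = "bacterial_microscopy_or_culture",
    bacterial_culture = "bacterial_microscopy_or_culture",
    central_venous_infusion = "central_venous_catheter_insertion",
    oxygen_administration = "pulse_oximetry")

  prevalence <- (counts$surviving_n + counts$deceased_n) / n_der
  marginal <- log((counts$deceased_n /
                     (attr(counts, "n_deceased") - counts$deceased_n)) /
                    (counts$surviving_n /
                       (attr(counts, "n_surviving") - counts$surviving_n)))
  eff <- proc_beta[ifelse(counts$procedure %in% names(member_of),
                          member_of[counts$procedure],
                          counts$procedure)]
  eff[is.na(eff)] <- 0
  procedures <- data.frame(
    name = counts$procedure,
    prevalence = prevalence,
    block = ifelse(counts$procedure %in% names(blocks_of),
                   blocks_of[counts$procedure], NA_character_),
    loading = pmin(pmax((marginal - unname(eff)) / confounding_scale,
                        -max_loading), max_loading),
    stringsAsFactors = FALSE)
  # strong acute interventions are the main carriers of the latent
  # severity that confounds the routine procedures, so their loadings
  # saturate the cap even where marginal matching alone would not need it
  strong <- is.na(procedures$block) & unname(eff) >= 0.5
  procedures$loading[strong] <- max_loading
  procedures <- rbind(procedures, data.frame(
    name = c("bronchoscopy", "hemodialysis"),
    prevalence = c(0.004, 0.006), block = NA_character_,
    loading = c(0.3, 0.3), stringsAsFactors = FALSE))
  # rare co-occurrence block: keep the severity loading moderate so the
  # shared latent cause, not the severity factor, dominates and the
  # within-block phi stays above the 0.6 grouping threshold
  cv <- procedures$block %in% "cv"
  procedures$loading[cv] <- pmin(procedures$loading[cv], 0.7)

  block_prob <- vapply(split(procedures$prevalence, procedures$block),
                       function(p) 0.97 * min(p), numeric(1L))
  # the block latent (the decision to order the whole panel) itself loads
  # on severity: members inherit the confounding undiluted even though
  # their own indicator is mostly explained by the latent cause
  block_loading <- vapply(split(procedures$loading, procedures$block),
                          mean, numeric(1L))
  blocks <- data.frame(block = names(block_prob),
                       prob = unname(block_prob),
                       log_odds = block_log_odds,
                       loading = unname(block_loading[names(block_prob)]),
                       stringsAsFactors = FALSE)

  truth <- list(
    intercept = intercept,
    diagnosis = stats::setNames(pub$beta[pub$type == "diagnosis"],
                                pub$term[pub$type == "diagnosis"]),
    sex_female = pub$beta[pub$term == "sex_female"],
    age = stats::setNames(pub$beta[pub$type == "age"],
                          c("60-69", "70-79", "80-89", ">=90")),
    cci = stats::setNames(pub$beta[pub$type == "cci"],
                          c("1", "2", ">=3")),
    procedures = as.list(proc_beta))

  structure(list(
    n = as.integer(n),
    diagnosis_probs = c(acute_myocardial_infarction = 20597,
                        congestive_heart_failure = 113897,
                        acute_cerebrovascular_disease = 180054,
                        gastrointestinal_hemorrhage = 69502,
                        pneumonia = 136773, septicemia = 18562) / 539385,
    age_probs = c("<60" = 74788, "60-69" = 94068, "70-79" = 146977,
                  "80-89" = 169929, ">=90" = 53623) / 539385,
    p_male = 0.575,
    cci_probs = c("0" = 323635, "1" = 68322, "2" = 105529,
                  ">=3" = 41899) / 539385,
    strata_probs = c(ambulance = 0.38, referral = 0.40,
                     academic = 0.127),
    procedures = procedures,
    blocks = blocks,
    member_of = as.list(member_of),
    truth = truth,
    confounding_scale = confounding_scale,
    max_loading = max_loading,
    p_icu = p_icu, p_life_support = p_life_support,
    p_under_18 = p_under_18,
    extra_event_rate = extra_event_rate,
    drug_codes = c("epinephrine", "norepinephrine", "dopamine",
                   "dobutamine", "vasopressin"),
    seed = as.integer(seed)),
    class = "si_synth_config")
}

#' @export
print.si_synth_config <- function(x, ...) {
  cat("Synthetic cohort configuration: n =", x$n, "\n")
  cat("  procedures:", nrow(x$procedures), " blocks:",
      nrow(x$blocks), "\n")
  cat("  true intercept:", x$truth$intercept,
      " confounding scale:", x$confounding_scale, "\n")
  invisible(x)
}

#' Read or write a synthetic configuration as JSON
#'
#' @param config An `si_synth_config`.
#' @param path File path.
#' @return `read_synth_config()` returns an `si_synth_config`.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "si_synth_config"))
  x <- unclass(config)
  # named atomic vectors must become objects, not bare arrays
  for (f in c("diagnosis_probs", "age_probs", "cci_probs",
              "strata_probs")) {
    x[[f]] <- as.list(x[[f]])
  }
  for (f in c("diagnosis", "age", "cci")) {
    x$truth[[f]] <- as.list(x$truth[[f]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("diagnosis_probs", "age_probs", "cci_probs", "strata_probs")) {
    x[[f]] <- unlist(x[[f]])
  }
  x$truth$diagnosis <- unlist(x$truth$diagnosis)
  x$truth$age <- unlist(x$truth$age)
  x$truth$cci <- unlist(x$truth$cci)
  x$truth$procedures <- as.list(x$truth$procedures)
  x$member_of <- as.list(x$member_of)
  x$n <- as.integer(x$n)
  x$seed <- as.integer(x$seed)
  structure(x, class = "si_synth_config")
}

# quadrature grid for expectations over the severity factor S ~ N(0,1)
.sev_grid <- local({
  s <- seq(-6, 6, length.out = 241L)
  w <- stats::dnorm(s)
  list(s = s, w = w / sum(w))
})

# E[plogis(a + lambda * S)]
.elogis <- function(a, lambda) {
  g <- .sev_grid
  sum(g$w * stats::plogis(a + lambda * g$s))
}

# solve alpha so that a procedure's marginal prevalence is `target`;
# `block_alpha`/`block_loading` describe the (possibly severity-loaded)
# latent block cause, `eta` its within-block log-odds bump
.calibrate_alpha <- function(target, lambda, eta = 0,
                             block_alpha = -Inf, block_loading = 0) {
  g <- .sev_grid
  pB <- stats::plogis(block_alpha + block_loading * g$s)
  f <- function(a) {
    p1 <- stats::plogis(a + eta + lambda * g$s)
    p0 <- stats::plogis(a + lambda * g$s)
    sum(g$w * (pB * p1 + (1 - pB) * p0)) - target
  }
  stats::uniroot(f, interval = c(-30, 30), tol = 1e-10)$root
}

#' Generate a synthetic admission cohort
#'
#' Samples demographics independently at the configured marginals; draws a
#' standard-normal severity factor and per-block latent binary causes;
#' samples each procedure indicator from a logistic model in the severity
#' factor and its block latent, with the intercept calibrated (by
#' quadrature) so the marginal prevalence matches the configuration; and
#' draws in-hospital death from the true logistic model on the consolidated
#' procedure variables and demographics.  All procedure/drug events are
#' emitted at day 0 (the catecholamines-or-vasopressin composite emits one
#' of its five drug codes); additional ignorable events are emitted at days
#' 1-5.  A fixed seed gives an identical cohort.
#'
#' @param config An [synthetic_config()] object.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return An `si_cohort` with a precomputed `cci` column; the true model
#'   is attached as attribute `truth`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "si_synth_config"))
  .check_probs(config)
  set.seed(as.integer(seed))
  n <- config$n

  diagnosis <- sample(names(config$diagnosis_probs), n, replace = TRUE,
                      prob = config$diagnosis_probs)
  band <- sample(names(config$age_probs), n, replace = TRUE,
                 prob = config$age_probs)
  lo <- c("<60" = 18, "60-69" = 60, "70-79" = 70, "80-89" = 80,
          ">=90" = 90)[band]
  hi <- c("<60" = 59, "60-69" = 69, "70-79" = 79, "80-89" = 89,
          ">=90" = 104)[band]
  age <- lo + floor(stats::runif(n) * (hi - lo + 1))
  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  cci_cat <- sample(names(config$cci_probs), n, replace = TRUE,
                    prob = config$cci_probs)
  cci <- c("0" = 0, "1" = 1, "2" = 2, ">=3" = 3)[cci_cat]

  sev <- stats::rnorm(n)
  blk <- config$blocks
  if (is.null(blk$loading)) blk$loading <- 0
  blk$alpha <- vapply(seq_len(nrow(blk)), function(i) {
    stats::uniroot(function(a) .elogis(a, blk$loading[i]) - blk$prob[i],
                   interval = c(-30, 30), tol = 1e-10)$root
  }, numeric(1L))
  B <- matrix(0L, n, nrow(blk), dimnames = list(NULL, blk$block))
  for (i in seq_len(nrow(blk))) {
    B[, i] <- stats::rbinom(n, 1L,
                            stats::plogis(blk$alpha[i] +
                                            blk$loading[i] * sev))
  }

  pr <- config$procedures
  X <- matrix(0L, n, nrow(pr), dimnames = list(NULL, pr$name))
  for (j in seq_len(nrow(pr))) {
    bj <- pr$block[j]
    if (is.na(bj)) {
      a <- .calibrate_alpha(pr$prevalence[j], pr$loading[j])
      eta <- stats::plogis(a + pr$loading[j] * sev)
    } else {
      bi <- match(bj, blk$block)
      a <- .calibrate_alpha(pr$prevalence[j], pr$loading[j],
                            eta = blk$log_odds[bi],
                            block_alpha = blk$alpha[bi],
                            block_loading = blk$loading[bi])
      eta <- stats::plogis(a + blk$log_odds[bi] * B[, bi] +
                             pr$loading[j] * sev)
    }
    X[, j] <- stats::rbinom(n, 1L, eta)
  }

  # consolidated candidate variables feeding the true death model
  tr <- config$truth
  member_map <- unlist(config$member_of)
  consolidated <- vapply(names(tr$procedures), function(v) {
    members <- c(names(member_map)[member_map == v],
                 intersect(v, colnames(X)))
    if (!length(members)) return(integer(n))
    as.integer(rowSums(X[, members, drop = FALSE]) > 0L)
  }, integer(n))
  lp <- rep(tr$intercept, n)
  dx_beta <- c(acute_myocardial_infarction = 0, tr$diagnosis)
  lp <- lp + unname(dx_beta[diagnosis])
  lp <- lp + ifelse(sex == "female", tr$sex_female, 0)
  age_beta <- c("<60" = 0, tr$age)
  lp <- lp + unname(age_beta[band])
  cci_beta <- c("0" = 0, tr$cci)
  lp <- lp + unname(cci_beta[cci_cat])
  for (v in names(tr$procedures)) {
    if (v %in% colnames(consolidated)) {
      lp <- lp + tr$procedures[[v]] * consolidated[, v]
    }
  }
  death <- stats::rbinom(n, 1L, stats::plogis(lp))

  adm <- data.frame(
    admission_id = sprintf("A%07d", seq_len(n)),
    diagnosis = diagnosis,
    age_years = as.integer(age),
    sex = sex,
    cci = as.numeric(cci),
    icu_day0 = stats::runif(n) < config$p_icu,
    life_support_day0 = stats::runif(n) < config$p_life_support,
    death = death,
    ambulance = as.integer(stats::runif(n) <
                             config$strata_probs[["ambulance"]]),
    referral = as.integer(stats::runif(n) <
                            config$strata_probs[["referral"]]),
    hospital_type = ifelse(stats::runif(n) <
                             config$strata_probs[["academic"]],
                           "academic", "non_academic"),
    stringsAsFactors = FALSE)
  if (config$p_under_18 > 0) {
    juv <- stats::runif(n) < config$p_under_18
    adm$age_years[juv] <- sample(1:17, sum(juv), replace = TRUE)
  }

  # day-0 events; the catecholamine composite emits a concrete drug code
  hits <- which(X == 1L, arr.ind = TRUE)
  code <- pr$name[hits[, 2L]]
  kind <- rep("procedure", length(code))
  is_drug <- code == "catecholamines_or_vasopressin"
  if (any(is_drug)) {
    code[is_drug] <- sample(config$drug_codes, sum(is_drug),
                            replace = TRUE)
    kind[is_drug] <- "drug"
  }
  ev <- data.frame(admission_id = adm$admission_id[hits[, 1L]],
                   code = code, day = 0L, kind = kind,
                   stringsAsFactors = FALSE)
  if (config$extra_event_rate > 0) {
    extra <- which(stats::runif(n) < config$extra_event_rate)
    n_extra <- sample(1:3, length(extra), replace = TRUE)
    noise_codes <- c(setdiff(pr$name, "catecholamines_or_vasopressin"),
                     config$drug_codes)
    ev2 <- data.frame(
      admission_id = rep(adm$admission_id[extra], n_extra),
      code = sample(noise_codes, sum(n_extra), replace = TRUE),
      day = sample(1:5, sum(n_extra), replace = TRUE),
      kind = "procedure", stringsAsFactors = FALSE)
    ev <- rbind(ev, ev2)
  }
  ev <- ev[order(ev$admission_id, ev$day, ev$code), , drop = FALSE]
  rownames(ev) <- NULL

  cohort <- si_cohort(adm, ev)
  attr(cohort, "truth") <- tr
  cohort
}

.check_probs <- function(config) {
  for (f in c("diagnosis_probs", "age_probs", "cci_probs")) {
    p <- config[[f]]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-6) {
      stop(f, " must be probabilities summing to 1", call. = FALSE)
    }
  }
  scalars <- c(config$p_male, config$strata_probs, config$p_icu,
               config$p_life_support, config$p_under_18,
               config$extra_event_rate, config$procedures$prevalence)
  if (any(scalars < 0) || any(scalars > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Calibrate the true-model intercept to a target mortality
#'
#' Simulates the linear predictor once (without the intercept term's
#' uncertainty) and solves for the intercept giving the target marginal
#' in-hospital mortality; monotone, so a single root-find suffices.  Used
#' once to fix the default intercept of [synthetic_config()].
#'
#' @param config An `si_synth_config`.
#' @param target Target mortality (default 0.095).
#' @param n Simulation size for the calibration (default 100000).
#' @param seed Seed for the calibration simulation.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(config, target = 0.095, n = 100000L,
                                seed = 1L) {
  cfg <- config
  cfg$n <- as.integer(n)
  cfg$extra_event_rate <- 0
  cohort <- generate_cohort(cfg, seed = seed)
  # recover the linear predictor net of the intercept via the truth model
  feats <- extract_features(cohort)
  cons <- resolve_groups(feats, lapply(default_group_policies(),
                                       `[[`, "members"),
                         default_group_policies())$features
  tr <- cfg$truth
  lp0 <- rep(0, n)
  dx_beta <- c(acute_myocardial_infarction = 0, tr$diagnosis)
  lp0 <- lp0 + unname(dx_beta[as.character(cons$diagnosis)])
  lp0 <- lp0 + ifelse(cons$sex == "female", tr$sex_female, 0)
  age_beta <- c("<60" = 0, tr$age)
  lp0 <- lp0 + unname(age_beta[as.character(cons$age_category)])
  cci_beta <- c("0" = 0, tr$cci)
  lp0 <- lp0 + unname(cci_beta[as.character(cons$cci_category)])
  for (v in names(tr$procedures)) {
    if (v %in% colnames(cons)) lp0 <- lp0 + tr$procedures[[v]] * cons[[v]]
  }
  stats::uniroot(function(c0) mean(stats::plogis(c0 + lp0)) - target,
                 interval = c(-15, 5), tol = 1e-8)$root
}
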