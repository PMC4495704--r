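#' Randomly split a cohort into derivation and validation halves
#'
#' Seeded admission-level shuffle-then-cut: the partition is exhaustive
#' and disjoint with sizes within one of `n * fraction`.  A Bernoulli
#' per-admission assignment (which only hits the expected sizes on
#' average) is available as an alternative.
#'
#' @param cohort An `si_cohort`.
#' @param seed Integer seed.
#' @param fraction Derivation fraction, in (0, 1) (default 0.5).
#' @param method `"shuffle"` (default) or `"bernoulli"`.
#' @return List with elements `derivation` and `validation`, both
#'   `si_cohort`s.
#' @export
split_cohort <- function(cohort, seed, fraction = 0.5,
                         method = c("shuffle", "bernoulli")) {
  stopifnot(inherits(cohort, "si_cohort"),
            fraction > 0, fraction < 1)
  method <- match.arg(method)
  n <- nrow(cohort$admissions)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  set.seed(as.integer(seed))
  in_der <- if (method == "shuffle") {
    seq_len(n) %in% sample.int(n)[seq_len(round(n * fraction))]
  } else {
    stats::runif(n) < fraction
  }
  take <- function(keep) {
    adm <- cohort$admissions[keep, , drop = FALSE]
    ev <- cohort$events[cohort$events$admission_id %in%
                          adm$admission_id, , drop = FALSE]
    si_cohort(adm, ev)
  }
  list(derivation = take(in_der), validation = take(!in_der))
}

#' Run configuration for the derivation pipeline
#'
#' Bundles the thresholds and seeds of a full run; serialisable to JSON.
#'
#' @param prevalence_threshold,p_screen,phi_threshold,alpha Stage
#'   thresholds (defaults 0.01, 0.1, 0.6, 0.05).
#' @param split_fraction Derivation fraction (default 0.5).
#' @param split_seed,bootstrap_seed,simulation_seed Named seeds; all
#'   randomness in the pipeline flows through these.
#' @param n_boot Bootstrap replicates for the omega interval.
#' @return A list of class `si_run_config`.
#' @export
run_config <- function(prevalence_threshold = 0.01, p_screen = 0.1,
                       phi_threshold = 0.6, alpha = 0.05,
                       split_fraction = 0.5, split_seed = 1L,
                       bootstrap_seed = 1L, simulation_seed = 1L,
                       n_boot = 200L) {
  stopifnot(prevalence_threshold > 0, prevalence_threshold < 1,
            p_screen > 0, p_screen < 1, phi_threshold > 0,
            phi_threshold < 1, alpha > 0, alpha < 1,
            split_fraction > 0, split_fraction < 1)
  structure(list(prevalence_threshold = prevalence_threshold,
                 p_screen = p_screen, phi_threshold = phi_threshold,
                 alpha = alpha, split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 bootstrap_seed = as.integer(bootstrap_seed),
                 simulation_seed = as.integer(simulation_seed),
                 n_boot = as.integer(n_boot)),
            class = "si_run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Derive an index from a raw cohort
#'
#' Convenience wrapper chaining the pipeline stages on a cohort:
#' exclusions, admission-day feature extraction, screening, consolidation,
#' regression and point assignment.  Stage boundaries are logged via
#' `message()`.
#'
#' @param cohort An `si_cohort` (derivation cohort).
#' @param config An [run_config()].
#' @param catalog Feature catalog (default [default_catalog()]).
#' @param policies Consolidation policies.
#' @return A `severity_index` object, with the exclusion tally attached
#'   as attribute `exclusions`.
#' @export
derive_index <- function(cohort, config = run_config(),
                         catalog = default_catalog(),
                         policies = default_group_policies()) {
  message("stage 1/4: exclusions")
  excl <- apply_exclusions(cohort)
  message("stage 2/4: feature extraction (",
          nrow(excl$cohort$admissions), " admissions)")
  feats <- extract_features(excl$cohort, catalog = catalog)
  message("stage 3/4: screening")
  message("stage 4/4: consolidation, regression, point assignment")
  fit <- severity_index(
    feats, prevalence_threshold = config$prevalence_threshold,
    p_screen = config$p_screen, phi_threshold = config$phi_threshold,
    alpha = config$alpha, policies = policies)
  attr(fit, "exclusions") <- excl$tally
  fit
}
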