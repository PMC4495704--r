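#' Derive a procedure-based severity index
#'
#' The main fitting function.  Runs the full derivation pipeline on an
#' admission-day feature table (see [extract_features()]):
#'
#' 1. **Screening** — every procedure with overall prevalence of at least
#'    `prevalence_threshold` is tested for association with in-hospital
#'    death (uncorrected Pearson chi-square); procedures positively
#'    associated at `p_screen` are retained.
#' 2. **Consolidation** — retained procedures with pairwise phi
#'    coefficients above `phi_threshold` are grouped (connected
#'    components) and resolved by the configured policies: combined into a
#'    single any-of variable, or reduced to the procedure performed first.
#' 3. **Regression** — multivariable logistic regression of death on
#'    diagnosis, sex, age band, CCI category and the candidate procedure
#'    variables.
#' 4. **Point assignment** — each significant procedure coefficient is
#'    divided by the reference coefficient (CCI = 1 when significant,
#'    otherwise half of CCI = 2) and rounded to the nearest integer
#'    (Sullivan scaling), yielding the index point table.
#'
#' @param features An `si_features` data frame from [extract_features()]
#'   (or any data frame with `death`, `diagnosis`, `sex`, `age_category`,
#'   `cci_category` and 0/1 procedure columns plus a `feature_names`
#'   attribute or explicit `feature_cols`).
#' @param feature_cols Procedure indicator columns; defaults to the
#'   `feature_names` attribute.
#' @param prevalence_threshold,p_screen Screening thresholds (defaults
#'   0.01 and 0.1).
#' @param phi_threshold Phi grouping threshold (default 0.6, strict).
#' @param alpha Significance level for both the reference-coefficient rule
#'   and the point gate (default 0.05).
#' @param policies Consolidation policies; defaults to the five published
#'   group policies ([default_group_policies()]).
#' @return An object of class `severity_index`: list with `screening`
#'   (the `si_screening` table), `groups`, `consolidation` (policies
#'   applied), `variables` (candidate variable names), `model` (the
#'   [fit_mortality_model()] result), `reference` (anchor coefficient),
#'   `points` (a [point_table]), `thresholds`, `n` and `call`.  Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`, `residuals`,
#'   `simulate`.
#' @examples
#' cfg <- synthetic_config(n = 4000)
#' cohort <- generate_cohort(cfg, seed = 1)
#' feats <- extract_features(cohort)
#' fit <- severity_index(feats)
#' fit$points
#' @export
severity_index <- function(features, feature_cols = attr(features,
                                                         "feature_names"),
                           prevalence_threshold = 0.01, p_screen = 0.1,
                           phi_threshold = 0.6, alpha = 0.05,
                           policies = default_group_policies()) {
  cl <- match.call()
  if (is.null(feature_cols)) {
    stop("supply `feature_cols` or a features table with a ",
         "`feature_names` attribute", call. = FALSE)
  }
  scr <- screen(features, feature_names = feature_cols,
                prevalence_threshold = prevalence_threshold,
                p_threshold = p_screen)
  retained <- scr$feature[scr$retained]
  thresholds <- list(prevalence = prevalence_threshold,
                     p_screen = p_screen, phi = phi_threshold,
                     alpha = alpha)
  if (length(retained) == 0L) {
    warning("no procedure passed the screen; returning an empty index",
            call. = FALSE)
    return(structure(list(screening = scr, groups = list(),
                          consolidation = NULL, variables = character(),
                          model = NULL, reference = NA_real_,
                          points = point_table(integer()),
                          thresholds = thresholds, n = nrow(features),
                          call = cl),
                     class = "severity_index"))
  }
  groups <- if (length(retained) >= 2L) {
    find_phi_groups(features[, retained, drop = FALSE],
                    threshold = phi_threshold)
  } else list()
  res <- resolve_groups(features, groups, policies,
                        feature_names = retained)
  model <- fit_mortality_model(
    res$features,
    covariates = c("diagnosis", "sex", "age_category", "cci_category",
                   res$variables))
  ref <- reference_coefficient(model, alpha = alpha)
  pts <- assign_points(model, ref, procedure_terms = res$variables,
                       alpha = alpha)
  structure(list(screening = scr, groups = groups,
                 consolidation = res$applied, variables = res$variables,
                 model = model, reference = ref, points = pts,
                 thresholds = thresholds, n = nrow(features), call = cl),
            class = "severity_index")
}

#' Apply a fitted index's consolidation to new features
#'
#' Rewrites a feature table with the grouping learned at derivation time
#' (combined any-of variables, dropped consecutive procedures) so the
#' fitted model and point table can be applied to new admissions.
#'
#' @param object A `severity_index`.
#' @param features A feature data frame with the original indicator
#'   columns.
#' @return The rewritten data frame.
#' @export
consolidate_features <- function(object, features) {
  stopifnot(inherits(object, "severity_index"))
  if (is.null(object$consolidation) || nrow(object$consolidation) == 0L) {
    return(features)
  }
  res <- resolve_groups(features, object$groups,
                        .policies_from_applied(object$consolidation))
  res$features
}

.policies_from_applied <- function(applied) {
  lapply(seq_len(nrow(applied)), function(i) {
    group_policy(strsplit(applied$members[i], "+", fixed = TRUE)[[1L]],
                 applied$policy[i], applied$result[i])
  })
}

#' @export
print.severity_index <- function(x, ...) {
  cat("Procedure-based severity index (n =", x$n, "admissions)\n")
  cat("  screened:", nrow(x$screening), "procedures;",
      sum(x$screening$retained), "retained;",
      length(x$variables), "candidate variables after consolidation\n")
  cat("  reference coefficient:", format(x$reference), "\n")
  print(x$points)
  invisible(x)
}

#' @export
summary.severity_index <- function(object, ...) {
  structure(list(index = object), class = "summary.severity_index")
}

#' @export
print.summary.severity_index <- function(x, ...) {
  obj <- x$index
  print(obj)
  if (!is.null(obj$consolidation) && nrow(obj$consolidation)) {
    cat("\nConsolidated groups:\n")
    print(obj$consolidation, row.names = FALSE)
  }
  if (!is.null(obj$model)) {
    cat("\n")
    print(obj$model)
  }
  invisible(x)
}

#' @export
coef.severity_index <- function(object, ...) {
  if (is.null(object$model)) return(numeric())
  coef(object$model)
}

#' Predict from a fitted severity index
#'
#' @param object A `severity_index`.
#' @param newdata Feature data frame (pre-consolidation indicator columns).
#' @param type `"score"` for the integer severity index, `"response"` for
#'   the fitted death probability from the derivation model, `"link"` for
#'   its log-odds.
#' @param ... Unused.
#' @return Numeric (or integer, for scores) vector.
#' @export
predict.severity_index <- function(object, newdata,
                                   type = c("score", "response", "link"),
                                   ...) {
  type <- match.arg(type)
  cons <- consolidate_features(object, newdata)
  if (type == "score") return(score_index(cons, object$points))
  if (is.null(object$model)) stop("empty index has no model", call. = FALSE)
  as.numeric(stats::predict(object$model$glm, newdata = cons, type = type))
}

#' @export
residuals.severity_index <- function(object, type = "deviance", ...) {
  if (is.null(object$model)) stop("empty index has no model", call. = FALSE)
  stats::residuals(object$model$glm, type = type)
}

#' @export
simulate.severity_index <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$model)) stop("empty index has no model", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- stats::fitted(object$model$glm)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.severity_index <- function(x, ...) {
  if (length(x$points) == 0L) {
    stop("empty index: nothing to plot", call. = FALSE)
  }
  p <- sort(as.integer(x$points))
  nm <- names(sort(unclass(x$points)))
  op <- graphics::par(mar = c(4, 14, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(p, names.arg = nm, horiz = TRUE, las = 1,
                    cex.names = 0.7, xlab = "points",
                    main = "Severity-index procedure points", ...)
  invisible(x)
}
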