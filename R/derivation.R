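#' Round to the nearest integer, halves away from zero
#'
#' Point assignment uses "the nearest integer"; an exact .5 quotient is
#' rounded away from zero so that positive and negative coefficients are
#' treated symmetrically (base R's `round()` rounds halves to even).
#'
#' @param x Numeric vector.
#' @return Integer vector.
#' @export
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Fit the multivariable in-hospital death model
#'
#' Maximum-likelihood logistic regression of in-hospital death on the
#' categorical covariates (admission-precipitating diagnosis, sex, age
#' band, CCI category) and the candidate procedure indicators, with
#' dummy coding and reference levels taken from the factor level order
#' (acute myocardial infarction, male, age < 60, CCI = 0 under the
#' [extract_features()] defaults).  Wald z tests and 95 percent
#' confidence intervals are reported per term.
#'
#' @param data Model data frame (consolidated features).
#' @param covariates Character vector of column names entering the model.
#' @param outcome Name of the 0/1 outcome column.
#' @param epsilon,maxit Convergence tolerance (relative deviance change)
#'   and iteration cap for the IRLS fit.
#' @return An object of class `mortality_fit`: list with the underlying
#'   `glm` fit, a `coefficients` data frame (`term`, `estimate`, `se`,
#'   `z`, `p`, `or`, `ci_low`, `ci_high`), `n`, `loglik`, `outcome` and
#'   `covariates`.
#' @export
fit_mortality_model <- function(data, covariates, outcome = "death",
                                epsilon = 1e-8, maxit = 100L) {
  miss <- setdiff(c(outcome, covariates), names(data))
  if (length(miss)) {
    stop("model data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  const <- covariates[vapply(covariates, function(v) {
    length(unique(data[[v]][!is.na(data[[v]])])) < 2L
  }, logical(1L))]
  if (length(const)) {
    stop("constant covariate(s): ", paste(const, collapse = ", "),
         call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    outcome, "~", paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- stats::glm(fml, data = data, family = stats::binomial(),
                    control = stats::glm.control(epsilon = epsilon,
                                                 maxit = maxit))
  if (!fit$converged) {
    stop("logistic fit did not converge in ", maxit,
         " IRLS iterations (possible separation); deviance = ",
         format(fit$deviance), call. = FALSE)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular design: aliased term(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, 1L], se = sm[, 2L], z = sm[, 3L], p = sm[, 4L],
    or = exp(sm[, 1L]),
    ci_low = exp(sm[, 1L] - 1.96 * sm[, 2L]),
    ci_high = exp(sm[, 1L] + 1.96 * sm[, 2L]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(glm = fit, coefficients = coefs, n = stats::nobs(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 outcome = outcome, covariates = covariates),
            class = "mortality_fit")
}

#' @export
print.mortality_fit <- function(x, digits = 3, ...) {
  cat("Logistic in-hospital death model: n =", x$n,
      " log-likelihood =", format(x$loglik, digits = 8), "\n")
  df <- x$coefficients
  df$estimate <- round(df$estimate, digits)
  df$or <- round(df$or, digits)
  df$p <- signif(df$p, digits)
  print(df[, c("term", "estimate", "or", "ci_low", "ci_high", "p")],
        digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mortality_fit <- function(object, ...) stats::coef(object$glm)

.fit_term <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("model has no term '", term, "'", call. = FALSE)
  fit$coefficients[i, ]
}

#' Sullivan reference coefficient
#'
#' The point scale is anchored to the log-odds of one CCI unit: the CCI = 1
#' coefficient when it is significant, otherwise half the CCI = 2
#' coefficient.  If neither CCI = 1 nor CCI = 2 reaches significance no
#' anchor is defined and an error is raised.
#'
#' @param fit A `mortality_fit` containing CCI category terms.
#' @param alpha Significance level for the Wald P value (default 0.05).
#' @param cci1_term,cci2_term Coefficient names of the CCI = 1 and CCI = 2
#'   dummies.
#' @return The reference log-odds coefficient (scalar).
#' @export
reference_coefficient <- function(fit, alpha = 0.05,
                                  cci1_term = "cci_category1",
                                  cci2_term = "cci_category2") {
  c1 <- .fit_term(fit, cci1_term)
  if (c1$p < alpha) return(c1$estimate)
  c2 <- .fit_term(fit, cci2_term)
  if (c2$p < alpha) return(c2$estimate / 2)
  stop("no reference coefficient: neither CCI = 1 nor CCI = 2 is ",
       "significant at alpha = ", alpha, call. = FALSE)
}

#' Assign integer points to procedures
#'
#' For every procedure term whose Wald P value is below `alpha`, the point
#' is the integer nearest to the term's coefficient divided by the
#' reference coefficient (halves away from zero).  Non-significant
#' procedures receive no entry.  Demographic and CCI terms never receive
#' points.
#'
#' @param fit A `mortality_fit`.
#' @param ref Reference coefficient, see [reference_coefficient()].
#' @param procedure_terms Coefficient names of the procedure indicators.
#' @param alpha Significance gate (default 0.05).
#' @return A [point_table] object.
#' @export
assign_points <- function(fit, ref, procedure_terms, alpha = 0.05) {
  stopifnot(is.numeric(ref), length(ref) == 1L, ref != 0)
  cf <- fit$coefficients
  cf <- cf[cf$term %in% procedure_terms, , drop = FALSE]
  cf <- cf[cf$p < alpha, , drop = FALSE]
  point_table(stats::setNames(round_half_away(cf$estimate / ref), cf$term),
              reference_coefficient = ref,
              note = sprintf(
                "derived: %d of %d candidate procedures significant at %g",
                nrow(cf), length(procedure_terms), alpha))
}

#' Procedure point tables
#'
#' A point table maps procedure names to integer points and defines a
#' severity index as the sum of points over performed procedures.
#'
#' @param points Named integer vector (procedure name to points).
#' @param reference_coefficient The log-odds anchor the points were scaled
#'   by.
#' @param note Free-text provenance note.
#' @return An object of class `point_table` (a named integer vector with
#'   attributes).
#' @export
point_table <- function(points, reference_coefficient = NA_real_,
                        note = "") {
  if (length(points) && (is.null(names(points)) ||
                         any(!nzchar(names(points))))) {
    stop("`points` must be a named vector", call. = FALSE)
  }
  if (length(points) && any(points != as.integer(points))) {
    stop("points must be integers", call. = FALSE)
  }
  structure(stats::setNames(as.integer(points), names(points)),
            reference_coefficient = reference_coefficient, note = note,
            class = "point_table")
}

#' @export
print.point_table <- function(x, ...) {
  cat("Severity-index point table:", length(x), "procedures")
  if (length(x)) {
    rng <- index_range(x)
    cat(", points", min(x), "to", max(x),
        sprintf("(index range %d to %d)", rng[["min"]], rng[["max"]]))
  }
  cat("\n  reference coefficient:",
      format(attr(x, "reference_coefficient")), "\n")
  if (length(x)) {
    df <- data.frame(procedure = names(x), points = as.integer(x))
    print(df[order(df$points), ], row.names = FALSE)
  }
  invisible(x)
}

#' @export
`[.point_table` <- function(x, i, ...) unclass(x)[i]

#' Score admissions with a point table
#'
#' The severity index of an admission is the integer sum of the points of
#' the procedures performed on the day of admission.  Procedures absent
#' from the feature columns are treated as not performed, with a warning.
#'
#' @param features Data frame of 0/1 indicator columns (consolidated
#'   variables for a derived table; see [consolidate_features()]).
#' @param points A [point_table].
#' @return Integer vector of index values, one per row.
#' @export
score_index <- function(features, points) {
  stopifnot(inherits(points, "point_table"))
  if (length(points) == 0L) return(rep(0L, nrow(features)))
  have <- intersect(names(points), colnames(features))
  miss <- setdiff(names(points), have)
  if (length(miss)) {
    warning("indicator(s) missing from features, treated as 0: ",
            paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!length(have)) return(rep(0L, nrow(features)))
  x <- as.matrix(features[, have, drop = FALSE])
  storage.mode(x) <- "double"
  as.integer(drop(x %*% as.numeric(points[have])))
}

#' Possible range of a severity index
#'
#' @param points A [point_table].
#' @return Named integer vector `c(min = sum of negative points,
#'   max = sum of positive points)`.
#' @export
index_range <- function(points) {
  p <- as.integer(points)
  c(min = sum(p[p < 0]), max = sum(p[p > 0]))
}

#' Serialise a point table to JSON
#'
#' Layout: `{"<procedure>": <points>, ...,
#' "_reference_coefficient": <ref>}`.
#'
#' @param points A [point_table].
#' @param path Output path.
#' @return `path` invisibly; `read_point_table()` returns a [point_table].
#' @export
write_point_table <- function(points, path) {
  stopifnot(inherits(points, "point_table"))
  obj <- as.list(stats::setNames(as.integer(points), names(points)))
  obj[["_reference_coefficient"]] <- attr(points, "reference_coefficient")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_point_table
#' @export
read_point_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- obj[["_reference_coefficient"]]
  obj[["_reference_coefficient"]] <- NULL
  point_table(unlist(obj), reference_coefficient =
                if (is.null(ref)) NA_real_ else ref)
}
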