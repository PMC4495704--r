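#' Concordance (c-) statistic with DeLong confidence interval
#'
#' The c-statistic is the probability that a randomly chosen event
#' receives a higher predicted risk than a randomly chosen non-event,
#' counting ties as one half: `[concordant + ties/2] / (events x
#' non-events)`.  The interval is DeLong's, computed through the pROC
#' package.
#'
#' @param p Predicted probabilities (any strictly increasing transform of
#'   risk gives the same estimate).
#' @param y 0/1 outcomes; both classes must be present.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate` and `ci` (length-2 vector).
#' @export
c_statistic <- function(p, y, conf = 0.95) {
  y <- as.integer(y)
  if (length(p) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- pROC::roc(response = y, predictor = as.numeric(p), quiet = TRUE,
                 levels = c(0L, 1L), direction = "<")
  # pROC warns that a degenerate (AUC = 1) interval is uninformative;
  # the estimate itself is what the callers assert on
  ci <- suppressWarnings(pROC::ci.auc(r, method = "delong",
                                      conf.level = conf))
  list(estimate = as.numeric(pROC::auc(r)),
       ci = c(as.numeric(ci[1L]), as.numeric(ci[3L])))
}

#' Integrated discrimination improvement
#'
#' The discrimination slope of a model is the mean predicted probability
#' among events minus the mean among non-events; the IDI is the difference
#' in slope between a new and an old model.  Its confidence interval uses
#' the standard errors of the mean within-person probability difference in
#' each outcome class: `IDI +/- z * sqrt(se_events^2 + se_nonevents^2)`.
#'
#' @param p_new,p_old Aligned predicted-probability vectors.
#' @param y 0/1 outcomes.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate`, `ci`, `slope_new`, `slope_old`.
#' @export
idi <- function(p_new, p_old, y, conf = 0.95) {
  y <- as.integer(y)
  if (length(p_new) != length(y) || length(p_old) != length(y)) {
    stop("length mismatch", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  ev <- y == 1L
  slope_new <- mean(p_new[ev]) - mean(p_new[!ev])
  slope_old <- mean(p_old[ev]) - mean(p_old[!ev])
  d <- p_new - p_old
  se_ev <- stats::sd(d[ev]) / sqrt(sum(ev))
  se_ne <- stats::sd(d[!ev]) / sqrt(sum(!ev))
  est <- slope_new - slope_old
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(se_ev^2 + se_ne^2)
  list(estimate = est, ci = c(est - half, est + half),
       slope_new = slope_new, slope_old = slope_old)
}

#' Omega variance-ratio statistic
#'
#' The omega statistic compares the contributions of two groups of
#' covariates to the linear predictor of a logistic model: the
#' contribution of group g for patient i is the sum of `beta_j * x_ij`
#' over the group's coefficients, and omega is the ratio of the sample
#' variances, across patients, of the two group contributions.  Omega
#' above 1 means group A contributes more predictive variation than
#' group B.  The confidence interval is a nonparametric percentile
#' bootstrap over patients, refitting the model in each replicate.
#'
#' @param fit A `mortality_fit`.
#' @param group_a,group_b Disjoint, non-empty sets of covariate names
#'   (model terms, e.g. `"diagnosis"` expands to all its dummies).
#' @param n_boot Bootstrap replicates (default 200); 0 skips the interval.
#' @param seed Optional seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate`, `ci` (NA when `n_boot = 0`), `var_a`,
#'   `var_b`.
#' @export
omega_statistic <- function(fit, group_a, group_b, n_boot = 200L,
                            seed = NULL, conf = 0.95) {
  stopifnot(inherits(fit, "mortality_fit"))
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (!length(group_a) || !length(group_b)) {
    stop("groups must be non-empty", call. = FALSE)
  }
  est <- .omega_point(fit$glm, group_a, group_b)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    mf <- stats::model.frame(fit$glm)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(mf), replace = TRUE)
      refit <- stats::glm(stats::formula(fit$glm), data = mf[idx, ],
                          family = stats::binomial())
      .omega_point(refit, group_a, group_b)$omega
    }, numeric(1L))
    al <- (1 - conf) / 2
    ci <- unname(stats::quantile(reps, c(al, 1 - al), na.rm = TRUE))
  }
  list(estimate = est$omega, ci = ci, var_a = est$var_a, var_b = est$var_b)
}

.omega_point <- function(glm_fit, group_a, group_b) {
  mm <- stats::model.matrix(glm_fit)
  asn <- attr(mm, "assign")
  labels <- attr(stats::terms(glm_fit), "term.labels")
  labels <- gsub("`", "", labels, fixed = TRUE)
  pick <- function(group) {
    idx <- match(group, labels)
    if (anyNA(idx)) {
      stop("unknown model term(s): ",
           paste(group[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    which(asn %in% idx)
  }
  beta <- stats::coef(glm_fit)
  contrib <- function(cols) drop(mm[, cols, drop = FALSE] %*% beta[cols])
  va <- stats::var(contrib(pick(group_a)))
  vb <- stats::var(contrib(pick(group_b)))
  if (vb == 0) stop("omega undefined: group B contribution has zero ",
                    "variance", call. = FALSE)
  list(omega = va / vb, var_a = va, var_b = vb)
}

#' Hosmer-Lemeshow decile table
#'
#' Ranks admissions by predicted probability (stable sort, so ties stay in
#' the lower group) and cuts them into `g` near-equal groups, reporting
#' per-group size, observed events, expected events (sum of predicted
#' probabilities) and mean predicted probability.  The expected column
#' conserves the total of `p` exactly.
#'
#' @param p Predicted probabilities.
#' @param y 0/1 outcomes.
#' @param g Number of groups (default 10); `n >= g` required.
#' @return Data frame with columns `group`, `n`, `observed`, `expected`,
#'   `mean_p`, plus attributes `statistic` and `p_value` for the usual
#'   chi-square summary on `g - 2` degrees of freedom.
#' @export
hosmer_lemeshow <- function(p, y, g = 10L) {
  y <- as.integer(y)
  n <- length(p)
  if (length(y) != n) stop("length mismatch", call. = FALSE)
  if (n < g) stop("need at least g observations", call. = FALSE)
  ord <- order(p)  # radix: stable
  sizes <- rep(n %/% g, g) + c(rep(1L, n %% g), rep(0L, g - n %% g))
  grp <- rep(seq_len(g), sizes)
  ps <- p[ord]
  ys <- y[ord]
  out <- data.frame(
    group = seq_len(g),
    n = sizes,
    observed = as.integer(tapply(ys, grp, sum)),
    expected = as.numeric(tapply(ps, grp, sum)),
    mean_p = as.numeric(tapply(ps, grp, mean)))
  ok <- out$expected > 0 & out$expected < out$n
  stat <- sum((out$observed[ok] - out$expected[ok])^2 /
                (out$expected[ok] * (1 - out$mean_p[ok])))
  attr(out, "statistic") <- stat
  attr(out, "p_value") <- stats::pchisq(stat, df = max(g - 2L, 1L),
                                        lower.tail = FALSE)
  out
}

#' Observed vs expected death rates by index value
#'
#' Bins admissions by integer index value, merging adjacent sparse values
#' (sweeping inward from both extremes, then any remaining interior
#' deficit into its smaller neighbour) until every bin holds at least
#' `min_fraction` of the admissions.  Observed-rate confidence intervals
#' use the Wald normal approximation to the binomial.
#'
#' @param index Integer severity-index values.
#' @param y 0/1 outcomes.
#' @param p_expected Optional predicted probabilities used for the
#'   expected rate per bin.
#' @param min_fraction Minimum bin fraction (default 0.01).
#' @param conf Confidence level for the observed rate (default 0.95).
#' @return Data frame with `label`, `lo`, `hi`, `n`, `observed`,
#'   `obs_rate`, `ci_low`, `ci_high` and (when `p_expected` is given)
#'   `exp_rate`.
#' @export
calibration_by_index <- function(index, y, p_expected = NULL,
                                 min_fraction = 0.01, conf = 0.95) {
  y <- as.integer(y)
  n <- length(index)
  stopifnot(length(y) == n)
  vals <- sort(unique(index))
  # bins as runs [lo, hi] of adjacent distinct values
  bins <- data.frame(lo = vals, hi = vals)
  counts <- function(b) {
    vapply(seq_len(nrow(b)), function(i) {
      sum(index >= b$lo[i] & index <= b$hi[i])
    }, numeric(1L))
  }
  need <- ceiling(min_fraction * n)
  merge_into <- function(b, i, j) {  # absorb bin i into neighbour j
    b$lo[j] <- min(b$lo[i], b$lo[j])
    b$hi[j] <- max(b$hi[i], b$hi[j])
    b[-i, , drop = FALSE]
  }
  repeat {
    if (nrow(bins) == 1L) break
    cn <- counts(bins)
    if (cn[1L] < need) { bins <- merge_into(bins, 1L, 2L); next }
    k <- nrow(bins)
    if (cn[k] < need) { bins <- merge_into(bins, k, k - 1L); next }
    def <- which(cn < need)
    if (!length(def)) break
    i <- def[1L]
    j <- if (cn[i - 1L] <= cn[i + 1L]) i - 1L else i + 1L
    bins <- merge_into(bins, i, j)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- do.call(rbind, lapply(seq_len(nrow(bins)), function(i) {
    sel <- index >= bins$lo[i] & index <= bins$hi[i]
    ni <- sum(sel)
    obs <- sum(y[sel])
    rate <- obs / ni
    half <- z * sqrt(rate * (1 - rate) / ni)
    data.frame(
      label = if (bins$lo[i] == bins$hi[i]) as.character(bins$lo[i]) else
        paste0(bins$lo[i], "-", bins$hi[i]),
      lo = bins$lo[i], hi = bins$hi[i], n = ni, observed = obs,
      obs_rate = rate, ci_low = max(0, rate - half),
      ci_high = min(1, rate + half),
      exp_rate = if (is.null(p_expected)) NA_real_ else
        mean(p_expected[sel]),
      stringsAsFactors = FALSE)
  }))
  if (is.null(p_expected)) out$exp_rate <- NULL
  out
}

#' Run the validation battery for a point table
#'
#' Scores the cohort with the point table and fits the four benchmark
#' logistic models on the validation features: the index alone as a
#' continuous variable (model 1); index, diagnosis, age and sex (model 2);
#' diagnosis, age, sex and CCI (model 3); and all five (model 4).
#' Reports the c-statistic of each model (DeLong intervals), the IDI of
#' model 4 over model 3, the omega statistic of the index against the
#' four other variables combined in model 4, the Hosmer-Lemeshow decile
#' table for model 4, and observed vs expected death rates by index value
#' (expected rates from model 1).  Optional subgroup analyses refit
#' model 4 within each level of the named stratum columns, and
#' per-diagnosis models use index, age, sex and CCI.
#'
#' @param features Feature data frame of the validation cohort
#'   (pre-consolidation indicators are fine: scoring treats missing
#'   consolidated columns via [score_index()] after consolidation when a
#'   `severity_index` object is given).
#' @param points A [point_table] or a fitted `severity_index` (whose
#'   consolidation is then applied before scoring).
#' @param subgroups Character vector of stratum column names (each a
#'   binary/logical or factor column of `features`); subgroup levels with
#'   a single outcome class are skipped with a warning.
#' @param n_boot Bootstrap replicates for the omega interval (default
#'   200; 0 skips it).
#' @param seed Seed for the bootstrap.
#' @param g Hosmer-Lemeshow groups (default 10).
#' @param min_fraction Minimum per-value bin fraction (default 0.01).
#' @return An object of class `index_validation`.
#' @export
run_validation <- function(features, points, subgroups = NULL,
                           n_boot = 200L, seed = NULL, g = 10L,
                           min_fraction = 0.01) {
  if (inherits(points, "severity_index")) {
    features_sc <- consolidate_features(points, features)
    points <- points$points
  } else {
    features_sc <- features
  }
  stopifnot(inherits(points, "point_table"))
  dat <- features
  dat$index <- score_index(features_sc, points)

  specs <- list(
    model1 = "index",
    model2 = c("index", "diagnosis", "age_category", "sex"),
    model3 = c("diagnosis", "age_category", "sex", "cci_category"),
    model4 = c("index", "diagnosis", "age_category", "sex",
               "cci_category"))
  fits <- lapply(specs, function(cv) fit_mortality_model(dat, cv))
  preds <- lapply(fits, function(f) stats::fitted(f$glm))
  cs <- lapply(preds, function(p) c_statistic(p, dat$death))
  idi4v3 <- idi(preds$model4, preds$model3, dat$death)
  om <- omega_statistic(fits$model4, group_a = "index",
                        group_b = c("diagnosis", "age_category", "sex",
                                    "cci_category"),
                        n_boot = n_boot, seed = seed)
  hl <- hosmer_lemeshow(preds$model4, dat$death, g = g)
  calib <- calibration_by_index(dat$index, dat$death,
                                p_expected = preds$model1,
                                min_fraction = min_fraction)

  sub_res <- list()
  for (s in subgroups) {
    for (lev in sort(unique(as.character(dat[[s]])))) {
      sel <- as.character(dat[[s]]) == lev
      lab <- paste0(s, "=", lev)
      if (length(unique(dat$death[sel])) < 2L) {
        warning("subgroup ", lab, " has a single outcome class; skipped",
                call. = FALSE)
        next
      }
      f <- fit_mortality_model(dat[sel, ], specs$model4)
      sub_res[[lab]] <- c(list(n = sum(sel),
                               mortality = mean(dat$death[sel])),
                          c_statistic(stats::fitted(f$glm),
                                      dat$death[sel]))
    }
  }
  diag_res <- list()
  for (dx in levels(droplevels(dat$diagnosis))) {
    sel <- dat$diagnosis == dx
    if (length(unique(dat$death[sel])) < 2L) {
      warning("diagnosis ", dx, " has a single outcome class; skipped",
              call. = FALSE)
      next
    }
    f <- fit_mortality_model(dat[sel, ],
                             c("index", "age_category", "sex",
                               "cci_category"))
    diag_res[[dx]] <- c(list(n = sum(sel),
                             mortality = mean(dat$death[sel])),
                        c_statistic(stats::fitted(f$glm), dat$death[sel]))
  }

  structure(list(c = cs, idi = idi4v3, omega = om, hosmer_lemeshow = hl,
                 calibration = calib, subgroups = sub_res,
                 by_diagnosis = diag_res, models = fits,
                 n = nrow(dat), index = dat$index),
            class = "index_validation")
}

#' @export
print.index_validation <- function(x, digits = 3, ...) {
  cat("Severity-index validation (n =", x$n, "admissions)\n")
  cat(sprintf("  index: range %d to %d, mean %.2f (sd %.2f)\n",
              min(x$index), max(x$index), mean(x$index),
              stats::sd(x$index)))
  for (m in names(x$c)) {
    cat(sprintf("  c(%s) = %.3f (%.3f-%.3f)\n", m, x$c[[m]]$estimate,
                x$c[[m]]$ci[1L], x$c[[m]]$ci[2L]))
  }
  cat(sprintf("  IDI (model4 vs model3) = %.4f (%.4f-%.4f)\n",
              x$idi$estimate, x$idi$ci[1L], x$idi$ci[2L]))
  cat(sprintf("  omega (index vs other covariates, model4) = %.2f",
              x$omega$estimate))
  if (!anyNA(x$omega$ci)) {
    cat(sprintf(" (%.2f-%.2f)", x$omega$ci[1L], x$omega$ci[2L]))
  }
  cat("\n")
  if (length(x$by_diagnosis)) {
    cat("  per-diagnosis c-statistics:\n")
    for (dx in names(x$by_diagnosis)) {
      r <- x$by_diagnosis[[dx]]
      cat(sprintf("    %-32s n=%6d  mortality=%5.1f%%  c=%.3f\n", dx,
                  r$n, 100 * r$mortality, r$estimate))
    }
  }
  invisible(x)
}

#' @export
plot.index_validation <- function(x, which = c("index", "deciles"), ...) {
  which <- match.arg(which)
  if (which == "index") {
    cb <- x$calibration
    mids <- (cb$lo + cb$hi) / 2
    graphics::plot(mids, cb$obs_rate, ylim = c(0, max(cb$ci_high)),
                   pch = 19, xlab = "severity index",
                   ylab = "in-hospital death rate",
                   main = "Observed vs expected death rate by index value",
                   ...)
    graphics::arrows(mids, cb$ci_low, mids, cb$ci_high, angle = 90,
                     code = 3, length = 0.03)
    if (!is.null(cb$exp_rate)) {
      graphics::lines(mids, cb$exp_rate, col = 2, lwd = 2)
      graphics::legend("topleft", legend = c("observed (95% CI)",
                                             "expected"),
                       pch = c(19, NA), lty = c(NA, 1), col = c(1, 2))
    }
  } else {
    hl <- x$hosmer_lemeshow
    graphics::plot(hl$expected / hl$n, hl$observed / hl$n, pch = 19,
                   xlab = "expected death rate",
                   ylab = "observed death rate",
                   main = "Hosmer-Lemeshow decile calibration", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
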