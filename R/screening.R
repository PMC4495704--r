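#' Pearson chi-square test for a 2x2 table
#'
#' Closed-form Pearson test without continuity correction,
#' `X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with a two-sided P value
#' from the upper tail of the chi-square distribution on 1 degree of
#' freedom.  The screening stage uses the uncorrected statistic: it is the
#' variant that reproduces the published screening P values from the
#' published counts.
#'
#' @param a,b,c,d Cell counts.  The screening convention is `a` =
#'   deceased-with-feature, `b` = deceased-without, `c` = surviving-with,
#'   `d` = surviving-without, but the statistic is symmetric in rows and
#'   columns.
#' @return List with `statistic` and `p`.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  if (min(a, b, c, d) < 0) stop("counts must be non-negative", call. = FALSE)
  if (min(a + b, c + d, a + c, b + d) == 0) {
    stop("chi-square test undefined: zero margin", call. = FALSE)
  }
  a <- as.double(a); b <- as.double(b)
  c <- as.double(c); d <- as.double(d)
  n <- a + b + c + d
  x2 <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = x2, p = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Prevalence and association screen from 2x2 counts
#'
#' The first derivation stage, applied directly to per-feature outcome
#' counts: a feature is retained when its overall prevalence reaches
#' `prevalence_threshold`, its uncorrected chi-square P value is below
#' `p_threshold`, and it is used more often in deceased than in surviving
#' admissions (positive direction).  Direction ties and constant features
#' are never retained.
#'
#' @param counts Data frame with columns `procedure` (or `feature`),
#'   `surviving_n` and `deceased_n`, e.g. [published_screen_counts()].
#' @param n_surviving,n_deceased Outcome-group denominators; default to the
#'   attributes carried by `counts`.
#' @param prevalence_threshold Minimum overall prevalence (default 0.01).
#' @param p_threshold Screening significance level (default 0.1).
#' @return An `si_screening` data frame: one row per feature with the 2x2
#'   counts (`a`,`b`,`c`,`d`), `prevalence`, `statistic`, `p`, `direction`
#'   (`"positive"`, `"negative"` or `"none"`), `retained` and `note`.
#' @export
screen_counts <- function(counts, n_surviving = attr(counts, "n_surviving"),
                          n_deceased = attr(counts, "n_deceased"),
                          prevalence_threshold = 0.01, p_threshold = 0.1) {
  stopifnot(prevalence_threshold > 0, prevalence_threshold < 1,
            p_threshold > 0, p_threshold < 1)
  nm <- if ("procedure" %in% names(counts)) counts$procedure else
    counts$feature
  n_total <- n_surviving + n_deceased
  res <- lapply(seq_len(nrow(counts)), function(i) {
    a <- counts$deceased_n[i]
    b <- n_deceased - a
    c_ <- counts$surviving_n[i]
    d <- n_surviving - c_
    prev <- (a + c_) / n_total
    if ((a + c_) == 0L || (b + d) == 0L) {
      return(data.frame(feature = nm[i], a = a, b = b, c = c_, d = d,
                        prevalence = prev, statistic = NA_real_,
                        p = NA_real_, direction = "none", retained = FALSE,
                        note = "constant feature: association undefined",
                        stringsAsFactors = FALSE))
    }
    ts <- chisq_2x2(a, b, c_, d)
    rate_dec <- a / n_deceased
    rate_sur <- c_ / n_surviving
    dir <- if (rate_dec > rate_sur) "positive" else
      if (rate_dec < rate_sur) "negative" else "none"
    data.frame(feature = nm[i], a = a, b = b, c = c_, d = d,
               prevalence = prev, statistic = ts$statistic, p = ts$p,
               direction = dir,
               retained = prev >= prevalence_threshold &&
                 ts$p < p_threshold && dir == "positive",
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("si_screening", "data.frame")
  out
}

#' Screen a cohort feature matrix against the outcome
#'
#' Tabulates every binary feature against in-hospital death and applies the
#' retention rule of [screen_counts()].  Prevalence is computed over the
#' whole cohort (deceased plus surviving).
#'
#' @param features An `si_features` data frame (see [extract_features()]) or
#'   any data frame of 0/1 columns.
#' @param outcome 0/1 outcome vector; defaults to the `death` column.
#' @param feature_names Columns to screen; defaults to the `feature_names`
#'   attribute.
#' @inheritParams screen_counts
#' @return An `si_screening` data frame.
#' @export
screen <- function(features, outcome = features$death,
                   feature_names = attr(features, "feature_names"),
                   prevalence_threshold = 0.01, p_threshold = 0.1) {
  if (is.null(feature_names)) {
    stop("`feature_names` must be supplied when `features` carries no ",
         "feature_names attribute", call. = FALSE)
  }
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L))) {
    stop("`outcome` must be binary", call. = FALSE)
  }
  n_dec <- sum(outcome)
  n_sur <- sum(1L - outcome)
  if (n_dec == 0L || n_sur == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  x <- as.matrix(features[, feature_names, drop = FALSE])
  counts <- data.frame(
    feature = feature_names,
    surviving_n = as.integer(crossprod(x, 1L - outcome)),
    deceased_n = as.integer(crossprod(x, outcome)),
    stringsAsFactors = FALSE)
  screen_counts(counts, n_surviving = n_sur, n_deceased = n_dec,
                prevalence_threshold = prevalence_threshold,
                p_threshold = p_threshold)
}

#' @export
print.si_screening <- function(x, digits = 3, ...) {
  cat("Procedure screen:", nrow(x), "features,",
      sum(x$retained), "retained\n")
  df <- data.frame(feature = x$feature,
                   prevalence = round(100 * x$prevalence, 1),
                   p = signif(x$p, digits), direction = x$direction,
                   retained = x$retained)
  print(df, row.names = FALSE)
  invisible(x)
}
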