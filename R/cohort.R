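#' @keywords internal
default_diagnoses <- function() {
  c("acute_myocardial_infarction", "congestive_heart_failure",
    "acute_cerebrovascular_disease", "gastrointestinal_hemorrhage",
    "pneumonia", "septicemia")
}

#' Admission cohorts
#'
#' A cohort holds one row per admission plus a long-form table of dated
#' events (procedures, drugs, reimbursement items).  Day offsets are 0-based:
#' the day of admission is day 0, and only day-0 events enter feature
#' extraction.
#'
#' @param admissions Data frame with columns `admission_id`, `diagnosis`,
#'   `age_years`, `sex` (`"male"`/`"female"`), `death` (0/1 or logical);
#'   optional `cci` (precomputed Charlson score), `comorbidity_codes`
#'   (present-on-admission ICD-10 codes, `;`-separated), `icu_day0`,
#'   `life_support_day0`, and any extra stratum columns (e.g. `ambulance`).
#' @param events Data frame with columns `admission_id`, `code`, `day`
#'   (integer offset >= 0) and optionally `kind`
#'   (`"procedure"`/`"drug"`/`"reimbursement"`).
#' @return An object of class `si_cohort`.
#' @export
si_cohort <- function(admissions, events = NULL) {
  required <- c("admission_id", "diagnosis", "age_years", "sex", "death")
  miss <- setdiff(required, names(admissions))
  if (length(miss)) {
    stop("admissions table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(events)) {
    events <- data.frame(admission_id = character(), code = character(),
                         day = integer(), kind = character(),
                         stringsAsFactors = FALSE)
  }
  if (!"kind" %in% names(events)) events$kind <- "procedure"
  admissions$admission_id <- as.character(admissions$admission_id)
  events$admission_id <- as.character(events$admission_id)
  for (fl in c("icu_day0", "life_support_day0")) {
    if (!fl %in% names(admissions)) admissions[[fl]] <- FALSE
    admissions[[fl]] <- .as_binary(admissions[[fl]], fl) == 1L
  }
  admissions$death <- .as_binary(admissions$death, "death")
  structure(list(admissions = admissions, events = events),
            class = "si_cohort")
}

# 0/1, logical, or their string forms -> integer 0/1
.as_binary <- function(x, what) {
  if (is.character(x)) {
    x <- trimws(x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("1", "TRUE", "true", "T", "yes")] <- 1L
    out[x %in% c("0", "FALSE", "false", "F", "no", "")] <- 0L
  } else {
    out <- as.integer(as.logical(x))
  }
  if (anyNA(out)) {
    stop("column '", what, "' must be binary (0/1 or TRUE/FALSE)",
         call. = FALSE)
  }
  out
}

#' @export
print.si_cohort <- function(x, ...) {
  cat("Admission cohort:", nrow(x$admissions), "admissions,",
      nrow(x$events), "events\n")
  cat("  in-hospital deaths:", sum(x$admissions$death), sprintf(
    "(%.1f%%)\n", 100 * mean(x$admissions$death)))
  invisible(x)
}

#' Load a cohort from delimited text files
#'
#' Reads an admissions CSV and (optionally) a long-form events CSV, applying
#' a column-mapping schema.  Events may instead be packed into a single
#' admissions column (one `code|day|kind` triple per event, `;`-separated),
#' named by `schema$packed_events`.  Malformed rows (unparseable age or day,
#' negative day) are collected and reported with their line numbers, and the
#' file is rejected if any are found.
#'
#' @param admissions_path,events_path CSV file paths (UTF-8, header row).
#' @param schema Optional list with elements `admissions` and `events`, each
#'   a named character vector mapping canonical field names to file column
#'   names, and optionally `packed_events` (a column name in the admissions
#'   file).  Defaults to identity naming.
#' @return An `si_cohort`.
#' @export
load_cohort <- function(admissions_path, events_path = NULL, schema = NULL) {
  adm <- utils::read.csv(admissions_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  adm <- .apply_schema(adm, schema$admissions, "admissions",
                       c("admission_id", "diagnosis", "age_years", "sex",
                         "death"))
  bad <- list()
  age <- suppressWarnings(as.numeric(adm$age_years))
  bad_age <- which(is.na(age) | age < 0)
  if (length(bad_age)) {
    bad$age <- sprintf("admissions line %d: unparseable age '%s'",
                       bad_age + 1L, adm$age_years[bad_age])
  }
  adm$age_years <- age

  ev <- NULL
  packed_col <- schema$packed_events
  if (!is.null(packed_col)) {
    if (!packed_col %in% names(adm)) {
      stop("packed events column '", packed_col, "' not found", call. = FALSE)
    }
    ev <- .unpack_events(adm$admission_id, adm[[packed_col]])
    adm[[packed_col]] <- NULL
  } else if (!is.null(events_path)) {
    ev <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                          colClasses = "character")
    ev <- .apply_schema(ev, schema$events, "events",
                        c("admission_id", "code", "day"))
  }
  if (!is.null(ev) && nrow(ev)) {
    day <- suppressWarnings(as.numeric(ev$day))
    bad_day <- which(is.na(day) | day < 0 | day != floor(day))
    if (length(bad_day)) {
      bad$day <- sprintf("events line %d: invalid day '%s'",
                         bad_day + 1L, ev$day[bad_day])
    }
    ev$day <- as.integer(day)
  }
  if (length(bad)) {
    stop("malformed rows:\n  ", paste(unlist(bad), collapse = "\n  "),
         call. = FALSE)
  }
  for (col in c("cci")) {
    if (col %in% names(adm)) adm[[col]] <- as.numeric(adm[[col]])
  }
  si_cohort(adm, ev)
}

.apply_schema <- function(df, map, what, required) {
  if (!is.null(map)) {
    miss_src <- setdiff(unname(map), names(df))
    if (length(miss_src)) {
      stop(what, " file is missing mapped column(s): ",
           paste(miss_src, collapse = ", "), call. = FALSE)
    }
    names(df)[match(unname(map), names(df))] <- names(map)
  }
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " file is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

.unpack_events <- function(ids, packed) {
  keep <- !is.na(packed) & nzchar(packed)
  if (!any(keep)) {
    return(data.frame(admission_id = character(), code = character(),
                      day = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(packed[keep], ";", fixed = TRUE)
  id <- rep(ids[keep], lengths(parts))
  trip <- strsplit(unlist(parts), "|", fixed = TRUE)
  data.frame(
    admission_id = id,
    code = vapply(trip, `[`, "", 1L),
    day = vapply(trip, `[`, "", 2L),
    kind = vapply(trip, function(z) if (length(z) >= 3L) z[3L] else
      "procedure", ""),
    stringsAsFactors = FALSE)
}

#' Write a cohort to CSV files
#'
#' Emits the same two-file layout [load_cohort()] reads, so simulated
#' cohorts round-trip through the text interface.
#'
#' @param cohort An `si_cohort`.
#' @param admissions_path,events_path Output CSV paths.
#' @return `admissions_path`, invisibly.
#' @export
write_cohort <- function(cohort, admissions_path, events_path) {
  stopifnot(inherits(cohort, "si_cohort"))
  utils::write.csv(cohort$admissions, admissions_path, row.names = FALSE)
  utils::write.csv(cohort$events, events_path, row.names = FALSE)
  invisible(admissions_path)
}

#' Apply the cohort exclusion rules
#'
#' Removes admissions that are under 18 years of age, admitted to an
#' intensive/coronary care unit on the day of admission, or in receipt of
#' cardiopulmonary life support on the day of admission.  Reasons are
#' reported disjointly with ICU taking precedence over life support, and
#' both taking precedence over the age rule, so the tally sums to the number
#' of removed admissions.
#'
#' @param cohort An `si_cohort`.
#' @return A list with elements `cohort` (the kept admissions and their
#'   events) and `tally` (named integer vector: `icu`, `life_support`,
#'   `under_18`).
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(inherits(cohort, "si_cohort"))
  adm <- cohort$admissions
  icu <- adm$icu_day0 %in% TRUE
  ls_ <- adm$life_support_day0 %in% TRUE & !icu
  young <- adm$age_years < 18 & !icu & !adm$life_support_day0 %in% TRUE
  drop <- icu | ls_ | young
  kept <- adm[!drop, , drop = FALSE]
  ev <- cohort$events
  ev <- ev[ev$admission_id %in% kept$admission_id, , drop = FALSE]
  list(
    cohort = si_cohort(kept, ev),
    tally = c(icu = sum(icu), life_support = sum(ls_),
              under_18 = sum(young)))
}

#' Bin age in years into the model's age bands
#'
#' Bands close on the left: `[60, 70)` is `"60-69"`.
#'
#' @param age_years Numeric vector of ages.
#' @return Factor with levels `<60`, `60-69`, `70-79`, `80-89`, `>=90`.
#' @export
age_category <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 60, 70, 80, 90, Inf), right = FALSE,
      labels = c("<60", "60-69", "70-79", "80-89", ">=90"))
}

#' Extract admission-day binary features
#'
#' Builds one feature row per admission: a 0/1 indicator per catalog feature
#' (1 iff at least one day-0 event matches any of the feature's codes),
#' the age band, the Charlson comorbidity index (CCI) category, diagnosis,
#' sex and outcome.  Extraction is insensitive to event order and idempotent.
#'
#' The CCI is taken from, in order of precedence: the `cci` argument, a
#' precomputed `cci` column of the admissions table, or Quan's ICD-10 coding
#' of the `comorbidity_codes` column (see [charlson()]).
#'
#' @param cohort An `si_cohort`.
#' @param catalog An `si_catalog`; defaults to [default_catalog()].
#' @param cci Optional numeric vector of precomputed Charlson scores aligned
#'   with the admissions table.
#' @param diagnoses Character vector of valid diagnosis labels (the factor
#'   level order fixes the regression reference level to the first entry).
#' @return A data frame of class `si_features` with demographic columns,
#'   any stratum columns carried through, and one integer indicator column
#'   per catalog feature.  Attributes `feature_names` and `strata_names`
#'   record which columns are which.
#' @export
extract_features <- function(cohort, catalog = default_catalog(), cci = NULL,
                             diagnoses = default_diagnoses()) {
  stopifnot(inherits(cohort, "si_cohort"), inherits(catalog, "si_catalog"))
  adm <- cohort$admissions
  unknown <- setdiff(unique(adm$diagnosis), diagnoses)
  if (length(unknown)) {
    stop("unknown diagnosis label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cci)) {
    if ("cci" %in% names(adm)) {
      cci <- adm$cci
    } else if ("comorbidity_codes" %in% names(adm)) {
      codes <- strsplit(ifelse(is.na(adm$comorbidity_codes), "",
                               adm$comorbidity_codes), ";", fixed = TRUE)
      cci <- charlson(codes)
    } else {
      stop("no CCI available: supply `cci`, a precomputed `cci` column, ",
           "or a `comorbidity_codes` column", call. = FALSE)
    }
  }
  if (length(cci) != nrow(adm)) {
    stop("`cci` must align with the admissions table", call. = FALSE)
  }

  known <- c("admission_id", "diagnosis", "age_years", "sex", "death",
             "cci", "comorbidity_codes", "icu_day0", "life_support_day0")
  strata <- setdiff(names(adm), known)

  out <- data.frame(
    admission_id = adm$admission_id,
    diagnosis = factor(adm$diagnosis, levels = diagnoses),
    sex = factor(adm$sex, levels = c("male", "female")),
    age_category = age_category(adm$age_years),
    cci_category = cci_category(cci),
    death = as.integer(adm$death),
    stringsAsFactors = FALSE)
  for (s in strata) out[[s]] <- adm[[s]]

  ev <- cohort$events
  ev <- ev[ev$day == 0L, , drop = FALSE]
  code2feat <- rep(names(catalog$entries), lengths(catalog$entries))
  names(code2feat) <- unlist(catalog$entries, use.names = FALSE)
  feat <- matrix(0L, nrow(adm), length(catalog$entries),
                 dimnames = list(NULL, names(catalog$entries)))
  if (nrow(ev)) {
    hit <- code2feat[ev$code]
    ok <- !is.na(hit)
    if (any(ok)) {
      ri <- match(ev$admission_id[ok], adm$admission_id)
      ci <- match(hit[ok], colnames(feat))
      keep <- !is.na(ri)
      feat[cbind(ri[keep], ci[keep])] <- 1L
    }
  }
  out <- cbind(out, as.data.frame(feat))
  attr(out, "feature_names") <- names(catalog$entries)
  attr(out, "strata_names") <- strata
  class(out) <- c("si_features", "data.frame")
  out
}
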