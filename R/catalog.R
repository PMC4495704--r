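#' Feature catalogs
#'
#' A feature catalog maps admission-day event codes (procedure, drug or
#' reimbursement codes) to named binary features.  An entry may list several
#' codes, in which case the feature is a composite: it switches on when at
#' least one of the listed codes appears on the day of admission (an
#' "any-of" match), e.g. a single "use of catecholamines or vasopressin"
#' feature covering epinephrine, norepinephrine, dopamine, dobutamine and
#' vasopressin.
#'
#' @param entries Named list; names are feature names, elements are
#'   non-empty character vectors of matching codes.
#' @return An object of class `si_catalog`.
#' @seealso [default_catalog()], [read_catalog()]
#' @export
feature_catalog <- function(entries) {
  if (!is.list(entries) || is.null(names(entries)) ||
      any(!nzchar(names(entries)))) {
    stop("`entries` must be a named list of code vectors", call. = FALSE)
  }
  if (anyDuplicated(names(entries))) {
    stop("feature names must be unique", call. = FALSE)
  }
  entries <- lapply(entries, as.character)
  if (any(lengths(entries) == 0L)) {
    stop("every catalog entry needs at least one code", call. = FALSE)
  }
  structure(list(entries = entries), class = "si_catalog")
}

#' @export
print.si_catalog <- function(x, ...) {
  cat("Feature catalog:", length(x$entries), "features\n")
  n_comp <- sum(lengths(x$entries) > 1L)
  if (n_comp > 0L) cat("  composites (any-of over >1 code):", n_comp, "\n")
  invisible(x)
}

#' Default admission-day procedure catalog
#'
#' Catalog of the 38 admission-day procedure/drug features screened in the
#' original derivation study, plus two deliberately rare procedures
#' (bronchoscopy, hemodialysis) that fall below the 1 percent prevalence
#' screen.  The event codes are the feature names themselves except for the
#' catecholamines-or-vasopressin composite, which matches the five individual
#' drug codes.  Real claims extracts use fee-schedule codes; supply a custom
#' catalog (see [read_catalog()]) mapping those codes to the same feature
#' names.
#'
#' @return An `si_catalog` object.
#' @export
default_catalog <- function() {
  nms <- published_screen_counts()$procedure
  entries <- stats::setNames(as.list(nms), nms)
  entries$catecholamines_or_vasopressin <-
    c("epinephrine", "norepinephrine", "dopamine", "dobutamine", "vasopressin")
  entries$bronchoscopy <- "bronchoscopy"
  entries$hemodialysis <- "hemodialysis"
  feature_catalog(entries)
}

#' Read or write a feature catalog as JSON
#'
#' The JSON layout is an object mapping feature names to arrays of codes:
#' `{"pulse_oximetry": ["D223"], "catecholamines_or_vasopressin":
#' ["epinephrine", ...]}`.
#'
#' @param path File path.
#' @return `read_catalog()` returns an `si_catalog`; `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  feature_catalog(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE))
}

#' @rdname read_catalog
#' @param catalog An `si_catalog` object.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "si_catalog"))
  jsonlite::write_json(catalog$entries, path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}
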