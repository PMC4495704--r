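#' Charlson condition map and weight tables
#'
#' `charlson_map()` returns the ICD-10 coding algorithm of Quan et al.
#' (2005) for the 17 Charlson conditions, as a named list of code prefixes
#' (dot-insensitive).  `charlson_weights()` returns a weight table: either
#' the original Charlson weights or the updated weights of Quan et al.
#' (2011); the update is the default throughout the package.  Both tables
#' are shipped as JSON under `inst/extdata` and are transcriptions of the
#' cited algorithms, not outputs of this package.
#'
#' @param version `"quan"` (2011 updated weights, default) or `"charlson"`
#'   (original 1987 weights).
#' @return `charlson_map()`: named list of character prefix vectors.
#'   `charlson_weights()`: a list with `weights` (named integer vector) and
#'   `hierarchy` (list of `c(superior, inferior)` pairs; when both members
#'   of a pair are present only the superior one is scored).
#' @export
charlson_map <- function() {
  path <- system.file("extdata", "charlson_icd10_quan.json",
                      package = "psindex", mustWork = TRUE)
  m <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  lapply(m, function(p) toupper(gsub("[. ]", "", unlist(p))))
}

#' @rdname charlson_map
#' @export
charlson_weights <- function(version = c("quan", "charlson")) {
  version <- match.arg(version)
  path <- system.file("extdata", "charlson_weights.json",
                      package = "psindex", mustWork = TRUE)
  w <- jsonlite::read_json(path, simplifyVector = FALSE)
  list(weights = unlist(w[[version]]),
       hierarchy = lapply(w$hierarchy, function(h) unlist(h,
                                                          use.names = FALSE)))
}

#' Map ICD-10 codes to Charlson conditions
#'
#' Prefix matching after uppercasing and removing dots and whitespace;
#' unmatched codes are ignored.  Hierarchy suppression is not applied here
#' (see [cci_score()]).
#'
#' @param codes Character vector of ICD-10 codes (may be empty).
#' @param cmap Condition map, as from [charlson_map()].
#' @return Character vector of condition names (a set).
#' @export
map_conditions <- function(codes, cmap = charlson_map()) {
  if (length(codes) == 0L) return(character())
  codes <- toupper(gsub("[. ]", "", as.character(codes)))
  codes <- codes[nzchar(codes)]
  hit <- vapply(cmap, function(prefixes) {
    any(vapply(prefixes, function(p) any(startsWith(codes, p)), logical(1L)))
  }, logical(1L))
  names(cmap)[hit]
}

#' Charlson comorbidity index from a condition set
#'
#' Sums condition weights after hierarchy suppression (metastatic solid
#' tumor supersedes any malignancy; moderate/severe liver disease supersedes
#' mild liver disease; diabetes with complications supersedes uncomplicated
#' diabetes) and bins the score into the categories 0, 1, 2, >=3 used by the
#' severity-index model.
#'
#' @param conditions Character vector of condition names.
#' @param weights Weight table from [charlson_weights()].
#' @return List with `score` (integer) and `category` (factor).
#' @export
cci_score <- function(conditions, weights = charlson_weights()) {
  conditions <- unique(as.character(conditions))
  missing_w <- setdiff(conditions, names(weights$weights))
  if (length(missing_w)) {
    stop("condition(s) missing from the weight table: ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  for (h in weights$hierarchy) {
    if (all(h %in% conditions)) conditions <- setdiff(conditions, h[2L])
  }
  score <- sum(weights$weights[conditions])
  list(score = as.integer(score), category = cci_category(score))
}

#' Bin a Charlson score into the model's categories
#'
#' @param score Numeric vector of Charlson scores.
#' @return Factor with levels `0`, `1`, `2`, `>=3`.
#' @export
cci_category <- function(score) {
  cut(score, breaks = c(-Inf, 1, 2, 3, Inf), right = FALSE,
      labels = c("0", "1", "2", ">=3"))
}

#' Charlson score from raw ICD-10 code lists
#'
#' Vectorised convenience wrapper: maps each admission's
#' present-on-admission codes to conditions and scores them.
#'
#' @param codes_list List of character vectors of ICD-10 codes, one element
#'   per admission.
#' @param cmap Condition map.
#' @param weights Weight table.
#' @return Integer vector of Charlson scores.
#' @export
charlson <- function(codes_list, cmap = charlson_map(),
                     weights = charlson_weights()) {
  vapply(codes_list, function(cc) {
    cci_score(map_conditions(cc, cmap), weights)$score
  }, integer(1L))
}
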