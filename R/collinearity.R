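#' Phi coefficient between two binary variables
#'
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` on the 2x2
#' cross-tabulation of two binary features; equivalently the Pearson
#' correlation of the two 0/1 vectors, so `phi^2 * N` equals the
#' uncorrected chi-square statistic on the same table.
#'
#' @param x,y Binary 0/1 vectors, or (if `y` is missing) `x` may be a 2x2
#'   table/matrix `rbind(c(a, b), c(c, d))`.
#' @return The phi coefficient, in `[-1, 1]`.
#' @export
phi_coefficient <- function(x, y = NULL) {
  if (is.null(y)) {
    stopifnot(is.matrix(x) || is.table(x), all(dim(x) == 2L))
    a <- x[1L, 1L]; b <- x[1L, 2L]; c_ <- x[2L, 1L]; d <- x[2L, 2L]
  } else {
    x <- as.integer(x); y <- as.integer(y)
    a <- sum(x & y); b <- sum(x & !y); c_ <- sum(!x & y); d <- sum(!x & !y)
  }
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (denom == 0) stop("phi undefined: zero margin", call. = FALSE)
  (a * d - b * c_) / sqrt(denom)
}

#' Pairwise phi matrix for a binary feature matrix
#'
#' @param features Data frame or matrix of 0/1 columns.
#' @return Symmetric matrix of pairwise phi coefficients (unit diagonal).
#' @export
phi_matrix <- function(features) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  m11 <- crossprod(x)
  cs <- colSums(x)
  denom <- sqrt(outer(cs * (n - cs), cs * (n - cs)))
  if (any(denom == 0)) {
    bad <- colnames(x)[cs == 0 | cs == n]
    stop("phi undefined for constant column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  phi <- (n * m11 - outer(cs, cs)) / denom
  diag(phi) <- 1
  phi
}

#' Find groups of phi-correlated features
#'
#' Builds a graph with an edge between two features wherever their phi
#' coefficient exceeds `threshold` (strict comparison of phi itself, not
#' its absolute value: collinear procedures co-occur positively), and
#' returns its connected components with at least two members.  Components
#' rather than cliques make the grouping deterministic and independent of
#' feature order.
#'
#' @param features Data frame or matrix of 0/1 columns (the retained
#'   features).
#' @param threshold Phi threshold (default 0.6).
#' @return List of character vectors of member names (sorted); empty list
#'   when no pair exceeds the threshold.
#' @export
find_phi_groups <- function(features, threshold = 0.6) {
  phi <- phi_matrix(features)
  adj <- phi > threshold
  diag(adj) <- FALSE
  nms <- colnames(phi)
  seen <- logical(length(nms))
  groups <- list()
  for (i in seq_along(nms)) {
    if (seen[i]) next
    comp <- i
    frontier <- i
    seen[i] <- TRUE
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2L, any) & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    if (length(comp) > 1L) groups[[length(groups) + 1L]] <- sort(nms[comp])
  }
  groups
}

#' Consolidation policy for a correlated group
#'
#' Whether a group of collinear procedures is performed simultaneously
#' (combine into a single any-of indicator) or consecutively (keep only the
#' procedure usually performed first) is clinical knowledge, so it is
#' explicit configuration.
#'
#' @param members Character vector of feature names (at least 2).
#' @param policy `"combine_any_of"` or `"keep_named_first"`.
#' @param arg For `combine_any_of`, the name of the combined variable; for
#'   `keep_named_first`, the member to keep.
#' @return An object of class `si_group_policy`.
#' @export
group_policy <- function(members,
                         policy = c("combine_any_of", "keep_named_first"),
                         arg) {
  policy <- match.arg(policy)
  members <- sort(as.character(members))
  if (length(members) < 2L) stop("a group needs >= 2 members", call. = FALSE)
  if (policy == "keep_named_first" && !arg %in% members) {
    stop("policy argument '", arg, "' is not a group member", call. = FALSE)
  }
  structure(list(members = members, policy = policy, arg = arg),
            class = "si_group_policy")
}

#' The five published consolidation policies
#'
#' Defaults reproducing the published consolidation: the three blood
#' examinations, two urine examinations and two microbiological
#' examinations are each combined into a single variable, while for the two
#' consecutively-performed pairs (central venous infusion after catheter
#' insertion; oxygen administration after pulse oximetry) only the
#' logically first procedure is kept.
#'
#' @return List of [group_policy()] objects.
#' @export
default_group_policies <- function() {
  list(
    group_policy(c("blood_chemistry_tests", "hematology_tests",
                   "plasma_protein_immunology_tests"),
                 "combine_any_of", "blood_tests_excl_coagulation"),
    group_policy(c("urine_tests_general", "urine_microscopy"),
                 "combine_any_of", "urinalyses_excl_chemistry"),
    group_policy(c("bacterial_microscopy", "bacterial_culture"),
                 "combine_any_of", "bacterial_microscopy_or_culture"),
    group_policy(c("central_venous_infusion",
                   "central_venous_catheter_insertion"),
                 "keep_named_first", "central_venous_catheter_insertion"),
    group_policy(c("oxygen_administration", "pulse_oximetry"),
                 "keep_named_first", "pulse_oximetry"))
}

#' Read consolidation policies from JSON
#'
#' Layout: `[{"members": [...], "policy": "combine_any_of",
#' "arg": "blood_tests_excl_coagulation"}, ...]`.
#'
#' @param path JSON file path.
#' @return List of `si_group_policy` objects.
#' @export
read_group_policies <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(g) {
    group_policy(unlist(g$members), g$policy, g$arg)
  })
}

#' Consolidate correlated feature groups
#'
#' Applies a consolidation policy to each discovered group:
#' `combine_any_of` replaces the members by their pointwise maximum under
#' the policy's combined name; `keep_named_first` keeps the named member
#' and drops the rest.  A discovered group without a matching configured
#' policy (matched on exact membership) falls back to `combine_any_of`
#' under a concatenated name, with a warning.  Untouched features pass
#' through; consolidation never increases the number of variables.
#'
#' @param features Data frame containing (at least) the grouped 0/1
#'   columns.
#' @param groups List of member-name vectors, as from [find_phi_groups()].
#' @param policies List of [group_policy()] objects.
#' @param feature_names The candidate variable names before consolidation;
#'   defaults to all columns of `features`.
#' @return List with `features` (the rewritten data frame), `variables`
#'   (the consolidated candidate names, in stable order) and `applied`
#'   (data frame describing each group resolution).
#' @export
resolve_groups <- function(features, groups, policies = list(),
                           feature_names = NULL) {
  if (is.null(feature_names)) feature_names <- colnames(features)
  variables <- feature_names
  applied <- list()
  for (g in groups) {
    g <- sort(g)
    pol <- NULL
    for (p in policies) if (identical(p$members, g)) { pol <- p; break }
    if (is.null(pol)) {
      warning("no configured policy for group {",
              paste(g, collapse = ", "),
              "}; combining as any-of", call. = FALSE)
      pol <- group_policy(g, "combine_any_of", paste(g, collapse = "_or_"))
    }
    if (pol$policy == "combine_any_of") {
      features[[pol$arg]] <- as.integer(
        do.call(pmax, features[, g, drop = FALSE]))
      keep_at <- match(g[1L], variables)
      variables[keep_at] <- pol$arg
      variables <- setdiff(variables, g)
      features <- features[, setdiff(colnames(features), g), drop = FALSE]
    } else {
      drop <- setdiff(g, pol$arg)
      variables <- setdiff(variables, drop)
      features <- features[, setdiff(colnames(features), drop),
                           drop = FALSE]
    }
    applied[[length(applied) + 1L]] <- data.frame(
      members = paste(g, collapse = "+"), policy = pol$policy,
      result = pol$arg, stringsAsFactors = FALSE)
  }
  list(features = features, variables = variables,
       applied = if (length(applied)) do.call(rbind, applied) else
         data.frame(members = character(), policy = character(),
                    result = character(), stringsAsFactors = FALSE))
}
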