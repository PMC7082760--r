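#' Declare the column roles of a patient cohort table
#'
#' A feature schema records which columns of a cohort table play which role
#' in the causal model: discrete proxy features (binary aberration
#' indicators and small-cardinality categorical clinical fields), continuous
#' proxy features (gene expression and continuous clinical fields), the
#' binary intervention column, the integer outcome column (Gleason Score),
#' and the race/ethnicity label column. The
#' \code{aberration_expression_map} links each candidate intervention (a
#' genomic aberration) to the continuous columns carrying that gene's
#' expression, so those columns can be excluded from the proxies when the
#' aberration is the intervention under study.
#'
#' @param discrete_columns character vector of discrete proxy column names.
#' @param continuous_columns character vector of continuous proxy column
#'   names.
#' @param treatment_column name of the binary intervention column
#'   (1 = aberration present).
#' @param outcome_column name of the integer Gleason Score column.
#' @param race_column name of the race/ethnicity label column.
#' @param aberration_expression_map named list mapping each aberration name
#'   to a (possibly empty) character vector of continuous expression
#'   columns for that gene.
#' @return An object of class \code{feature_schema}.
#' @examples
#' sc <- feature_schema(
#'   discrete_columns = c("ERG_fusion", "SPOP_mut"),
#'   continuous_columns = c("ERG_expr", "AR_expr"),
#'   treatment_column = "ERG_fusion_t",
#'   outcome_column = "gleason",
#'   race_column = "race",
#'   aberration_expression_map = list(ERG_fusion_t = "ERG_expr")
#' )
#' @export
feature_schema <- function(discrete_columns,
                           continuous_columns,
                           treatment_column,
                           outcome_column,
                           race_column,
                           aberration_expression_map = list()) {
  discrete_columns <- as.character(discrete_columns)
  continuous_columns <- as.character(continuous_columns)
  stopifnot(length(treatment_column) == 1L, length(outcome_column) == 1L,
            length(race_column) == 1L)
  roles <- list(discrete = discrete_columns, continuous = continuous_columns,
                treatment = treatment_column, outcome = outcome_column,
                race = race_column)
  all_cols <- unlist(roles, use.names = FALSE)
  dup <- unique(all_cols[duplicated(all_cols)])
  if (length(dup))
    stopf("schema column roles must be pairwise disjoint; duplicated: %s",
          paste(dup, collapse = ", "))
  if (!is.list(aberration_expression_map))
    stopf("aberration_expression_map must be a named list")
  if (length(aberration_expression_map) &&
      (is.null(names(aberration_expression_map)) ||
       any(!nzchar(names(aberration_expression_map)))))
    stopf("every entry of aberration_expression_map must be named")
  for (ab in names(aberration_expression_map)) {
    cols <- as.character(aberration_expression_map[[ab]])
    bad <- setdiff(cols, continuous_columns)
    if (length(bad))
      stopf("aberration '%s' maps to columns not in continuous_columns: %s",
            ab, paste(bad, collapse = ", "))
    aberration_expression_map[[ab]] <- cols
  }
  structure(list(discrete_columns = discrete_columns,
                 continuous_columns = continuous_columns,
                 treatment_column = treatment_column,
                 outcome_column = outcome_column,
                 race_column = race_column,
                 aberration_expression_map = aberration_expression_map),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema>\n")
  cat("  discrete proxies:  ", length(x$discrete_columns), "\n")
  cat("  continuous proxies:", length(x$continuous_columns), "\n")
  cat("  treatment:", x$treatment_column,
      " outcome:", x$outcome_column, " race:", x$race_column, "\n")
  cat("  aberration map:", length(x$aberration_expression_map), "entries\n")
  invisible(x)
}

schema_columns <- function(schema) {
  c(schema$discrete_columns, schema$continuous_columns,
    schema$treatment_column, schema$outcome_column, schema$race_column)
}

#' Remove an aberration's own expression columns from the proxy set
#'
#' When a genomic aberration is designated as the intervention, the
#' expression values of the same gene are direct readouts of the
#' intervention rather than proxies of latent confounders, so they are
#' excluded from the continuous feature set before model fitting.
#'
#' @param schema a \code{\link{feature_schema}}.
#' @param aberration an aberration name; must be a key of
#'   \code{schema$aberration_expression_map} (possibly mapping to an empty
#'   set of columns).
#' @return A new \code{feature_schema} whose \code{continuous_columns} omit
#'   exactly the mapped expression columns; other roles unchanged.
#' @export
exclude_intervention_expression <- function(schema, aberration) {
  stopifnot(inherits(schema, "feature_schema"))
  known <- names(schema$aberration_expression_map)
  if (!aberration %in% known)
    stopf("unknown aberration '%s'; known aberrations: %s", aberration,
          paste(known, collapse = ", "))
  drop <- schema$aberration_expression_map[[aberration]]
  out <- schema
  out$continuous_columns <- setdiff(schema$continuous_columns, drop)
  out$aberration_expression_map <-
    lapply(schema$aberration_expression_map, function(cols)
      intersect(cols, out$continuous_columns))
  class(out) <- "feature_schema"
  out
}

#' Map a Gleason Score to its clinical grade stratum
#'
#' Low-risk disease is GS <= 6, intermediate-risk is GS = 7, and
#' high-risk/aggressive disease is GS >= 8.
#'
#' @param gs integer Gleason Score(s) in \code{[2, 10]}.
#' @return factor with levels \code{low}, \code{intermediate}, \code{high}.
#' @examples
#' grade_stratum(c(6, 7, 10))
#' @export
grade_stratum <- function(gs) {
  if (any(!is.finite(gs)) || any(gs != round(gs)))
    stopf("Gleason Scores must be finite integers")
  if (any(gs < 2 | gs > 10))
    stopf("Gleason Scores out of the valid range [2, 10]: %s",
          paste(unique(gs[gs < 2 | gs > 10]), collapse = ", "))
  lab <- ifelse(gs <= 6, "low", ifelse(gs == 7, "intermediate", "high"))
  factor(lab, levels = c("low", "intermediate", "high"))
}

#' Serialize / restore a feature schema as YAML
#'
#' @param schema a \code{feature_schema}.
#' @param path file path to write to / read from.
#' @return \code{read_schema} returns a \code{feature_schema};
#'   \code{write_schema} returns \code{path} invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  obj <- unclass(schema)
  # yaml drops empty lists; keep keys of empty-mapped aberrations explicit
  obj$aberration_expression_map <-
    lapply(obj$aberration_expression_map, as.list)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  obj <- yaml::read_yaml(path)
  map <- lapply(obj$aberration_expression_map %||% list(),
                function(v) as.character(unlist(v)))
  feature_schema(discrete_columns = as.character(unlist(obj$discrete_columns)),
                 continuous_columns = as.character(unlist(obj$continuous_columns)),
                 treatment_column = obj$treatment_column,
                 outcome_column = obj$outcome_column,
                 race_column = obj$race_column,
                 aberration_expression_map = map)
}
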