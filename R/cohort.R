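#' Construct and validate a cohort table
#'
#' A cohort table is a data frame of one row per patient carrying every
#' column the \code{\link{feature_schema}} declares, with the schema
#' attached. Validation enforces: binary treatment in \{0,1\}, integer
#' outcomes in \code{[2,10]}, no missing treatment/outcome, and — when a
#' ground-truth block of potential outcomes is present (synthetic cohorts)
#' — exact consistency between the observed outcome and the factual
#' potential outcome. Race labels are normalized to the closed vocabulary
#' \code{EA}, \code{AA}, \code{Asian}, \code{unknown}; rows whose label is
#' missing or unrecognized are kept and flagged as \code{unknown}.
#'
#' @param data a data frame with a header naming every schema column.
#' @param schema a \code{\link{feature_schema}}.
#' @return A data frame of class \code{cohort_table} with the schema in
#'   \code{attr(, "schema")}. If \code{data} has \code{y0_true} and
#'   \code{y1_true} columns they are validated as the truth block.
#' @export
cohort_table <- function(data, schema) {
  stopifnot(is.data.frame(data), inherits(schema, "feature_schema"))
  missing_cols <- setdiff(schema_columns(schema), names(data))
  if (length(missing_cols))
    stopf("cohort is missing schema column(s): %s",
          paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  tv <- data[[schema$treatment_column]]
  if (anyNA(tv))
    stopf("missing treatment values at row(s): %s",
          paste(utils::head(which(is.na(tv)), 5L), collapse = ", "))
  if (!all(tv %in% c(0, 1)))
    stopf("non-binary treatment value at row(s): %s",
          paste(utils::head(which(!tv %in% c(0, 1)), 5L), collapse = ", "))
  data[[schema$treatment_column]] <- as.integer(tv)

  yv <- data[[schema$outcome_column]]
  if (anyNA(yv))
    stopf("missing outcome values at row(s): %s",
          paste(utils::head(which(is.na(yv)), 5L), collapse = ", "))
  if (!is.numeric(yv) || any(yv != round(yv)))
    stopf("non-integer outcome value at row(s): %s",
          paste(utils::head(which(!is.numeric(yv) | yv != round(yv)), 5L),
                collapse = ", "))
  if (any(yv < 2 | yv > 10))
    stopf("outcome values outside [2, 10] at row(s): %s",
          paste(utils::head(which(yv < 2 | yv > 10), 5L), collapse = ", "))
  data[[schema$outcome_column]] <- as.integer(yv)

  data[[schema$race_column]] <- normalize_race(data[[schema$race_column]])

  for (col in schema$discrete_columns) {
    v <- data[[col]]
    if (is.numeric(v) && all(is.na(v) | v %in% c(0, 1)))
      data[[col]] <- as.integer(v)
    else
      data[[col]] <- as.character(v)
  }
  for (col in schema$continuous_columns) data[[col]] <- as.numeric(data[[col]])

  if (all(c("y0_true", "y1_true") %in% names(data))) {
    fac <- ifelse(data[[schema$treatment_column]] == 1L,
                  data$y1_true, data$y0_true)
    if (!isTRUE(all(fac == yv)))
      stopf("truth block inconsistent with observed outcome at row(s): %s",
            paste(utils::head(which(fac != yv), 5L), collapse = ", "))
  }

  attr(data, "schema") <- schema
  class(data) <- c("cohort_table", "data.frame")
  data
}

#' @export
print.cohort_table <- function(x, ...) {
  sc <- attr(x, "schema")
  cat(sprintf("<cohort_table> %d patients, %d discrete + %d continuous proxies%s\n",
              nrow(x), length(sc$discrete_columns),
              length(sc$continuous_columns),
              if (has_truth(x)) ", with potential-outcome truth" else ""))
  NextMethod()
}

#' @export
`[.cohort_table` <- function(x, i, j, ...) {
  sc <- attr(x, "schema")
  out <- NextMethod()
  if (is.data.frame(out) && all(schema_columns(sc) %in% names(out))) {
    attr(out, "schema") <- sc
    class(out) <- c("cohort_table", "data.frame")
  } else if (is.data.frame(out)) {
    class(out) <- setdiff(class(out), "cohort_table")
  }
  out
}

has_truth <- function(cohort) all(c("y0_true", "y1_true") %in% names(cohort))

#' @rdname cohort_table
#' @param cohort a \code{cohort_table}.
#' @export
cohort_schema <- function(cohort) attr(cohort, "schema")

#' @rdname cohort_table
#' @param x object to test.
#' @export
is_cohort_table <- function(x) inherits(x, "cohort_table")

# closed race vocabulary; anything unrecognized or missing becomes "unknown"
normalize_race <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("ea", "european american", "european-american", "white",
               "caucasian")] <- "EA"
  out[x %in% c("aa", "african american", "african-american", "black",
               "black or african american")] <- "AA"
  out[x %in% c("asian")] <- "Asian"
  out
}

#' Read / write cohort tables as delimited text
#'
#' \code{read_cohort} accepts comma- or tab-separated files (the delimiter
#' is sniffed from the header line) and validates the result against the
#' schema. \code{write_cohort} emits tab-separated text. Row order is
#' preserved; the round trip is lossless for every cell.
#'
#' @param path file path.
#' @param schema a \code{\link{feature_schema}}.
#' @param cohort a \code{\link{cohort_table}}.
#' @return \code{read_cohort}: a validated \code{cohort_table};
#'   \code{write_cohort}: \code{path}, invisibly.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  cohort_table(df, schema)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is_cohort_table(cohort))
  out <- as.data.frame(cohort)
  # 17 significant digits: doubles survive the decimal round trip exactly
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.17g", out[[j]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# --- feature encoding -------------------------------------------------------

# Deterministic design-matrix encoding of the proxies.
# Binary discrete columns pass through; categorical discrete columns are
# one-hot expanded with lexicographically ordered levels so the input
# dimension is reproducible across runs. Returns the level dictionary so a
# fitted model can re-apply the identical encoding at inference time.
encode_proxies <- function(cohort, schema = cohort_schema(cohort),
                           levels_map = NULL, cont_center = NULL,
                           cont_scale = NULL, cont_impute = NULL) {
  n <- nrow(cohort)
  blocks <- list(); new_levels <- list()
  for (col in schema$discrete_columns) {
    v <- cohort[[col]]
    if (is.numeric(v)) {
      x <- matrix(as.numeric(v), ncol = 1L,
                  dimnames = list(NULL, col))
      x[is.na(x)] <- 0
      blocks[[col]] <- x
    } else {
      levs <- if (!is.null(levels_map) && !is.null(levels_map[[col]]))
        levels_map[[col]] else sort(unique(stats::na.omit(v)))
      new_levels[[col]] <- levs
      x <- matrix(0, n, length(levs),
                  dimnames = list(NULL, paste(col, levs, sep = ".")))
      for (j in seq_along(levs)) x[, j] <- as.numeric(v == levs[j] & !is.na(v))
      blocks[[col]] <- x
    }
  }
  x1 <- if (length(blocks)) do.call(cbind, blocks) else matrix(0, n, 0L)

  x2 <- as.matrix(as.data.frame(cohort)[, schema$continuous_columns,
                                        drop = FALSE])
  storage.mode(x2) <- "double"
  if (is.null(cont_impute)) {
    cont_impute <- apply(x2, 2L, function(v) {
      m <- mean(v, na.rm = TRUE); if (is.nan(m)) 0 else m
    })
  }
  n_imputed <- 0L
  for (j in seq_len(ncol(x2))) {
    miss <- is.na(x2[, j])
    if (any(miss)) { x2[miss, j] <- cont_impute[j]; n_imputed <- n_imputed + sum(miss) }
  }
  if (is.null(cont_center)) cont_center <- colMeans(x2)
  if (is.null(cont_scale)) {
    cont_scale <- apply(x2, 2L, stats::sd)
    cont_scale[!is.finite(cont_scale) | cont_scale < 1e-8] <- 1
  }
  x2s <- sweep(sweep(x2, 2L, cont_center, "-"), 2L, cont_scale, "/")

  list(x1 = x1, x2 = x2s,
       levels_map = if (is.null(levels_map)) new_levels else levels_map,
       cont_center = cont_center, cont_scale = cont_scale,
       cont_impute = cont_impute, n_imputed = n_imputed)
}
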