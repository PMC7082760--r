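#' Replicated stratified cross-validation plan
#'
#' The evaluation protocol: per replication the cohort is partitioned into
#' \code{n_folds} test folds (stratified by grade stratum by default);
#' within each fold's complement, patients are split into training and
#' validation sets so that overall about 47/20/33 percent of the group is
#' used for training, validation and testing. Every patient lands in
#' exactly one test fold per replication, so all samples contribute to
#' performance assessment.
#'
#' @param n_replications number of independent replications (default 10).
#' @param n_folds number of test folds per replication (default 3).
#' @param fractions named train/valid/test fractions; must sum to 1.
#' @param stratify_by \code{"grade"} (stratify on the outcome's grade
#'   stratum) or \code{"none"}.
#' @param master_seed integer seed; the full plan is deterministic in it.
#' @return An object of class \code{cv_plan}.
#' @export
cv_plan <- function(n_replications = 10L, n_folds = 3L,
                    fractions = c(train = 0.47, valid = 0.20, test = 0.33),
                    stratify_by = c("grade", "none"), master_seed = 1L) {
  stratify_by <- match.arg(stratify_by)
  if (!is_count(n_replications) || !is_count(n_folds) || n_folds < 2L)
    stopf("n_replications and n_folds must be positive integers, n_folds >= 2")
  if (abs(sum(fractions) - 1) > 0.01)
    stopf("train/valid/test fractions must sum to 1 (got %.3f)",
          sum(fractions))
  structure(list(n_replications = as.integer(n_replications),
                 n_folds = as.integer(n_folds),
                 fractions = fractions, stratify_by = stratify_by,
                 master_seed = as.integer(master_seed)),
            class = "cv_plan")
}

# deal shuffled indices round-robin into n_folds groups, per stratum
deal_folds <- function(strata_key, n_folds) {
  fold <- integer(length(strata_key))
  for (s in unique(strata_key)) {
    idx <- sample(which(strata_key == s))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Materialize a cross-validation plan into index triples
#'
#' @param cohort a \code{\link{cohort_table}} with at least
#'   \code{3 * n_folds} patients.
#' @param plan a \code{\link{cv_plan}}.
#' @return A list with one element per (replication, fold):
#'   \code{list(replication, fold, train, valid, test)} of disjoint row
#'   indices. Within a replication the test folds partition the cohort.
#' @export
make_cv_plan <- function(cohort, plan = cv_plan()) {
  stopifnot(is_cohort_table(cohort), inherits(plan, "cv_plan"))
  n <- nrow(cohort)
  min_n <- 3L * plan$n_folds
  if (n < min_n)
    stopf("cohort too small for the plan: %d patients, minimum %d", n, min_n)
  sc <- cohort_schema(cohort)
  key <- if (plan$stratify_by == "grade")
    as.character(grade_stratum(cohort[[sc$outcome_column]]))
  else rep("all", n)
  valid_share <- plan$fractions[["valid"]] /
    (plan$fractions[["train"]] + plan$fractions[["valid"]])

  out <- list()
  for (r in seq_len(plan$n_replications)) {
    set.seed(child_seed(plan$master_seed, r))
    fold <- deal_folds(key, plan$n_folds)
    for (f in seq_len(plan$n_folds)) {
      test <- which(fold == f)
      rest <- which(fold != f)
      valid <- integer(0)
      for (s in unique(key[rest])) {
        cand <- sample(rest[key[rest] == s])
        n_v <- round(valid_share * length(cand))
        valid <- c(valid, cand[seq_len(n_v)])
      }
      train <- setdiff(rest, valid)
      out[[length(out) + 1L]] <-
        list(replication = r, fold = f, train = sort(train),
             valid = sort(valid), test = sort(test))
    }
  }
  out
}

#' Run the full evaluation protocol for one aberration
#'
#' For each racial group separately: replicated stratified
#' cross-validation in which the model is fitted on the train/validation
#' split and counterfactuals are inferred on the test fold; test-set
#' estimates are pooled within each replication and summarized as AICE
#' and RMSE per grade stratum (grades assigned by the observed Gleason
#' Score). Groups smaller than the plan's minimum are skipped with a
#' message; empty (race, grade) cells within a replication are emitted
#' with \code{n = 0} and missing metrics, never fabricated.
#'
#' @param cohort a \code{cohort_table}; any of its binary aberration
#'   columns may be studied.
#' @param aberration the intervention column to study; its mapped
#'   expression columns are excluded from the continuous proxies.
#' @param plan a \code{\link{cv_plan}}.
#' @param config a \code{\link{dlvm_config}}.
#' @param convention AICE/RMSE aggregation convention.
#' @param races race labels to include (default: all labels present with
#'   enough patients).
#' @return list with \code{metrics} (one row per race x grade x
#'   replication: n, aice, rmse, mean_ice, convention), \code{estimates}
#'   (pooled per-patient counterfactual estimates with race, grade and
#'   replication), and \code{skipped} (character vector of skipped race
#'   labels).
#' @export
run_aberration_experiment <- function(cohort, aberration, plan = cv_plan(),
                                      config = dlvm_config_desk(),
                                      convention = c("root", "mean-square"),
                                      races = NULL) {
  convention <- match.arg(convention)
  stopifnot(is_cohort_table(cohort))
  sc <- cohort_schema(cohort)
  if (!identical(aberration, sc$treatment_column))
    cohort <- designate_treatment(cohort, aberration)
  sc <- cohort_schema(cohort)
  if (aberration %in% names(sc$aberration_expression_map)) {
    sc2 <- exclude_intervention_expression(sc, aberration)
    cohort <- cohort_table(as.data.frame(cohort), sc2)
    sc <- sc2
  }

  race_all <- cohort[[sc$race_column]]
  if (is.null(races)) races <- sort(unique(race_all))
  metrics <- list(); est_rows <- list(); skipped <- character(0)

  for (rc in races) {
    sub <- cohort[race_all == rc, , drop = FALSE]
    sub <- cohort_table(as.data.frame(sub), sc)
    if (nrow(sub) < 3L * plan$n_folds) {
      skipped <- c(skipped, rc)
      message(sprintf("skipping race group '%s': %d patients (< %d)",
                      rc, nrow(sub), 3L * plan$n_folds))
      next
    }
    splits <- make_cv_plan(sub, plan)
    for (r in seq_len(plan$n_replications)) {
      pooled <- list()
      for (sp in splits[vapply(splits, function(s) s$replication == r, TRUE)]) {
        cfg <- config
        cfg$seed <- child_seed(config$seed, 1000L * r + sp$fold)
        tr <- cohort_table(as.data.frame(sub[sp$train, , drop = FALSE]), sc)
        va <- cohort_table(as.data.frame(sub[sp$valid, , drop = FALSE]), sc)
        te <- cohort_table(as.data.frame(sub[sp$test, , drop = FALSE]), sc)
        fit <- fit_dlvm(tr, va, cfg)
        est <- infer_counterfactual(fit, te, seed = cfg$seed)
        est$row <- sp$test
        pooled[[length(pooled) + 1L]] <- est
      }
      pooled <- do.call(rbind, pooled)
      pooled$race <- rc
      pooled$replication <- r
      pooled$grade <- as.character(grade_stratum(pooled$y_factual))
      pooled$aberration <- aberration
      est_rows[[length(est_rows) + 1L]] <- pooled
      for (g in c("low", "intermediate", "high")) {
        cell <- pooled[pooled$grade == g, , drop = FALSE]
        metrics[[length(metrics) + 1L]] <- data.frame(
          aberration = aberration, race = rc, grade = g, replication = r,
          n = nrow(cell),
          aice = if (nrow(cell)) as.numeric(aice(cell, convention)) else NA_real_,
          rmse = if (nrow(cell)) as.numeric(rmse(cell, convention)) else NA_real_,
          mean_ice = if (nrow(cell)) mean_ice(cell) else NA_real_,
          convention = convention, stringsAsFactors = FALSE)
      }
    }
  }
  list(metrics = do.call(rbind, metrics),
       estimates = do.call(rbind, est_rows),
       skipped = skipped, convention = convention)
}

#' Two-sided paired t-test between replicate metric vectors
#'
#' Replicate values are paired by replication index (each cross-validation
#' replication yields one metric value per group). Zero-variance
#' differences are reported at their limiting values with a degeneracy
#' flag instead of an error.
#'
#' @param values_a,values_b equal-length numeric vectors (length >= 2).
#' @param alpha significance level (default 0.05).
#' @param group_a,group_b,metric labels carried into the result.
#' @return An object of class \code{comparison_result}: list with
#'   \code{t_statistic}, \code{p_value}, \code{ci_low}, \code{ci_high}
#'   (95\% CI of the mean paired difference), \code{reject}
#'   (\code{p < alpha}), \code{degenerate}, and the labels.
#' @examples
#' paired_t_test(c(2, 3, 4), c(1, 1, 1))  # differences 1, 2, 3
#' @export
paired_t_test <- function(values_a, values_b, alpha = 0.05,
                          group_a = "A", group_b = "B", metric = "aice") {
  if (length(values_a) != length(values_b))
    stopf("paired vectors must have equal length (%d vs %d)",
          length(values_a), length(values_b))
  if (length(values_a) < 2L) stopf("need at least 2 paired values")
  d <- values_a - values_b
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    m <- mean(d)
    tt <- list(statistic = if (m == 0) 0 else sign(m) * Inf,
               p.value = if (m == 0) 1 else 0,
               conf.int = c(m, m))
  } else {
    tt <- stats::t.test(values_a, values_b, paired = TRUE,
                        conf.level = 0.95)
  }
  structure(list(group_a = group_a, group_b = group_b, metric = metric,
                 t_statistic = unname(tt$statistic),
                 p_value = unname(tt$p.value),
                 ci_low = tt$conf.int[1L], ci_high = tt$conf.int[2L],
                 mean_difference = mean(d), alpha = alpha,
                 reject = unname(tt$p.value) < alpha,
                 degenerate = degenerate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s on %s: t = %.4f, p = %.4g, 95%% CI [%.4f, %.4f], %s at alpha = %g%s\n",
              x$group_a, x$group_b, x$metric, x$t_statistic, x$p_value,
              x$ci_low, x$ci_high,
              if (x$reject) "REJECT" else "no rejection", x$alpha,
              if (x$degenerate) " (degenerate: zero-variance differences)" else ""))
  invisible(x)
}

#' Compare metric replicate vectors between two racial groups
#'
#' Applies the paired t-test per (aberration, grade) cell of an
#' experiment's metrics table. Raw per-comparison p-values are reported
#' (each at level \code{alpha}, uncorrected); Benjamini-Hochberg adjusted
#' p-values are appended as a clearly separate column.
#'
#' @param metrics the \code{metrics} data frame of
#'   \code{\link{run_aberration_experiment}}.
#' @param race_a,race_b the two group labels to compare.
#' @param metric \code{"aice"}, \code{"rmse"}, or \code{"grs"} (if
#'   present).
#' @param alpha significance level.
#' @return Data frame, one row per (aberration, grade): test statistics,
#'   CI, reject flag, and \code{p_adjusted_bh}.
#' @export
compare_race_groups <- function(metrics, race_a = "AA", race_b = "EA",
                                metric = "aice", alpha = 0.05) {
  rows <- list()
  for (ab in unique(metrics$aberration)) for (g in unique(metrics$grade)) {
    a <- metrics[metrics$aberration == ab & metrics$grade == g &
                   metrics$race == race_a, ]
    b <- metrics[metrics$aberration == ab & metrics$grade == g &
                   metrics$race == race_b, ]
    a <- a[order(a$replication), ]; b <- b[order(b$replication), ]
    if (!nrow(a) || !nrow(b) || anyNA(a[[metric]]) || anyNA(b[[metric]])) next
    cr <- paired_t_test(a[[metric]], b[[metric]], alpha,
                        group_a = race_a, group_b = race_b, metric = metric)
    rows[[length(rows) + 1L]] <- data.frame(
      aberration = ab, grade = g, metric = metric,
      group_a = race_a, group_b = race_b,
      mean_a = mean(a[[metric]]), mean_b = mean(b[[metric]]),
      mean_difference = cr$mean_difference,
      t_statistic = cr$t_statistic, p_value = cr$p_value,
      ci_low = cr$ci_low, ci_high = cr$ci_high,
      reject = cr$reject, degenerate = cr$degenerate,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$p_adjusted_bh <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Map estimated Gleason Scores to genomic risk scores in [0, 1]
#'
#' A monotone mapping from the estimated tumor grade to a population-level
#' metastasis-risk score. The default mapping is a logistic curve centered
#' at GS 7.5 with unit scale — a declared stand-in, \emph{not} the
#' published genomic risk assessment model; users may supply their own
#' monotone mapping (e.g. published coefficients) via \code{mapping}.
#'
#' @param estimated_gs numeric estimated Gleason Score(s).
#' @param mapping optional function; must be monotone non-decreasing on
#'   the GS range (checked on a probe grid) and is clipped into [0, 1].
#' @param center,scale parameters of the default logistic mapping.
#' @return Numeric risk score(s) in [0, 1].
#' @export
map_gs_to_grs <- function(estimated_gs, mapping = NULL,
                          center = 7.5, scale = 1) {
  f <- if (is.null(mapping))
    function(g) logistic((g - center) / scale)
  else mapping
  probe <- seq(2, 10, by = 0.25)
  pv <- f(probe)
  if (any(diff(pv) < -1e-12))
    stopf("GRS mapping must be monotone non-decreasing on the GS range")
  pmin(1, pmax(0, f(estimated_gs)))
}

#' Summarize an experiment into tidy report tables
#'
#' @param metrics metrics table(s) from
#'   \code{\link{run_aberration_experiment}} (rows may span several
#'   aberrations).
#' @param comparisons optional comparison table(s) from
#'   \code{\link{compare_race_groups}}.
#' @return list of data frames: \code{replicates} (one row per aberration
#'   x race x grade x replication x metric, long format),
#'   \code{summary} (replicate means and sds per cell), and
#'   \code{comparisons} (pass-through, possibly NULL).
#' @export
summarize_experiment <- function(metrics, comparisons = NULL) {
  long <- list()
  for (m in c("aice", "rmse", "mean_ice", "grs")) {
    if (!m %in% names(metrics)) next
    keep <- !is.na(metrics[[m]])
    if (!any(keep)) next
    long[[m]] <- data.frame(metrics[keep, c("aberration", "race", "grade",
                                            "replication", "n")],
                            metric = m, value = metrics[[m]][keep],
                            convention = metrics$convention[keep],
                            stringsAsFactors = FALSE)
  }
  replicates <- do.call(rbind, long)
  rownames(replicates) <- NULL
  key <- interaction(replicates$aberration, replicates$race,
                     replicates$grade, replicates$metric, drop = TRUE)
  agg <- do.call(rbind, lapply(split(replicates, key), function(d)
    data.frame(aberration = d$aberration[1L], race = d$race[1L],
               grade = d$grade[1L], metric = d$metric[1L],
               n_replications = nrow(d), mean = mean(d$value),
               sd = stats::sd(d$value), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(replicates = replicates, summary = agg, comparisons = comparisons)
}

#' Export metric box plots per aberration and grade
#'
#' One panel per grade stratum, replicate metric values boxed by race —
#' the standard visual for race-specific AICE/RMSE/GRS comparisons.
#' Written as a PNG via base graphics.
#'
#' @param metrics metrics table from
#'   \code{\link{run_aberration_experiment}} (a single aberration).
#' @param metric column to plot (\code{"aice"}, \code{"rmse"},
#'   \code{"grs"}).
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return \code{path}, invisibly.
#' @export
plot_metric_boxes <- function(metrics, metric = "aice", path,
                              width = 900, height = 350) {
  ab <- unique(metrics$aberration)
  if (length(ab) != 1L) stopf("plot one aberration at a time (got %d)",
                              length(ab))
  keep <- !is.na(metrics[[metric]])
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  for (g in c("low", "intermediate", "high")) {
    d <- metrics[keep & metrics$grade == g, ]
    if (nrow(d)) {
      graphics::boxplot(d[[metric]] ~ d$race, xlab = "race",
                        ylab = toupper(metric),
                        main = sprintf("%s — %s grade", ab, g))
    } else {
      graphics::plot.new()
      graphics::title(main = sprintf("%s — %s grade (no data)", ab, g))
    }
  }
  invisible(path)
}

#' Write / read a report table as tab-separated text
#'
#' Numeric values survive the round trip to at least 1e-9.
#'
#' @param table a data frame.
#' @param path file path.
#' @return \code{read_report_table} returns the data frame.
#' @export
write_report_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_table
#' @export
read_report_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
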