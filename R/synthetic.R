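#' Parameters of the synthetic data-generating process
#'
#' The generator is a forward simulation of the causal graph the latent
#' variable model assumes: Bernoulli latents z1 and Gaussian latents z2
#' mix into a joint confounder Z; discrete proxies x1 are bit-flipped
#' views of z1 and continuous proxies x2 are noisy linear views of z2;
#' the binary intervention is confounded through Z; potential outcomes
#' y(0), y(1) are generated on a continuous Gleason-like scale, rounded
#' into the valid GS range for the observed column, and both retained as
#' ground truth. Default dimensions are deliberately small (5 + 5 true
#' latents, 20 + 20 proxies) so full simulation studies run in minutes on
#' one CPU.
#'
#' @param n cohort size (overridden by \code{strata} sizes when given).
#' @param dim_z1_true,dim_z2_true true latent dimensions.
#' @param n_discrete_proxies,n_continuous_proxies proxy block widths.
#' @param flip_rate Bernoulli proxy bit-flip probability, in [0, 0.5).
#' @param x2_sd Gaussian proxy noise standard deviation.
#' @param confounding strength of the treatment's dependence on the
#'   standardized confounder score (0 = randomized).
#' @param effect_model \code{"zero"}, \code{"constant"}, or
#'   \code{"heterogeneous"} (effect modulated by Z, mean \code{tau}).
#' @param tau treatment effect size on the GS scale.
#' @param outcome_sd outcome noise standard deviation.
#' @param strata list of strata, each \code{list(label=, size=, effect_shift=)};
#'   default one \code{"EA"} stratum of size \code{n}.
#' @param gs_range integer bounds the observed GS is clipped into.
#' @param seed integer seed; the whole table is deterministic given it.
#' @return An object of class \code{dgp_params}.
#' @export
dgp_params <- function(n = 2000L, dim_z1_true = 5L, dim_z2_true = 5L,
                       n_discrete_proxies = 20L, n_continuous_proxies = 20L,
                       flip_rate = 0.1, x2_sd = 0.5, confounding = 1.0,
                       effect_model = c("constant", "zero", "heterogeneous"),
                       tau = 1.0, outcome_sd = 0.5, strata = NULL,
                       gs_range = c(2L, 10L), seed = 1L) {
  effect_model <- match.arg(effect_model)
  if (is.null(strata)) strata <- list(list(label = "EA", size = n))
  sizes <- vapply(strata, function(s) as.integer(s$size), 1L)
  if (any(sizes <= 0)) stopf("stratum sizes must be positive")
  n <- sum(sizes)
  if (flip_rate < 0 || flip_rate >= 0.5) stopf("flip_rate must be in [0, 0.5)")
  if (x2_sd <= 0 || outcome_sd <= 0) stopf("noise sds must be > 0")
  for (v in list(dim_z1_true, dim_z2_true, n_discrete_proxies,
                 n_continuous_proxies))
    if (!is_count(v)) stopf("dimensions must be positive integers")
  structure(list(n = n, dim_z1_true = as.integer(dim_z1_true),
                 dim_z2_true = as.integer(dim_z2_true),
                 n_discrete_proxies = as.integer(n_discrete_proxies),
                 n_continuous_proxies = as.integer(n_continuous_proxies),
                 flip_rate = flip_rate, x2_sd = x2_sd,
                 confounding = confounding, effect_model = effect_model,
                 tau = tau, outcome_sd = outcome_sd, strata = strata,
                 gs_range = as.integer(gs_range), seed = as.integer(seed)),
            class = "dgp_params")
}

# fixed structural coefficients of the DGP, drawn from their own seed so
# they are shared across cohorts that differ only in n or noise seeds
dgp_structure <- function(params) {
  set.seed(child_seed(params$seed, 101L))
  k1 <- params$dim_z1_true; k2 <- params$dim_z2_true
  dZ <- k2
  M1 <- matrix(stats::rnorm(k1 * dZ), k1, dZ) / sqrt(k1)
  M2 <- matrix(stats::rnorm(k2 * dZ), k2, dZ) / sqrt(k2)
  W2 <- matrix(stats::rnorm(k2 * params$n_continuous_proxies), k2,
               params$n_continuous_proxies)
  parent <- ((seq_len(params$n_discrete_proxies) - 1L) %% k1) + 1L
  w_t <- stats::rnorm(dZ)
  b_raw <- stats::rnorm(dZ)
  w_y <- (w_t + b_raw) / 2           # outcome score correlated with the
  w_h <- stats::rnorm(dZ)            # treatment score => confounding
  list(M1 = M1, M2 = M2, W2 = W2, parent = parent,
       w_t = w_t, w_y = w_y, w_h = w_h, dZ = dZ)
}

# analytic sd of a linear score a'Z where Z = (z1-0.5)'M1 + z2'M2
score_sd <- function(str, a) {
  v1 <- drop(str$M1 %*% a); v2 <- drop(str$M2 %*% a)
  sqrt(0.25 * sum(v1^2) + sum(v2^2))
}

#' Generate a synthetic cohort with known potential outcomes
#'
#' @param params a \code{\link{dgp_params}}.
#' @return A \code{\link{cohort_table}} whose extra columns carry the
#'   ground truth: integer potential outcomes \code{y0_true},
#'   \code{y1_true} (consistent with the observed outcome), their
#'   continuous-scale counterparts \code{y0_cont}, \code{y1_cont}, and the
#'   per-patient true effect \code{tau_true} (continuous scale, before
#'   rounding).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "dgp_params"))
  str <- dgp_structure(params)
  n <- params$n
  set.seed(child_seed(params$seed, 202L))

  z1 <- matrix(as.numeric(stats::runif(n * params$dim_z1_true) < 0.5), n,
               params$dim_z1_true)
  z2 <- matrix(stats::rnorm(n * params$dim_z2_true), n, params$dim_z2_true)
  Z <- (z1 - 0.5) %*% str$M1 + z2 %*% str$M2

  # discrete proxies: bit-flipped views of their parent z1 coordinate
  x1 <- z1[, str$parent, drop = FALSE]
  flips <- matrix(stats::runif(n * ncol(x1)) < params$flip_rate, n, ncol(x1))
  x1 <- abs(x1 - flips)
  colnames(x1) <- sprintf("d%02d", seq_len(ncol(x1)))

  x2 <- z2 %*% str$W2 +
    matrix(stats::rnorm(n * params$n_continuous_proxies, sd = params$x2_sd),
           n, params$n_continuous_proxies)
  colnames(x2) <- sprintf("c%02d", seq_len(ncol(x2)))

  u_t <- drop(Z %*% str$w_t) / score_sd(str, str$w_t)
  tv <- as.numeric(stats::runif(n) < logistic(params$confounding * u_t))

  race <- unlist(lapply(params$strata, function(s) rep(s$label, s$size)))
  shift <- unlist(lapply(params$strata,
                         function(s) rep(s$effect_shift %||% 0, s$size)))

  v_y <- drop(Z %*% str$w_y) / score_sd(str, str$w_y)
  y0_cont <- 8 + v_y + stats::rnorm(n, sd = params$outcome_sd)
  tau_i <- switch(params$effect_model,
                  zero = rep(0, n),
                  constant = rep(params$tau, n),
                  heterogeneous = params$tau * 2 *
                    logistic(drop(Z %*% str$w_h) / score_sd(str, str$w_h)))
  tau_i <- tau_i + shift
  y1_cont <- y0_cont + tau_i

  lo <- params$gs_range[1L]; hi <- params$gs_range[2L]
  y0_true <- pmin(hi, pmax(lo, round(y0_cont)))
  y1_true <- pmin(hi, pmax(lo, round(y1_cont)))
  y_obs <- ifelse(tv == 1, y1_true, y0_true)

  df <- data.frame(x1, x2, t_aberration = as.integer(tv),
                   gleason = as.integer(y_obs), race = race,
                   y0_true = as.integer(y0_true),
                   y1_true = as.integer(y1_true),
                   y0_cont = y0_cont, y1_cont = y1_cont, tau_true = tau_i,
                   check.names = FALSE)
  schema <- feature_schema(
    discrete_columns = colnames(x1),
    continuous_columns = colnames(x2),
    treatment_column = "t_aberration",
    outcome_column = "gleason",
    race_column = "race",
    aberration_expression_map = list(t_aberration = character(0)))
  cohort_table(df, schema)
}

#' True individual and group average treatment effects
#'
#' Requires the ground-truth block of a synthetic cohort. The ITE is
#' \code{y1_true - y0_true} per patient (integer scale; the
#' continuous-scale ITE is also returned when available), and the ATE its
#' mean per requested grouping.
#'
#' @param cohort a \code{cohort_table} with truth columns.
#' @param by optional column name(s) to group the ATE by.
#' @return list with \code{ite} (numeric vector), \code{ite_cont} (or
#'   NULL), and \code{ate} (data frame of group means of the integer-scale
#'   ITE).
#' @export
true_effects <- function(cohort, by = NULL) {
  stopifnot(is_cohort_table(cohort))
  if (!has_truth(cohort))
    stopf("cohort carries no ground-truth potential outcomes")
  ite <- cohort$y1_true - cohort$y0_true
  ite_cont <- if (all(c("y0_cont", "y1_cont") %in% names(cohort)))
    cohort$y1_cont - cohort$y0_cont else NULL
  ate <- if (is.null(by)) {
    data.frame(group = "all", ate = mean(ite))
  } else {
    key <- interaction(as.data.frame(cohort)[, by, drop = FALSE], drop = TRUE)
    stats::aggregate(data.frame(ate = ite), list(group = key), mean)
  }
  list(ite = ite, ite_cont = ite_cont, ate = ate)
}

# -- prostate-cohort-shaped fixture ------------------------------------------

prad_aberrations <- c("ERG_fusion",
                      "SPOP_mut", "TP53_mut", "FOXA1_mut", "ATM_mut",
                      "BRCA2_mut", "PTEN_mut",
                      "BRCA1_germline", "BRCA2_germline",
                      "LCP1_cna", "ERG_cna", "PTEN_cna", "FOXA1_cna")

prad_expression_map <- function() {
  list(ERG_fusion = "ERG_expr",
       SPOP_mut = "SPOP_expr", TP53_mut = "TP53_expr",
       FOXA1_mut = "FOXA1_expr", ATM_mut = "ATM_expr",
       BRCA2_mut = "BRCA2_expr", PTEN_mut = "PTEN_expr",
       BRCA1_germline = character(0), BRCA2_germline = character(0),
       LCP1_cna = "LCP1_expr", ERG_cna = "ERG_expr",
       PTEN_cna = "PTEN_expr", FOXA1_cna = "FOXA1_expr")
}

#' Generate a synthetic cohort shaped like the TCGA prostate cohort
#'
#' A 313-patient cohort with the published stratum sizes (270 EA, 43 AA),
#' the 13 studied aberration columns (ERG fusion; somatic SPOP, TP53,
#' FOXA1, ATM, BRCA2, PTEN; germline BRCA1, BRCA2; CNAs in LCP1, ERG,
#' PTEN, FOXA1), an expression block linked to the aberrations through an
#' aberration-to-expression map, and integer Gleason Scores in 6-10
#' populating all three grade strata in both races. All values are
#' synthetic (simulated from the package's own generative process); no
#' real patient data is used or emulated beyond the layout. The ERG fusion
#' is the designated intervention of the emitted schema and the
#' ground-truth block refers to it; use
#' \code{\link{designate_treatment}} to study another aberration.
#'
#' @param seed integer seed.
#' @return A \code{\link{cohort_table}} with truth block.
#' @export
generate_prad_like_fixture <- function(seed = 1L) {
  set.seed(child_seed(seed, 303L))
  sizes <- c(EA = 270L, AA = 43L)
  n <- sum(sizes)
  race <- rep(names(sizes), sizes)
  g <- stats::rnorm(n) + 0.3 * (race == "AA")   # latent tumor-risk score

  ab <- matrix(0L, n, length(prad_aberrations),
               dimnames = list(NULL, prad_aberrations))
  base_logit <- stats::runif(length(prad_aberrations), -2.4, -0.6)
  load <- stats::runif(length(prad_aberrations), 0.3, 0.9)
  for (j in seq_along(prad_aberrations))
    ab[, j] <- as.integer(stats::runif(n) <
                            logistic(base_logit[j] + load[j] * g))

  genes <- c("ERG", "SPOP", "TP53", "FOXA1", "ATM", "BRCA2", "PTEN", "LCP1")
  expr <- sapply(genes, function(gene) {
    drivers <- prad_aberrations[grepl(paste0("^", gene, "_"),
                                      prad_aberrations) &
                                  !grepl("germline", prad_aberrations)]
    eff <- if (length(drivers))
      rowSums(ab[, drivers, drop = FALSE]) * 1.5 else 0
    eff + 0.5 * g + stats::rnorm(n, sd = 0.7)
  })
  colnames(expr) <- paste0(genes, "_expr")
  age <- round(61 + 5 * g + stats::rnorm(n, sd = 4), 1)

  tv <- ab[, "ERG_fusion"]
  tau_i <- 0.5 + 0.4 * (race == "AA")
  y0_cont <- 7.6 + 0.9 * g + stats::rnorm(n, sd = 0.5)
  y1_cont <- y0_cont + tau_i
  y0_true <- pmin(10L, pmax(6L, as.integer(round(y0_cont))))
  y1_true <- pmin(10L, pmax(6L, as.integer(round(y1_cont))))
  y_obs <- ifelse(tv == 1L, y1_true, y0_true)

  # deterministic fix-up: guarantee every race x grade cell is populated
  for (r in names(sizes)) for (target in c(6L, 7L, 9L)) {
    cell <- race == r & grade_stratum(y_obs) == grade_stratum(target)
    if (!any(cell)) {
      i <- which(race == r)[which.min(abs(y_obs[race == r] - target))]
      delta <- target - y_obs[i]
      y0_true[i] <- pmin(10L, pmax(6L, y0_true[i] + delta))
      y1_true[i] <- pmin(10L, pmax(6L, y1_true[i] + delta))
      y_obs[i] <- if (tv[i] == 1L) y1_true[i] else y0_true[i]
    }
  }

  df <- data.frame(ab, expr, age = age, gleason = as.integer(y_obs),
                   race = race,
                   y0_true = y0_true, y1_true = y1_true,
                   y0_cont = y0_cont, y1_cont = y1_cont, tau_true = tau_i,
                   check.names = FALSE)
  schema <- feature_schema(
    discrete_columns = setdiff(prad_aberrations, "ERG_fusion"),
    continuous_columns = c(colnames(expr), "age"),
    treatment_column = "ERG_fusion",
    outcome_column = "gleason",
    race_column = "race",
    aberration_expression_map = prad_expression_map())
  cohort_table(df, schema)
}

#' Re-designate which aberration is the intervention column
#'
#' Moves the current treatment column back into the discrete proxy set and
#' promotes the named aberration to intervention. The truth block (if any)
#' is dropped, since recorded potential outcomes refer to the previously
#' designated intervention.
#'
#' @param cohort a \code{cohort_table}.
#' @param aberration name of a binary column to treat as the intervention.
#' @return A new \code{cohort_table}.
#' @export
designate_treatment <- function(cohort, aberration) {
  stopifnot(is_cohort_table(cohort))
  sc <- cohort_schema(cohort)
  if (identical(aberration, sc$treatment_column)) return(cohort)
  if (!aberration %in% sc$discrete_columns)
    stopf("'%s' is not a discrete column of the cohort", aberration)
  v <- cohort[[aberration]]
  if (!all(v %in% c(0, 1)))
    stopf("'%s' is not binary and cannot be an intervention", aberration)
  new_schema <- feature_schema(
    discrete_columns = c(setdiff(sc$discrete_columns, aberration),
                         sc$treatment_column),
    continuous_columns = sc$continuous_columns,
    treatment_column = aberration,
    outcome_column = sc$outcome_column,
    race_column = sc$race_column,
    aberration_expression_map = sc$aberration_expression_map)
  df <- as.data.frame(cohort)
  df <- df[, setdiff(names(df),
                     c("y0_true", "y1_true", "y0_cont", "y1_cont",
                       "tau_true")), drop = FALSE]
  cohort_table(df, new_schema)
}
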