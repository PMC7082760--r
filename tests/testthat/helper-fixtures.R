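# Shared fixtures: all test data is built in code, none stored on disk.

toy_schema <- function() {
  feature_schema(
    discrete_columns = c("d1", "d2", "d3"),
    continuous_columns = c("ERG_expr", "c1", "c2"),
    treatment_column = "t",
    outcome_column = "gs",
    race_column = "race",
    aberration_expression_map = list(ERG = "ERG_expr",
                                     BRCA1_germline = character(0)))
}

toy_cohort <- function(n = 5L, seed = 42L) {
  set.seed(seed)
  df <- data.frame(
    d1 = rbinom(n, 1, 0.5), d2 = rbinom(n, 1, 0.3),
    d3 = sample(c("a", "b", "c"), n, replace = TRUE),
    ERG_expr = rnorm(n), c1 = rnorm(n), c2 = rnorm(n),
    t = rbinom(n, 1, 0.5),
    gs = sample(6:10, n, replace = TRUE),
    race = sample(c("EA", "AA", "Asian", "unknown"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  cohort_table(df, toy_schema())
}

# a random cohort with arbitrary shape, for round-trip property tests
random_cohort <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  nd <- sample(1:4, 1); nc <- sample(1:4, 1)
  df <- data.frame(matrix(rbinom(n * nd, 1, 0.5), n, nd))
  names(df) <- paste0("d", seq_len(nd))
  for (j in seq_len(nc)) df[[paste0("c", j)]] <- round(rnorm(n), 6)
  df$t <- rbinom(n, 1, 0.5)
  df$gs <- sample(2:10, n, replace = TRUE)
  df$race <- sample(c("EA", "AA", "Asian", "unknown"), n, replace = TRUE)
  schema <- feature_schema(paste0("d", seq_len(nd)),
                           paste0("c", seq_len(nc)),
                           "t", "gs", "race")
  cohort_table(df, schema)
}

# module-level cache so expensive fits are shared across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small confounded synthetic cohort + fitted model, reused by several files
small_sim <- function() {
  cached("small_sim", {
    co <- generate_cohort(dgp_params(n = 500, seed = 3))
    set.seed(1)
    idx <- sample(nrow(co))
    list(cohort = co,
         train = co[idx[1:320], ], valid = co[idx[321:400], ],
         test = co[idx[401:500], ])
  })
}

small_fit <- function() {
  cached("small_fit", {
    s <- small_sim()
    fit_dlvm(s$train, s$valid, dlvm_config_desk(epochs = 30L, seed = 7L))
  })
}

# Three well-separated Gaussian classes embedded in a cohort layout: a
# Bayes-separable construction on which a working classifier must score
# highly.
separable_cohort <- function(n_per = 200L, sep = 5, seed = 1L) {
  set.seed(seed)
  classes <- c("AA", "Asian", "EA")
  centers <- rbind(c(0, 0, 0, 0), c(sep, sep, 0, 0), c(0, 0, sep, sep))
  n <- n_per * 3L
  lab <- rep(classes, each = n_per)
  X <- centers[rep(1:3, each = n_per), ] + matrix(rnorm(n * 4), n, 4)
  df <- data.frame(d1 = rbinom(n, 1, 0.5),
                   X, t = rbinom(n, 1, 0.5),
                   gs = sample(6:10, n, replace = TRUE), race = lab,
                   stringsAsFactors = FALSE)
  names(df)[2:5] <- paste0("c", 1:4)
  schema <- feature_schema("d1", paste0("c", 1:4), "t", "gs", "race")
  cohort_table(df[sample(n), ], schema)
}

# tiny model for ELBO oracle / gradient work: 2-dim latents, 2 patients
tiny_setup <- function(outcome_model = "gaussian") {
  set.seed(99)
  n <- 24L
  df <- data.frame(d1 = rbinom(n, 1, 0.5), d2 = rbinom(n, 1, 0.4),
                   d3 = rbinom(n, 1, 0.6),
                   c1 = rnorm(n), c2 = rnorm(n), c3 = rnorm(n),
                   t = rbinom(n, 1, 0.5), gs = sample(6:9, n, TRUE),
                   race = "EA", stringsAsFactors = FALSE)
  schema <- feature_schema(c("d1", "d2", "d3"), c("c1", "c2", "c3"),
                           "t", "gs", "race")
  cohort <- cohort_table(df, schema)
  cfg <- dlvm_config(dim_Z = 2L, dim_z1 = 2L, dim_z2 = 2L,
                     hidden_sizes = 4L, hidden_activation = "tanh",
                     epochs = 3L, batch_size = 8L, learning_rate = 1e-2,
                     decay_rate = 0, outcome_model = outcome_model,
                     seed = 5L)
  list(cohort = cohort, cfg = cfg,
       model = suppressWarnings(fit_dlvm(cohort, NULL, cfg)))
}
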