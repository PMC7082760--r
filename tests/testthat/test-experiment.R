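test_that("the CV plan yields 30 stratified triples with the stated fractions", {
  co <- generate_cohort(dgp_params(n = 300, seed = 21))
  plan <- cv_plan(master_seed = 77L)
  splits <- make_cv_plan(co, plan)
  expect_length(splits, 30L)

  for (r in 1:10) {
    reps <- Filter(function(s) s$replication == r, splits)
    tests <- lapply(reps, `[[`, "test")
    expect_identical(sort(unlist(tests)), 1:300)   # partition, disjoint
    expect_equal(sum(lengths(tests)), 300L)
    for (s in reps) {
      expect_length(intersect(s$train, s$valid), 0L)
      expect_length(intersect(s$train, s$test), 0L)
      expect_length(intersect(s$valid, s$test), 0L)
      expect_lt(abs(length(s$train) / 300 - 0.47), 0.03)
      expect_lt(abs(length(s$valid) / 300 - 0.20), 0.03)
      expect_lt(abs(length(s$test) / 300 - 1 / 3), 0.03)
    }
  }

  # deterministic in the master seed
  expect_identical(splits, make_cv_plan(co, plan))
  expect_false(identical(splits,
                         make_cv_plan(co, cv_plan(master_seed = 78L))))

  expect_error(make_cv_plan(co[1:8, ], plan), "minimum 9")
  expect_error(cv_plan(fractions = c(train = 0.6, valid = 0.3,
                                     test = 0.3)), "sum to 1")
})

test_that("the paired t-test reproduces the textbook example and edge cases", {
  # differences 1, 2, 3: mean 2, sd 1, t = 2 / (1/sqrt(3)) = 3.4641
  r <- paired_t_test(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$t_statistic, 2 * sqrt(3), tolerance = 1e-6)
  expect_equal(r$t_statistic, 3.4641, tolerance = 1e-4)
  expect_equal(r$p_value, 2 * stats::pt(-2 * sqrt(3), df = 2))
  expect_equal(r$p_value, 0.0742, tolerance = 1e-3)
  expect_false(r$reject)

  ident <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t_statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_false(ident$reject)
  expect_true(ident$degenerate)

  degen <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 0)
  expect_true(degen$reject)

  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    r <- paired_t_test(a, b)
    expect_true(r$ci_low <= mean(a - b) && mean(a - b) <= r$ci_high)
    expect_identical(r$reject, r$p_value < r$alpha)
  }
  expect_error(paired_t_test(1:3, 1:4), "equal length")
  expect_error(paired_t_test(1, 2), "at least 2")
})

test_that("group comparison machinery is calibrated and has directional power", {
  # analytic stand-in for the metric: simulated replicate AICE vectors
  set.seed(42)
  nulls <- replicate(200, {
    paired_t_test(rnorm(10, 1.5, 0.3), rnorm(10, 1.5, 0.3))$reject
  })
  rate_null <- mean(nulls)
  expect_gte(rate_null, 0.015)   # 99% binomial band around 5% at 200 reps
  expect_lte(rate_null, 0.095)

  shifted <- replicate(200, {
    paired_t_test(rnorm(10, 2.5, 0.3), rnorm(10, 1.5, 0.3))$reject
  })
  expect_gt(mean(shifted), rate_null)
})

test_that("the risk-score mapping is monotone, bounded and midpoint-calibrated", {
  expect_equal(map_gs_to_grs(7.5), 0.5)
  g <- sort(runif(50, 0, 20))
  v <- map_gs_to_grs(g)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diff(v) >= 0))
  # extreme inputs stay clipped
  expect_equal(map_gs_to_grs(1e6, mapping = function(x) x / 10 - 1e5 + 2), 1)
  expect_error(map_gs_to_grs(7, mapping = function(x) -x), "monotone")
})

test_that("the per-aberration experiment pools every patient once per replication", {
  co <- generate_cohort(dgp_params(
    seed = 23, strata = list(list(label = "EA", size = 45))))
  plan <- cv_plan(n_replications = 10L, master_seed = 5L)
  cfg <- dlvm_config_desk(dim_Z = 4L, dim_z1 = 6L, dim_z2 = 6L,
                          hidden_sizes = c(8L, 8L), epochs = 2L,
                          batch_size = 32L, seed = 11L)
  res <- run_aberration_experiment(co, "t_aberration", plan, cfg)

  # replicate vectors have length 10 under the default plan
  cell <- res$metrics[res$metrics$race == "EA" &
                        res$metrics$grade == "intermediate", ]
  expect_equal(sort(cell$replication), 1:10)

  # every patient contributes exactly one test-set estimate per replication
  for (r in 1:10) {
    est_r <- res$estimates[res$estimates$replication == r, ]
    expect_identical(sort(est_r$row), 1:45)
  }
  # grade cells partition the pooled estimates
  expect_equal(sum(res$metrics$n[res$metrics$replication == 1]), 45L)

  # too-small groups are skipped, not fitted
  df <- as.data.frame(co)
  df$race[1:4] <- "AA"
  co2 <- cohort_table(df, cohort_schema(co))
  expect_message(
    res2 <- run_aberration_experiment(co2, "t_aberration",
                                      cv_plan(n_replications = 1L,
                                              master_seed = 5L), cfg),
    "skipping")
  expect_identical(res2$skipped, "AA")
})

test_that("AICE grows with the true effect size in paired simulations", {
  plan <- cv_plan(n_replications = 2L, master_seed = 9L)
  cfg <- dlvm_config_desk(epochs = 20L, seed = 31L)
  vals <- sapply(c(0, 2), function(tau) {
    p <- dgp_params(n = 150, seed = 77,
                    effect_model = if (tau == 0) "zero" else "constant",
                    tau = tau)
    co <- generate_cohort(p)
    res <- run_aberration_experiment(co, "t_aberration", plan, cfg)
    mean(res$metrics$aice[res$metrics$n > 0])
  })
  expect_lt(vals[1], vals[2])
})

test_that("summaries mirror their inputs and survive serialization", {
  set.seed(6)
  metrics <- expand.grid(aberration = c("A1", "A2"), race = c("AA", "EA"),
                         grade = c("low", "intermediate", "high"),
                         replication = 1:10, stringsAsFactors = FALSE)
  metrics$n <- 5L
  metrics$aice <- rnorm(nrow(metrics), 1.4, 0.2) +
    0.5 * (metrics$race == "AA" & metrics$aberration == "A1")
  metrics$rmse <- abs(rnorm(nrow(metrics), 0.8, 0.1))
  metrics$mean_ice <- rnorm(nrow(metrics), 0, 0.2)
  metrics$convention <- "root"

  cmp <- compare_race_groups(metrics, "AA", "EA", metric = "aice")
  expect_equal(nrow(cmp), 6L)   # 2 aberrations x 3 grades
  expect_true(all(cmp$reject == (cmp$p_value < 0.05)))
  expect_true(all(cmp$ci_low <= cmp$ci_high))
  expect_true("p_adjusted_bh" %in% names(cmp))
  # the planted A1 effect should dominate the smallest p-values
  expect_true(all(cmp$aberration[order(cmp$p_value)][1:3] == "A1"))

  rep_tabs <- summarize_experiment(metrics, cmp)
  # row count: aberrations x races x grades x replications x metrics
  expect_equal(nrow(rep_tabs$replicates), 2L * 2L * 3L * 10L * 3L)
  expect_equal(nrow(rep_tabs$summary), 2L * 2L * 3L * 3L)
  expect_identical(rep_tabs$comparisons$reject, cmp$reject)

  p <- withr::local_tempfile(fileext = ".tsv")
  write_report_table(rep_tabs$replicates, p)
  back <- read_report_table(p)
  expect_equal(back$value, rep_tabs$replicates$value, tolerance = 1e-9)
  write_report_table(cmp, p)
  back2 <- read_report_table(p)
  expect_equal(back2$p_value, cmp$p_value, tolerance = 1e-9)
  expect_identical(back2$reject, cmp$reject)
})

test_that("box-plot export writes one panel set per aberration", {
  set.seed(2)
  metrics <- expand.grid(aberration = "A1", race = c("AA", "EA"),
                         grade = c("low", "intermediate", "high"),
                         replication = 1:10, stringsAsFactors = FALSE)
  metrics$aice <- abs(rnorm(nrow(metrics), 1.2, 0.2))
  p <- withr::local_tempfile(fileext = ".png")
  plot_metric_boxes(metrics, "aice", p)
  expect_true(file.exists(p) && file.size(p) > 0)
  metrics2 <- rbind(metrics, within(metrics, aberration <- "A2"))
  expect_error(plot_metric_boxes(metrics2, "aice", p), "one aberration")
})
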