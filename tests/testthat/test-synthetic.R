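test_that("the generator is deterministic and internally consistent", {
  p <- dgp_params(n = 300, seed = 5)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # consistency: observed outcome equals the selected potential outcome
  expect_identical(a$gleason,
                   ifelse(a$t_aberration == 1L, a$y1_true, a$y0_true))

  # generated tables pass validation with no warnings
  expect_no_warning(cohort_table(as.data.frame(a), cohort_schema(a)))
})

test_that("effect models shape the truth block as constructed", {
  z <- generate_cohort(dgp_params(n = 400, seed = 6, effect_model = "zero"))
  expect_identical(z$y0_true, z$y1_true)
  expect_true(all(z$tau_true == 0))
  expect_equal(true_effects(z)$ate$ate, 0)

  cst <- generate_cohort(dgp_params(n = 400, seed = 6, tau = 1.5))
  expect_true(all(cst$tau_true == 1.5))
  expect_equal(cst$y1_cont - cst$y0_cont, rep(1.5, 400))

  te <- true_effects(cst)
  expect_identical(te$ite, cst$y1_true - cst$y0_true)
  expect_equal(te$ite_cont, rep(1.5, 400))
  expect_error(true_effects(designate_treatment(
    generate_prad_like_fixture(1), "SPOP_mut")), "no ground-truth")
})

test_that("heterogeneous effects average to the quadrature mean of tau(Z)", {
  p <- dgp_params(n = 40000, seed = 8, effect_model = "heterogeneous",
                  tau = 1.2)
  co <- generate_cohort(p)
  # high-n forward run serves as the oracle for E[tau(Z)]; by symmetry of
  # the latent mixing the expectation is tau itself
  expect_equal(mean(co$tau_true), 1.2, tolerance = 0.02)
  expect_equal(mean(co$y1_cont - co$y0_cont), mean(co$tau_true))
})

test_that("the treatment marginal matches a large-sample forward oracle", {
  p <- dgp_params(n = 4000, seed = 9, confounding = 1.0)
  co <- generate_cohort(p)
  p_hat <- mean(co$t_aberration)
  # oracle: 1e6-draw forward simulation of the same assignment mechanism
  str <- dlvmcf:::dgp_structure(p)
  set.seed(12345)
  m <- 1e6
  z1 <- matrix(as.numeric(runif(m * p$dim_z1_true) < 0.5), m)
  z2 <- matrix(rnorm(m * p$dim_z2_true), m)
  Z <- (z1 - 0.5) %*% str$M1 + z2 %*% str$M2
  u <- drop(Z %*% str$w_t) / dlvmcf:::score_sd(str, str$w_t)
  p_true <- mean(dlvmcf:::logistic(p$confounding * u))
  se <- sqrt(p_true * (1 - p_true) / nrow(co))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("the confounding knob monotonically strengthens the t-confounder correlation", {
  cors <- sapply(c(0, 1, 3), function(cf) {
    p <- dgp_params(n = 5000, seed = 10, confounding = cf)
    co <- generate_cohort(p)
    str <- dlvmcf:::dgp_structure(p)
    # recompute the true confounder score for the generated rows
    set.seed(dlvmcf:::child_seed(p$seed, 202L))
    z1 <- matrix(as.numeric(runif(5000 * p$dim_z1_true) < 0.5), 5000)
    z2 <- matrix(rnorm(5000 * p$dim_z2_true), 5000)
    Z <- (z1 - 0.5) %*% str$M1 + z2 %*% str$M2
    u <- drop(Z %*% str$w_t)
    cor(co$t_aberration, u)
  })
  expect_true(all(diff(cors) > 0))
})

test_that("parameter validation rejects invalid settings", {
  expect_error(dgp_params(flip_rate = 0.6), "flip_rate")
  expect_error(dgp_params(x2_sd = 0), "sds")
  expect_error(dgp_params(strata = list(list(label = "EA", size = 0))),
               "positive")
})

test_that("strata control sizes, labels and effect shifts", {
  p <- dgp_params(seed = 4, tau = 0.5,
                  strata = list(list(label = "EA", size = 150),
                                list(label = "AA", size = 50,
                                     effect_shift = 0.7)))
  co <- generate_cohort(p)
  expect_equal(nrow(co), 200L)
  expect_equal(sum(co$race == "EA"), 150L)
  expect_equal(sum(co$race == "AA"), 50L)
  expect_true(all(co$tau_true[co$race == "EA"] == 0.5))
  expect_true(all(co$tau_true[co$race == "AA"] == 1.2))
})

test_that("the prostate-shaped fixture has the published layout", {
  co <- generate_prad_like_fixture(seed = 1)
  expect_equal(nrow(co), 313L)
  expect_equal(sum(co$race == "EA"), 270L)
  expect_equal(sum(co$race == "AA"), 43L)

  expected <- c("ERG_fusion", "SPOP_mut", "TP53_mut", "FOXA1_mut",
                "ATM_mut", "BRCA2_mut", "PTEN_mut", "BRCA1_germline",
                "BRCA2_germline", "LCP1_cna", "ERG_cna", "PTEN_cna",
                "FOXA1_cna")
  expect_true(all(expected %in% names(co)))
  expect_true(all(vapply(expected, function(cn) all(co[[cn]] %in% 0:1),
                         TRUE)))

  sc <- cohort_schema(co)
  expect_identical(sc$aberration_expression_map$ERG_fusion, "ERG_expr")
  expect_identical(sc$aberration_expression_map$BRCA1_germline,
                   character(0))
  expect_true(all(co$gleason >= 6L & co$gleason <= 10L))
  # every race x grade cell populated
  tab <- table(co$race, grade_stratum(co$gleason))
  expect_true(all(tab > 0))
  # deterministic
  expect_identical(as.data.frame(generate_prad_like_fixture(seed = 1)),
                   as.data.frame(co))
})
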