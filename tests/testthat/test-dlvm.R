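test_that("fitting is deterministic given the seed and rejects bad inputs", {
  s <- small_sim()
  sub <- s$cohort[1:60, ]
  cfg <- dlvm_config_desk(epochs = 4L, seed = 13L)
  f1 <- fit_dlvm(sub, NULL, cfg)
  f2 <- fit_dlvm(sub, NULL, cfg)
  p1 <- dlvmcf:::dlvm_get_params(f1$nets)
  p2 <- dlvmcf:::dlvm_get_params(f2$nets)
  expect_identical(p1, p2)
  # parameter checksum, the coarse version of the same contract
  csum <- function(p) sum(abs(unlist(p)))
  expect_identical(csum(p1), csum(p2))

  expect_error(fit_dlvm(s$cohort[0, ], NULL, cfg), "empty")

  one_arm <- s$cohort[s$cohort$t_aberration == 1, ][1:30, ]
  expect_warning(fit_dlvm(one_arm, NULL, cfg), "not identifiable")
})

test_that("closed-form KL terms are zero at the prior and non-negative elsewhere", {
  ts <- tiny_setup()
  cfg <- ts$cfg
  enc <- dlvmcf:::dlvm_encode(ts$cohort, cohort_schema(ts$cohort), ts$model)
  batch <- list(x1 = enc$x1, x2 = enc$x2, tv = enc$tv, ys = enc$ys,
                ycls = enc$ycls)

  # force every encoder head to output exactly the prior parameters:
  # logits 0 (p = 1/2), Gaussian mean 0 / logvar 0 on both q and p heads
  nets0 <- ts$model$nets
  for (nm in c("enc_z1", "enc_z2", "enc_Z", "prior_Z")) {
    L <- length(nets0[[nm]]$W)
    nets0[[nm]]$W[[L]] <- nets0[[nm]]$W[[L]] * 0
    nets0[[nm]]$b[[L]] <- nets0[[nm]]$b[[L]] * 0
  }
  set.seed(1)
  res0 <- dlvmcf:::dlvm_step(nets0, cfg, batch, grad = FALSE, sample = TRUE)
  expect_equal(unname(res0$kl), c(0, 0, 0), tolerance = 1e-12)

  # generic fitted encoders: every KL component non-negative on random
  # sub-batches (Gibbs' inequality, via the closed forms)
  set.seed(2)
  for (i in 1:10) {
    idx <- sample(nrow(enc$x1), 8L)
    b <- list(x1 = enc$x1[idx, ], x2 = enc$x2[idx, ], tv = enc$tv[idx],
              ys = enc$ys[idx], ycls = enc$ycls[idx])
    res <- dlvmcf:::dlvm_step(ts$model$nets, cfg, b, grad = FALSE,
                              sample = TRUE)
    expect_true(all(res$kl >= 0))
  }
})

test_that("Monte-Carlo ELBO matches a quadrature/enumeration oracle at 2-dim latents", {
  skip_if_not_installed("pracma")
  ts <- tiny_setup()
  two <- ts$cohort[1:2, ]
  oracle <- mean(c(elbo_enum_oracle(ts$model, two, 1L),
                   elbo_enum_oracle(ts$model, two, 2L)))
  mc <- dlvm_elbo(ts$model, two, n_samples = 1e4, seed = 2L)
  expect_lt(abs(as.numeric(mc) - oracle) / abs(oracle), 0.005)
})

test_that("factual reconstruction is the factual arm of counterfactual inference", {
  fit <- small_fit()
  s <- small_sim()
  est <- infer_counterfactual(fit, s$test, seed = 17L)
  rec <- reconstruct_factual(fit, s$test, seed = 17L)
  expect_identical(rec, ifelse(est$t_factual == 1L, est$y_hat_1,
                               est$y_hat_0))
  expect_true(all(is.finite(est$y_hat_0)))
  expect_true(all(is.finite(est$y_hat_1)))
  # ICE identity per the definition
  expect_equal(est$ice, ifelse(est$t_factual == 1L,
                               est$y_factual - est$y_hat_0,
                               est$y_hat_1 - est$y_factual))
  # beats the constant predictor from the training outcomes
  ybar <- mean(s$train$gleason)
  expect_lt(mean(abs(rec - s$test$gleason)),
            mean(abs(ybar - s$test$gleason)))
})

test_that("Monte-Carlo estimates converge with the posterior sample size", {
  fit <- small_fit()
  s <- small_sim()
  te <- s$test[1:40, ]
  ref <- infer_counterfactual(fit, te, n_samples = 4096L, seed = 100L)
  err <- sapply(c(1L, 16L, 256L), function(S) {
    devs <- sapply(1:6, function(r) {
      est <- infer_counterfactual(fit, te, n_samples = S, seed = 100L + r)
      mean(abs(est$y_hat_1 - ref$y_hat_1))
    })
    mean(devs)
  })
  expect_true(all(diff(err) < 0))
})

test_that("row permutations permute the estimates identically", {
  fit <- small_fit()
  s <- small_sim()
  te <- s$test
  set.seed(8)
  perm <- sample(nrow(te))
  est <- infer_counterfactual(fit, te, n_samples = 64L, seed = 5L)
  est_p <- infer_counterfactual(fit, te[perm, ], n_samples = 64L, seed = 5L)
  rownames(est) <- rownames(est_p) <- NULL
  expect_equal(est[perm, ], est_p, ignore_attr = TRUE)
})

test_that("the smoothed training objective trends upward late in training", {
  s <- small_sim()
  ok <- 0L
  for (sd in 1:5) {
    fit <- fit_dlvm(s$train, s$valid, dlvm_config_desk(epochs = 30L,
                                                       seed = sd))
    obj <- fit$training_log$train_objective
    ma <- stats::filter(obj, rep(1 / 10, 10), sides = 1L)
    late <- ma[!is.na(ma)]
    late <- late[max(1L, ceiling(0.2 * length(late))):length(late)]
    if (all(diff(late) > -0.05 * stats::sd(obj))) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("the ordinal outcome head yields simplex probabilities and usable estimates", {
  s <- small_sim()
  cfg <- dlvm_config_desk(epochs = 10L, seed = 3L, outcome_model = "ordinal")
  fit <- fit_dlvm(s$train[1:150, ], NULL, cfg)
  te <- s$test[1:30, ]
  est <- infer_counterfactual(fit, te, n_samples = 32L)
  expect_true(all(est$y_hat_0 >= min(fit$y_levels) &
                    est$y_hat_0 <= max(fit$y_levels)))
  expect_true(all(is.finite(est$ice)))
  # the categorical head itself is a simplex on random latent inputs
  set.seed(4)
  Z <- matrix(rnorm(20 * fit$config$dim_Z), 20L)
  p <- dlvmcf:::softmax_rows(
    dlvmcf:::mlp_forward(fit$nets$dec_y, cbind(Z, rbinom(20, 1, 0.5)))$out)
  expect_equal(rowSums(p), rep(1, 20L), tolerance = 1e-6)
})

test_that("proxies-only conditioning infers without using the observed outcome", {
  fit <- small_fit()
  s <- small_sim()
  te <- s$test[1:25, ]
  est <- infer_counterfactual(fit, te, n_samples = 64L,
                              conditioning = "proxies-only", seed = 9L)
  expect_true(all(is.finite(est$y_hat_0 + est$y_hat_1)))
  # altering y must not change proxies-only estimates
  df <- as.data.frame(te)
  df$gleason <- pmax(6L, pmin(10L, df$gleason + sample(c(-1L, 1L), 25L,
                                                       TRUE)))
  te2 <- cohort_table(df[, !(names(df) %in%
                               c("y0_true", "y1_true", "y0_cont",
                                 "y1_cont", "tau_true"))],
                      cohort_schema(te))
  est2 <- infer_counterfactual(fit, te2, n_samples = 64L,
                               conditioning = "proxies-only", seed = 9L)
  expect_equal(est$y_hat_1, est2$y_hat_1)
})

test_that("checkpoints round-trip and refuse a mismatched schema", {
  fit <- small_fit()
  s <- small_sim()
  p <- withr::local_tempfile(fileext = ".rds")
  save_dlvm(fit, p)
  back <- load_dlvm(p, cohort_schema(s$cohort))
  est1 <- infer_counterfactual(fit, s$test[1:10, ], n_samples = 16L)
  est2 <- infer_counterfactual(back, s$test[1:10, ], n_samples = 16L)
  expect_identical(est1, est2)
  expect_error(load_dlvm(p, toy_schema()), "fingerprint")
  expect_error(dlvm_elbo(fit, toy_cohort()), "schema")
})
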