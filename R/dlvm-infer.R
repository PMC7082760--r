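# Posterior evaluation and counterfactual inference for a fitted model.

# forward pass of the outcome head at a forced intervention arm, on the
# standardized scale for the gaussian head and the GS scale for ordinal
outcome_mean <- function(model, Z, t_arm) {
  fy <- mlp_forward(model$nets$dec_y, cbind(Z, t_arm))
  if (model$config$outcome_model == "gaussian")
    fy$out[, 1L]
  else
    drop(softmax_rows(fy$out) %*% model$y_levels)
}

unstandardize_y <- function(model, v) {
  if (model$config$outcome_model == "gaussian")
    v * model$y_scale + model$y_center
  else v
}

#' Monte-Carlo evidence lower bound of a fitted model on a batch
#'
#' Estimates the per-patient lower bound — expected log-likelihood of
#' \code{(x1, x2, t, y)} under latents sampled from the approximate
#' posteriors, minus the closed-form KL divergences of \code{q(z1|x1)}
#' against its Bernoulli(0.5) prior and \code{q(z2|x2)} against the
#' standard Gaussian, minus the joint-layer divergence
#' \code{KL(q(Z|.) || p(Z|z1,z2))} — and returns the batch mean. Discrete
#' latents are sampled as hard Bernoulli draws at evaluation time.
#'
#' @param model a \code{trained_dlvm}.
#' @param cohort a non-empty \code{cohort_table} with the model's schema.
#' @param n_samples Monte-Carlo sample count (default from the config).
#' @param seed seed for the posterior draws.
#' @return Scalar ELBO estimate (batch mean) with attribute
#'   \code{"kl"} holding the mean closed-form KL components.
#' @export
dlvm_elbo <- function(model, cohort,
                      n_samples = model$config$n_posterior_samples,
                      seed = model$config$seed) {
  stopifnot(inherits(model, "trained_dlvm"), is_cohort_table(cohort))
  check_model_schema(model, cohort)
  if (nrow(cohort) == 0L) stopf("empty batch")
  cfg <- model$config; nets <- model$nets
  enc <- dlvm_encode(cohort, model$schema, model)
  B <- nrow(enc$x1); k1 <- cfg$dim_z1; k2 <- cfg$dim_z2; kZ <- cfg$dim_Z

  f1 <- mlp_forward(nets$enc_z1, enc$x1); p1 <- logistic(f1$out)
  h2 <- split_gauss_head(mlp_forward(nets$enc_z2, enc$x2)$out, k2)
  hq <- split_gauss_head(
    mlp_forward(nets$enc_Z, cbind(enc$x1, enc$x2, enc$tv, enc$ys))$out, kZ)

  p1c <- clip01(p1)
  kl_z1 <- rowSums(p1c * log(p1c) + (1 - p1c) * log(1 - p1c) + log(2))
  kl_z2 <- rowSums(0.5 * (h2$mu^2 + exp(h2$lv) - 1 - h2$lv))

  lvx2 <- clamp_lv(nets$loose$lv_x2)
  lvx2m <- matrix(lvx2, B, length(lvx2), byrow = TRUE)

  set.seed(child_seed(seed, 11L))
  acc <- numeric(B)
  for (s in seq_len(n_samples)) {
    z1 <- matrix(as.numeric(stats::runif(B * k1) < p1), B, k1)
    z2 <- h2$mu + exp(h2$lv / 2) * matrix(stats::rnorm(B * k2), B, k2)
    Z <- hq$mu + exp(hq$lv / 2) * matrix(stats::rnorm(B * kZ), B, kZ)

    lx1 <- mlp_forward(nets$dec_x1, z1)$out
    ll_x1 <- rowSums(enc$x1 * log_sigmoid(lx1) +
                       (1 - enc$x1) * log_sigmoid(-lx1))
    mux2 <- mlp_forward(nets$dec_x2, z2)$out
    ll_x2 <- rowSums(-0.5 * log(2 * pi) - 0.5 * lvx2m -
                       0.5 * (enc$x2 - mux2)^2 * exp(-lvx2m))
    hp <- split_gauss_head(mlp_forward(nets$prior_Z, cbind(z1, z2))$out, kZ)
    dmu <- hq$mu - hp$mu
    kl_Z <- rowSums(0.5 * (hp$lv - hq$lv +
                             (exp(hq$lv) + dmu^2) * exp(-hp$lv) - 1))
    lt <- mlp_forward(nets$dec_t, Z)$out[, 1L]
    ll_t <- enc$tv * log_sigmoid(lt) + (1 - enc$tv) * log_sigmoid(-lt)
    fyout <- mlp_forward(nets$dec_y, cbind(Z, enc$tv))$out
    if (cfg$outcome_model == "gaussian") {
      lv_y <- clamp_lv(nets$loose$lv_y)
      ll_y <- -0.5 * log(2 * pi) - 0.5 * lv_y -
        0.5 * (enc$ys - fyout[, 1L])^2 * exp(-lv_y)
    } else {
      ll_y <- log(clip01(softmax_rows(fyout)[cbind(seq_len(B), enc$ycls)]))
    }
    acc <- acc + ll_x1 + ll_x2 + ll_t + ll_y - kl_Z
  }
  rows <- acc / n_samples - kl_z1 - kl_z2
  structure(mean(rows),
            kl = c(z1 = mean(kl_z1), z2 = mean(kl_z2)),
            per_patient = rows)
}

check_model_schema <- function(model, cohort) {
  sc <- cohort_schema(cohort)
  if (!identical(schema_fingerprint(sc), model$schema_fingerprint))
    stopf("cohort schema does not match the schema the model was fitted on")
  invisible(TRUE)
}

#' Estimate factual and counterfactual outcomes per patient
#'
#' For each patient, draws from the approximate posterior over the joint
#' confounder Z given the proxies (and the factual intervention and
#' outcome under the default train-style conditioning), evaluates the
#' outcome head at both intervention arms, and returns posterior-mean
#' estimates of y(0) and y(1) together with the individual causal effect
#' (ICE): \code{y - y_hat_0} for treated patients and \code{y_hat_1 - y}
#' for untreated ones. One shared stream of posterior draws is used for
#' all patients (common random numbers), which makes the estimates exactly
#' equivariant under row permutations.
#'
#' @param model a \code{trained_dlvm}.
#' @param cohort a \code{cohort_table} matching the model's schema.
#' @param n_samples posterior draws per patient.
#' @param conditioning \code{"train-style"} (condition on factual t and y)
#'   or \code{"proxies-only"} (y replaced by the auxiliary predictor).
#' @param seed seed for the posterior draws.
#' @return A data frame of class \code{counterfactual_estimates} with
#'   columns \code{y_hat_0}, \code{y_hat_1}, \code{t_factual},
#'   \code{y_factual}, \code{ice}.
#' @export
infer_counterfactual <- function(model, cohort,
                                 n_samples = model$config$n_posterior_samples,
                                 conditioning = model$config$counterfactual_conditioning,
                                 seed = model$config$seed) {
  stopifnot(inherits(model, "trained_dlvm"), is_cohort_table(cohort))
  check_model_schema(model, cohort)
  if (nrow(cohort) == 0L) stopf("empty cohort")
  if (!is_count(n_samples)) stopf("n_samples must be a positive integer")
  cfg <- model$config; nets <- model$nets
  enc <- dlvm_encode(cohort, model$schema, model)
  B <- nrow(enc$x1); kZ <- cfg$dim_Z

  yin <- if (identical(conditioning, "train-style")) {
    enc$ys
  } else {
    fay <- mlp_forward(nets$aux_y, cbind(enc$x1, enc$x2, enc$tv))
    if (cfg$outcome_model == "gaussian") fay$out[, 1L]
    else (drop(softmax_rows(fay$out) %*% model$y_levels) - model$y_center) /
      model$y_scale
  }
  hq <- split_gauss_head(
    mlp_forward(nets$enc_Z, cbind(enc$x1, enc$x2, enc$tv, yin))$out, kZ)
  sdq <- exp(hq$lv / 2)

  set.seed(child_seed(seed, 3L))
  eps <- matrix(stats::rnorm(n_samples * kZ), n_samples, kZ)
  y0 <- numeric(B); y1 <- numeric(B)
  zero <- rep(0, B); one <- rep(1, B)
  for (s in seq_len(n_samples)) {
    Z <- hq$mu + sdq * matrix(eps[s, ], B, kZ, byrow = TRUE)
    y0 <- y0 + outcome_mean(model, Z, zero)
    y1 <- y1 + outcome_mean(model, Z, one)
  }
  y0 <- unstandardize_y(model, y0 / n_samples)
  y1 <- unstandardize_y(model, y1 / n_samples)

  out <- data.frame(y_hat_0 = y0, y_hat_1 = y1,
                    t_factual = as.integer(enc$tv),
                    y_factual = as.integer(enc$y))
  out$ice <- ice(out$y_factual,
                 ifelse(out$t_factual == 1L, out$y_hat_0, out$y_hat_1),
                 out$t_factual)
  class(out) <- c("counterfactual_estimates", "data.frame")
  out
}

#' Reconstruct the factual-arm outcome per patient
#'
#' Identical machinery to \code{\link{infer_counterfactual}}, read off at
#' the factual intervention arm; with the same seed the two functions
#' agree exactly on the shared arm.
#'
#' @inheritParams infer_counterfactual
#' @return Numeric vector of \code{y_hat(t_factual)} per patient.
#' @export
reconstruct_factual <- function(model, cohort,
                                n_samples = model$config$n_posterior_samples,
                                conditioning = model$config$counterfactual_conditioning,
                                seed = model$config$seed) {
  est <- infer_counterfactual(model, cohort, n_samples, conditioning, seed)
  ifelse(est$t_factual == 1L, est$y_hat_1, est$y_hat_0)
}
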