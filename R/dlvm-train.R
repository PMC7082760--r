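# Training machinery for the joint latent-confounder model.
#
# Generative factorization:
#   p(z1) p(z2) p(x1|z1) p(x2|z2) p(Z|z1,z2) p(t|Z) p(y|t,Z)
# with Bernoulli(0.5) prior on z1 and standard Gaussian prior on z2.
# Approximate posteriors: q(z1|x1) Bernoulli, q(z2|x2) Gaussian,
# q(Z|x1,x2,t,y) Gaussian. Auxiliary predictors q(t|x) and q(y|t,x) are
# trained jointly so that inference can proceed when y is withheld.
#
# The per-batch objective (minimized) is the negative evidence lower bound
#   -E_q[ log p(x1|z1) + log p(x2|z2) + log p(t|Z) + log p(y|t,Z) ]
#   + KL(q(z1|x1) || Bern(0.5)) + KL(q(z2|x2) || N(0,I))
#   + E_q(z1,z2)[ KL(q(Z|.) || p(Z|z1,z2)) ]
# plus the auxiliary-prediction losses. Gradients flow through the latents
# via the Gaussian reparameterization (z2, Z) and a relaxed-Bernoulli
# (concrete) sample for z1; all gradients are derived by hand and verified
# against finite differences in the tests.

LV_CLAMP <- 10  # log-variance clamp, guards exp() overflow early in training

clamp_lv <- function(lv) pmax(pmin(lv, LV_CLAMP), -LV_CLAMP)

split_gauss_head <- function(out, k) {
  mu <- out[, seq_len(k), drop = FALSE]
  lv_raw <- out[, k + seq_len(k), drop = FALSE]
  list(mu = mu, lv = clamp_lv(lv_raw), mask = abs(lv_raw) < LV_CLAMP)
}

# One evaluation of the objective on a batch, optionally with gradients.
# batch: list(x1, x2, tv, ys, ycls); sample=TRUE draws latents (training),
# sample=FALSE uses posterior means (deterministic surrogate used for
# model selection).
dlvm_step <- function(nets, cfg, batch, grad = TRUE, sample = TRUE) {
  x1 <- batch$x1; x2 <- batch$x2; tv <- batch$tv; ys <- batch$ys
  B <- nrow(x1); k1 <- cfg$dim_z1; k2 <- cfg$dim_z2; kZ <- cfg$dim_Z
  gaussian_y <- cfg$outcome_model == "gaussian"
  tau_c <- cfg$concrete_temperature
  scale <- 1 / B

  # --- encoders ---
  f1 <- mlp_forward(nets$enc_z1, x1)
  logits1 <- f1$out; p1 <- logistic(logits1)
  if (sample) {
    u <- matrix(stats::runif(B * k1), B, k1)
    s_pre <- (logits1 + log(u) - log1p(-u)) / tau_c
    z1 <- logistic(s_pre)
  } else z1 <- p1

  f2 <- mlp_forward(nets$enc_z2, x2)
  h2 <- split_gauss_head(f2$out, k2)
  eps2 <- if (sample) matrix(stats::rnorm(B * k2), B, k2) else 0
  z2 <- h2$mu + exp(h2$lv / 2) * eps2

  cZ <- cbind(x1, x2, tv, ys)
  fZ <- mlp_forward(nets$enc_Z, cZ)
  hq <- split_gauss_head(fZ$out, kZ)
  epsZ <- if (sample) matrix(stats::rnorm(B * kZ), B, kZ) else 0
  Z <- hq$mu + exp(hq$lv / 2) * epsZ

  # --- decoders / likelihoods ---
  fx1 <- mlp_forward(nets$dec_x1, z1); lx1 <- fx1$out
  ll_x1 <- rowSums(x1 * log_sigmoid(lx1) + (1 - x1) * log_sigmoid(-lx1))

  fx2 <- mlp_forward(nets$dec_x2, z2); mux2 <- fx2$out
  lvx2 <- clamp_lv(nets$loose$lv_x2)
  lvx2m <- matrix(lvx2, B, length(lvx2), byrow = TRUE)
  ll_x2 <- rowSums(-0.5 * log(2 * pi) - 0.5 * lvx2m -
                     0.5 * (x2 - mux2)^2 * exp(-lvx2m))

  fp <- mlp_forward(nets$prior_Z, cbind(z1, z2))
  hp <- split_gauss_head(fp$out, kZ)
  dmu <- hq$mu - hp$mu
  kl_Z <- rowSums(0.5 * (hp$lv - hq$lv +
                           (exp(hq$lv) + dmu^2) * exp(-hp$lv) - 1))

  ft <- mlp_forward(nets$dec_t, Z); lt <- ft$out[, 1L]
  ll_t <- tv * log_sigmoid(lt) + (1 - tv) * log_sigmoid(-lt)

  fy <- mlp_forward(nets$dec_y, cbind(Z, tv))
  if (gaussian_y) {
    muy <- fy$out[, 1L]
    lv_y <- clamp_lv(nets$loose$lv_y)
    ll_y <- -0.5 * log(2 * pi) - 0.5 * lv_y - 0.5 * (ys - muy)^2 * exp(-lv_y)
  } else {
    py <- softmax_rows(fy$out)
    ll_y <- log(clip01(py[cbind(seq_len(B), batch$ycls)]))
  }

  # --- KL of the split latents against their priors ---
  p1c <- clip01(p1)
  kl_z1 <- rowSums(p1c * log(p1c) + (1 - p1c) * log(1 - p1c) + log(2))
  kl_z2 <- rowSums(0.5 * (h2$mu^2 + exp(h2$lv) - 1 - h2$lv))

  # --- auxiliary predictors ---
  fa_t <- mlp_forward(nets$aux_t, cbind(x1, x2)); la <- fa_t$out[, 1L]
  ll_at <- tv * log_sigmoid(la) + (1 - tv) * log_sigmoid(-la)
  fa_y <- mlp_forward(nets$aux_y, cbind(x1, x2, tv))
  if (gaussian_y) {
    ma <- fa_y$out[, 1L]
    ll_ay <- -0.5 * (ys - ma)^2
  } else {
    pa <- softmax_rows(fa_y$out)
    ll_ay <- log(clip01(pa[cbind(seq_len(B), batch$ycls)]))
  }

  elbo_rows <- ll_x1 + ll_x2 + ll_t + ll_y - kl_z1 - kl_z2 - kl_Z
  loss <- mean(-elbo_rows) + mean(-ll_at) + mean(-ll_ay)
  if (!grad)
    return(list(loss = loss, elbo = mean(elbo_rows),
                kl = c(z1 = mean(kl_z1), z2 = mean(kl_z2), Z = mean(kl_Z))))

  # --- backward pass ---
  # outcome head
  if (gaussian_y) {
    dmuy <- scale * (muy - ys) * exp(-lv_y)
    d_lv_y <- scale * sum(0.5 - 0.5 * (ys - muy)^2 * exp(-lv_y)) *
      (abs(nets$loose$lv_y) < LV_CLAMP)
    dy_out <- matrix(dmuy, B, 1L)
  } else {
    onehot <- matrix(0, B, ncol(fy$out))
    onehot[cbind(seq_len(B), batch$ycls)] <- 1
    dy_out <- scale * (py - onehot)
    d_lv_y <- NULL
  }
  by <- mlp_backward(nets$dec_y, fy, dy_out)
  dZ <- by$dX[, seq_len(kZ), drop = FALSE]

  # treatment head
  bt <- mlp_backward(nets$dec_t, ft,
                     matrix(scale * (logistic(lt) - tv), B, 1L))
  dZ <- dZ + bt$dX

  # joint-layer KL: gradients to q(Z) and p(Z|z1,z2) heads
  e_lvq_lvp <- exp(hq$lv - hp$lv)
  dmuq_kl <- scale * dmu * exp(-hp$lv)
  dlvq_kl <- scale * 0.5 * (e_lvq_lvp - 1)
  dmup <- -dmuq_kl
  dlvp <- scale * 0.5 * (1 - (exp(hq$lv) + dmu^2) * exp(-hp$lv))

  dmuq <- dZ + dmuq_kl
  dlvq <- dZ * (Z - hq$mu) * 0.5 + dlvq_kl
  bZ <- mlp_backward(nets$enc_Z, fZ, cbind(dmuq, dlvq * hq$mask))

  bp <- mlp_backward(nets$prior_Z, fp, cbind(dmup, dlvp * hp$mask))
  dz1_p <- bp$dX[, seq_len(k1), drop = FALSE]
  dz2_p <- bp$dX[, k1 + seq_len(k2), drop = FALSE]

  # continuous reconstruction
  dmux2 <- scale * (mux2 - x2) * exp(-lvx2m)
  d_lv_x2 <- scale * unname(colSums(0.5 - 0.5 * (x2 - mux2)^2 * exp(-lvx2m))) *
    (abs(nets$loose$lv_x2) < LV_CLAMP)
  bx2 <- mlp_backward(nets$dec_x2, fx2, dmux2)

  # discrete reconstruction
  bx1 <- mlp_backward(nets$dec_x1, fx1, scale * (logistic(lx1) - x1))

  # back into the split encoders through the samples + their KL terms
  dz2 <- bx2$dX + dz2_p
  dmu2 <- dz2 + scale * h2$mu
  dlv2 <- dz2 * (z2 - h2$mu) * 0.5 + scale * 0.5 * (exp(h2$lv) - 1)
  b2 <- mlp_backward(nets$enc_z2, f2, cbind(dmu2, dlv2 * h2$mask))

  dz1 <- bx1$dX + dz1_p
  dlogits1 <- if (sample) dz1 * z1 * (1 - z1) / tau_c else dz1 * p1 * (1 - p1)
  dlogits1 <- dlogits1 + scale * logits1 * p1 * (1 - p1)
  b1 <- mlp_backward(nets$enc_z1, f1, dlogits1)

  # auxiliary nets
  ba_t <- mlp_backward(nets$aux_t, fa_t,
                       matrix(scale * (logistic(la) - tv), B, 1L))
  if (gaussian_y) {
    ba_y <- mlp_backward(nets$aux_y, fa_y, matrix(scale * (ma - ys), B, 1L))
  } else {
    ba_y <- mlp_backward(nets$aux_y, fa_y, scale * (pa - onehot))
  }

  grads <- list(enc_z1 = b1$grads, enc_z2 = b2$grads, enc_Z = bZ$grads,
                dec_x1 = bx1$grads, dec_x2 = bx2$grads, prior_Z = bp$grads,
                dec_t = bt$grads, dec_y = by$grads, aux_t = ba_t$grads,
                aux_y = ba_y$grads,
                loose = c(list(lv_x2 = d_lv_x2),
                          if (gaussian_y) list(lv_y = d_lv_y)))
  list(loss = loss, grads = grads)
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# Build the numeric training representation of a cohort under a model's
# (or fresh) encoding statistics.
dlvm_encode <- function(cohort, schema, model = NULL) {
  enc <- encode_proxies(cohort, schema,
                        levels_map = model$encoding$levels_map,
                        cont_center = model$encoding$cont_center,
                        cont_scale = model$encoding$cont_scale,
                        cont_impute = model$encoding$cont_impute)
  y <- cohort[[schema$outcome_column]]
  if (is.null(model)) {
    y_center <- mean(y); y_scale <- stats::sd(y)
    if (!is.finite(y_scale) || y_scale < 1e-8) y_scale <- 1
    y_levels <- sort(unique(y))
  } else {
    y_center <- model$y_center; y_scale <- model$y_scale
    y_levels <- model$y_levels
  }
  ycls <- vapply(y, function(v) which.min(abs(y_levels - v)), 1L)
  list(x1 = enc$x1, x2 = enc$x2,
       tv = as.numeric(cohort[[schema$treatment_column]]),
       y = as.numeric(y), ys = (y - y_center) / y_scale, ycls = ycls,
       y_center = y_center, y_scale = y_scale, y_levels = y_levels,
       encoding = enc)
}

#' Fit the deep latent variable model to a cohort
#'
#' Trains the twin variational autoencoders and joint confounder layer by
#' stochastic gradient ascent (ADAM) on the evidence lower bound plus
#' auxiliary prediction losses. The checkpoint with the best validation
#' objective within the epoch budget is returned ("up to" semantics of the
#' epoch limit). Fully deterministic given \code{config$seed}.
#'
#' @param train a \code{\link{cohort_table}}; the intervention-expression
#'   exclusion rule (\code{\link{exclude_intervention_expression}}) is
#'   expected to have been applied to its schema already.
#' @param valid optional validation \code{cohort_table} with an identical
#'   schema; used for model selection. When \code{NULL}, the training
#'   objective is used.
#' @param config a \code{\link{dlvm_config}}.
#' @return An object of class \code{trained_dlvm} carrying fitted
#'   parameters, encoding statistics, and a per-epoch training log
#'   (data frame with \code{epoch}, \code{train_objective},
#'   \code{valid_objective}; objectives are negated losses, higher is
#'   better).
#' @export
fit_dlvm <- function(train, valid = NULL, config = dlvm_config_desk()) {
  stopifnot(is_cohort_table(train), inherits(config, "dlvm_config"))
  schema <- cohort_schema(train)
  if (nrow(train) == 0L) stopf("training cohort is empty")
  if (!is.null(valid)) {
    stopifnot(is_cohort_table(valid))
    if (!identical(unclass(cohort_schema(valid)), unclass(schema)))
      stopf("train and valid schemas differ")
  }
  tv_all <- train[[schema$treatment_column]]
  if (length(unique(tv_all)) == 1L)
    warnf("all training patients have t = %d; the counterfactual arm is not identifiable from data alone",
          tv_all[1L])
  if (length(schema$discrete_columns) == 0L)
    stopf("at least one discrete proxy column is required")
  if (length(schema$continuous_columns) == 0L)
    stopf("at least one continuous proxy column is required")

  set.seed(child_seed(config$seed, 1L))
  enc <- dlvm_encode(train, schema)
  if (enc$encoding$n_imputed > 0L)
    message(sprintf("imputed %d missing continuous value(s) by training-split column means",
                    enc$encoding$n_imputed))
  n <- nrow(train); d1 <- ncol(enc$x1); d2 <- ncol(enc$x2)
  nets <- dlvm_init_nets(config, d1, d2, n_y_levels = length(enc$y_levels))

  venc <- NULL
  if (!is.null(valid)) {
    stub <- list(encoding = enc$encoding, y_center = enc$y_center,
                 y_scale = enc$y_scale, y_levels = enc$y_levels)
    venc <- dlvm_encode(valid, schema, model = stub)
  }
  eval_batch <- function(e) list(x1 = e$x1, x2 = e$x2, tv = e$tv,
                                 ys = e$ys, ycls = e$ycls)

  params <- dlvm_get_params(nets)
  state <- adam_new(params)
  bs <- min(config$batch_size, n)
  log_rows <- vector("list", config$epochs)
  best <- list(obj = -Inf, params = params, epoch = 0L)

  set.seed(child_seed(config$seed, 2L))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    ep_loss <- 0
    for (st in starts) {
      idx <- ord[st:min(st + bs - 1L, n)]
      batch <- list(x1 = enc$x1[idx, , drop = FALSE],
                    x2 = enc$x2[idx, , drop = FALSE],
                    tv = enc$tv[idx], ys = enc$ys[idx], ycls = enc$ycls[idx])
      stepres <- dlvm_step(nets, config, batch, grad = TRUE, sample = TRUE)
      upd <- adam_step(params, stepres$grads, state,
                       lr = config$learning_rate,
                       weight_decay = config$decay_rate)
      params <- upd$params; state <- upd$state
      nets <- dlvm_set_params(nets, params)
      ep_loss <- ep_loss + stepres$loss * length(idx)
    }
    train_obj <- -ep_loss / n
    valid_obj <- if (is.null(venc)) {
      -dlvm_step(nets, config, eval_batch(enc), grad = FALSE,
                 sample = FALSE)$loss
    } else {
      -dlvm_step(nets, config, eval_batch(venc), grad = FALSE,
                 sample = FALSE)$loss
    }
    if (is.finite(valid_obj) && valid_obj > best$obj)
      best <- list(obj = valid_obj, params = params, epoch = ep)
    log_rows[[ep]] <- data.frame(epoch = ep, train_objective = train_obj,
                                 valid_objective = valid_obj)
  }
  nets <- dlvm_set_params(nets, best$params)

  model <- structure(list(
    config = config, nets = nets, schema = schema,
    schema_fingerprint = schema_fingerprint(schema),
    encoding = enc$encoding[c("levels_map", "cont_center", "cont_scale",
                              "cont_impute")],
    y_center = enc$y_center, y_scale = enc$y_scale, y_levels = enc$y_levels,
    d1 = d1, d2 = d2, n_train = n,
    best_epoch = best$epoch,
    training_log = do.call(rbind, log_rows)), class = "trained_dlvm")
  model
}

#' @export
print.trained_dlvm <- function(x, ...) {
  cat(sprintf("<trained_dlvm> %d patients, %d+%d encoded proxies, best epoch %d/%d (objective %.3f)\n",
              x$n_train, x$d1, x$d2, x$best_epoch, x$config$epochs,
              max(x$training_log$valid_objective)))
  invisible(x)
}
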