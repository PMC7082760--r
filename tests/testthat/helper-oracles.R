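# Independent oracles used by both the unit tests and the acceptance
# checks. They are literal re-codings of the definitions (loops, explicit
# branches) or quadrature/enumeration computations, deliberately sharing
# no code with the implementation paths they verify.

oracle_ice <- function(y, yhat_other, t) {
  out <- numeric(length(y))
  for (i in seq_along(y)) {
    out[i] <- if (t[i] == 1) y[i] - yhat_other[i] else yhat_other[i] - y[i]
  }
  out
}

oracle_aice <- function(est, root = TRUE) {
  s <- 0
  for (i in seq_len(nrow(est))) {
    s <- s + if (est$t_factual[i] == 0)
      (est$y_hat_1[i] - est$y_factual[i])^2
    else
      (est$y_factual[i] - est$y_hat_0[i])^2
  }
  if (root) sqrt(s / nrow(est)) else s / nrow(est)
}

oracle_rmse <- function(est) {
  s <- 0
  for (i in seq_len(nrow(est))) {
    s <- s + if (est$t_factual[i] == 0)
      (est$y_hat_0[i] - est$y_factual[i])^2
    else
      (est$y_hat_1[i] - est$y_factual[i])^2
  }
  sqrt(s / nrow(est))
}

random_estimates <- function(n) {
  est <- data.frame(y_hat_0 = runif(n, 5, 10), y_hat_1 = runif(n, 5, 10),
                    t_factual = rbinom(n, 1, 0.5),
                    y_factual = sample(6:10, n, replace = TRUE))
  est$ice <- ice(est$y_factual,
                 ifelse(est$t_factual == 1, est$y_hat_0, est$y_hat_1),
                 est$t_factual)
  est
}

# Exact per-patient lower bound for a model with 2-dim latents: exact
# enumeration over the 4 binary z1 states, tensor Gauss-Hermite quadrature
# (24 nodes/dim) over the 2-dim Gaussian posteriors of z2 and Z.
elbo_enum_oracle <- function(model, cohort, i) {
  nets <- model$nets
  enc <- dlvmcf:::dlvm_encode(cohort, cohort_schema(cohort), model)
  gh <- pracma::gaussHermite(24L)
  x1 <- enc$x1[i, , drop = FALSE]; x2 <- enc$x2[i, , drop = FALSE]
  tv <- enc$tv[i]; ys <- enc$ys[i]
  p1 <- dlvmcf:::logistic(dlvmcf:::mlp_forward(nets$enc_z1, x1)$out)
  h2 <- dlvmcf:::split_gauss_head(
    dlvmcf:::mlp_forward(nets$enc_z2, x2)$out, 2L)
  hq <- dlvmcf:::split_gauss_head(
    dlvmcf:::mlp_forward(nets$enc_Z, cbind(x1, x2, tv, ys))$out, 2L)

  p1c <- dlvmcf:::clip01(p1)
  kl1 <- sum(p1c * log(p1c) + (1 - p1c) * log(1 - p1c) + log(2))
  kl2 <- sum(0.5 * (h2$mu^2 + exp(h2$lv) - 1 - h2$lv))

  z1_atoms <- as.matrix(expand.grid(0:1, 0:1))
  pr_atom <- apply(z1_atoms, 1L, function(z)
    prod(ifelse(z == 1, p1, 1 - p1)))
  lx1 <- dlvmcf:::mlp_forward(nets$dec_x1, z1_atoms)$out
  x1v <- as.numeric(x1[1, ])
  ll1_atom <- as.numeric(dlvmcf:::log_sigmoid(lx1) %*% x1v +
                           dlvmcf:::log_sigmoid(-lx1) %*% (1 - x1v))
  E_ll_x1 <- sum(pr_atom * ll1_atom)

  grid2 <- as.matrix(expand.grid(gh$x, gh$x))
  w2 <- apply(as.matrix(expand.grid(gh$w, gh$w)), 1L, prod) / pi
  G <- nrow(grid2)
  z2g <- sweep(sweep(grid2, 2L, sqrt(2) * exp(h2$lv[1, ] / 2), "*"),
               2L, h2$mu[1, ], "+")
  mux2 <- dlvmcf:::mlp_forward(nets$dec_x2, z2g)$out
  lvx2 <- dlvmcf:::clamp_lv(nets$loose$lv_x2)
  lvm <- matrix(lvx2, G, length(lvx2), byrow = TRUE)
  x2m <- matrix(as.numeric(x2[1, ]), G, ncol(x2), byrow = TRUE)
  ll2_g <- rowSums(-0.5 * log(2 * pi) - 0.5 * lvm -
                     0.5 * (x2m - mux2)^2 * exp(-lvm))
  E_ll_x2 <- sum(w2 * ll2_g)

  qmu <- matrix(hq$mu[1, ], G, 2L, byrow = TRUE)
  qlv <- matrix(hq$lv[1, ], G, 2L, byrow = TRUE)
  E_kl_Z <- 0
  for (a in seq_len(nrow(z1_atoms))) {
    inp <- cbind(matrix(z1_atoms[a, ], G, 2L, byrow = TRUE), z2g)
    hp <- dlvmcf:::split_gauss_head(
      dlvmcf:::mlp_forward(nets$prior_Z, inp)$out, 2L)
    klg <- rowSums(0.5 * (hp$lv - qlv +
                            (exp(qlv) + (qmu - hp$mu)^2) * exp(-hp$lv) - 1))
    E_kl_Z <- E_kl_Z + pr_atom[a] * sum(w2 * klg)
  }

  Zg <- sweep(sweep(grid2, 2L, sqrt(2) * exp(hq$lv[1, ] / 2), "*"),
              2L, hq$mu[1, ], "+")
  lt <- dlvmcf:::mlp_forward(nets$dec_t, Zg)$out[, 1L]
  ll_t <- tv * dlvmcf:::log_sigmoid(lt) +
    (1 - tv) * dlvmcf:::log_sigmoid(-lt)
  muy <- dlvmcf:::mlp_forward(nets$dec_y, cbind(Zg, tv))$out[, 1L]
  lv_y <- dlvmcf:::clamp_lv(nets$loose$lv_y)
  ll_y <- -0.5 * log(2 * pi) - 0.5 * lv_y - 0.5 * (ys - muy)^2 * exp(-lv_y)
  E_llty <- sum(w2 * (ll_t + ll_y))

  E_ll_x1 + E_ll_x2 + E_llty - kl1 - kl2 - E_kl_Z
}
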