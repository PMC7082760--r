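# Minimal matrix-based neural network engine.
#
# The latent-variable model and the race imputer are trained with manual
# reverse-mode gradients through small multilayer perceptrons; everything is
# vectorized over the batch so a training step is a handful of BLAS calls.
# Gradients are verified against central finite differences in the test
# suite. Uses R's own RNG throughout, so seeding is the caller's concern.

# -- activations -------------------------------------------------------------

act_apply <- function(a, act, alpha = 0.25) {
  switch(act,
         sigmoid = logistic(a),
         tanh = tanh(a),
         relu = pmax(a, 0),
         prelu = ifelse(a > 0, a, alpha * a),
         identity = a,
         stopf("unknown activation '%s'", act))
}

# derivative wrt pre-activation, given pre-activation a and output h
act_deriv <- function(a, h, act, alpha = 0.25) {
  switch(act,
         sigmoid = h * (1 - h),
         tanh = 1 - h^2,
         relu = (a > 0) + 0,
         prelu = ifelse(a > 0, 1, alpha),
         identity = array(1, dim(a)),
         stopf("unknown activation '%s'", act))
}

# -- multilayer perceptron ---------------------------------------------------

# sizes = c(d_in, h1, ..., d_out); hidden layers use `act`, output is linear
# (likelihood heads apply their own link). PReLU slope is a learnable scalar
# per hidden layer, initialized at 0.25.
mlp_new <- function(sizes, act = "sigmoid") {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  net <- list(W = W, b = b, act = act, sizes = sizes)
  if (act == "prelu") net$alpha <- rep(0.25, L - 1L)
  net
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  H <- vector("list", L + 1L); A <- vector("list", L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    A[[l]] <- H[[l]] %*% net$W[[l]] +
      matrix(net$b[[l]], nrow(X), length(net$b[[l]]), byrow = TRUE)
    H[[l + 1L]] <- if (l < L)
      act_apply(A[[l]], net$act, if (net$act == "prelu") net$alpha[l] else 0.25)
    else A[[l]]
  }
  list(out = H[[L + 1L]], H = H, A = A)
}

# dOut: gradient of the scalar objective wrt the network output.
# Returns input gradient and parameter gradients (same shapes as net$W etc).
mlp_backward <- function(net, fw, dOut) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  dalpha <- if (!is.null(net$alpha)) numeric(length(net$alpha)) else NULL
  dA <- dOut
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fw$H[[l]], dA)
    db[[l]] <- colSums(dA)
    dH <- dA %*% t(net$W[[l]])
    if (l > 1L) {
      al <- if (net$act == "prelu") net$alpha[l - 1L] else 0.25
      dA <- dH * act_deriv(fw$A[[l - 1L]], fw$H[[l]], net$act, al)
      # note fw$H[[l]] is the *output* of layer l-1's activation
      if (net$act == "prelu")
        dalpha[l - 1L] <- sum(dH * pmin(fw$A[[l - 1L]], 0))
    } else {
      dA <- dH
    }
  }
  g <- list(W = dW, b = db)
  if (!is.null(dalpha)) g$alpha <- dalpha
  list(dX = dA, grads = g)
}

# -- parameter trees and ADAM ------------------------------------------------

# Parameters are nested lists whose leaves are numeric arrays; grads mirror
# the structure. ADAM with optional decoupled weight decay on W matrices.

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    out
  } else f(a, b)
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_new <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  if (weight_decay > 0)
    params <- rapply(params, function(p) p * (1 - lr * weight_decay),
                     how = "replace")
  list(params = params, state = state)
}

# extract / restore the trainable leaves of a model component list
net_params <- function(net) {
  keep <- intersect(names(net), c("W", "b", "alpha"))
  net[keep]
}

net_set_params <- function(net, params) {
  for (nm in names(params)) net[[nm]] <- params[[nm]]
  net
}
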