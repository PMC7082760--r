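#' Hyperparameter configuration for the deep latent variable model
#'
#' Defaults follow the reference architecture used for cohort-scale
#' analysis: latent dimensions 50 (joint confounder Z), 160 (discrete z1),
#' 160 (continuous z2); three sigmoid hidden layers of 300, 300 and 100
#' neurons; ADAM with learning rate 1e-5, weight-decay 1e-5, batch size 10,
#' up to 300 epochs. \code{dlvm_config_desk()} is a scaled-down profile for
#' simulation studies and tests on a single CPU, with the same structure
#' but small layers and a correspondingly larger learning rate.
#'
#' @param dim_Z dimension of the joint latent confounder Z.
#' @param dim_z1 dimension of the Bernoulli latent confounder z1.
#' @param dim_z2 dimension of the Gaussian latent confounder z2.
#' @param hidden_sizes integer vector of hidden layer widths shared by all
#'   encoder/decoder networks.
#' @param hidden_activation hidden activation (\code{"sigmoid"},
#'   \code{"tanh"}, \code{"relu"}, \code{"prelu"}).
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate ADAM learning rate.
#' @param decay_rate weight-decay coefficient applied with ADAM.
#' @param n_posterior_samples Monte-Carlo samples for posterior averaging.
#' @param outcome_model \code{"gaussian"} (continuous head on the GS scale,
#'   the default) or \code{"ordinal"} (categorical head over the observed
#'   GS levels; predictions are posterior expectations, so still real).
#' @param concrete_temperature temperature of the relaxed-Bernoulli sampler
#'   used for z1 during training.
#' @param counterfactual_conditioning \code{"train-style"} (posterior over
#'   Z conditions on proxies plus factual t and y) or \code{"proxies-only"}
#'   (y is replaced by the auxiliary predictor's estimate).
#' @param seed master seed; every source of randomness in fitting and
#'   inference derives from it.
#' @return An object of class \code{dlvm_config}.
#' @export
dlvm_config <- function(dim_Z = 50L, dim_z1 = 160L, dim_z2 = 160L,
                        hidden_sizes = c(300L, 300L, 100L),
                        hidden_activation = "sigmoid",
                        epochs = 300L, batch_size = 10L,
                        learning_rate = 1e-5, decay_rate = 1e-5,
                        n_posterior_samples = 100L,
                        outcome_model = c("gaussian", "ordinal"),
                        concrete_temperature = 0.5,
                        counterfactual_conditioning = c("train-style",
                                                        "proxies-only"),
                        seed = 1L) {
  outcome_model <- match.arg(outcome_model)
  counterfactual_conditioning <- match.arg(counterfactual_conditioning)
  for (v in list(dim_Z, dim_z1, dim_z2, epochs, batch_size,
                 n_posterior_samples))
    if (!is_count(v)) stopf("all dimensions and counts must be positive integers")
  if (!all(vapply(hidden_sizes, is_count, TRUE)))
    stopf("hidden_sizes must be positive integers")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stopf("learning_rate must be > 0")
  if (!is.numeric(decay_rate) || decay_rate < 0)
    stopf("decay_rate must be >= 0")
  structure(list(dim_Z = as.integer(dim_Z), dim_z1 = as.integer(dim_z1),
                 dim_z2 = as.integer(dim_z2),
                 hidden_sizes = as.integer(hidden_sizes),
                 hidden_activation = hidden_activation,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, decay_rate = decay_rate,
                 optimizer = "adam",
                 n_posterior_samples = as.integer(n_posterior_samples),
                 outcome_model = outcome_model,
                 concrete_temperature = concrete_temperature,
                 counterfactual_conditioning = counterfactual_conditioning,
                 seed = as.integer(seed)),
            class = "dlvm_config")
}

#' @rdname dlvm_config
#' @param ... overrides passed on to \code{dlvm_config}.
#' @export
dlvm_config_desk <- function(...) {
  defaults <- list(dim_Z = 8L, dim_z1 = 12L, dim_z2 = 12L,
                   hidden_sizes = c(32L, 16L), hidden_activation = "tanh",
                   epochs = 60L, batch_size = 100L,
                   learning_rate = 5e-3, decay_rate = 1e-5,
                   n_posterior_samples = 100L)
  args <- utils::modifyList(defaults, list(...))
  do.call(dlvm_config, args)
}

#' @export
print.dlvm_config <- function(x, ...) {
  cat(sprintf(
    "<dlvm_config> Z=%d z1=%d z2=%d hidden=(%s, %s) epochs=%d batch=%d lr=%g wd=%g outcome=%s seed=%d\n",
    x$dim_Z, x$dim_z1, x$dim_z2, paste(x$hidden_sizes, collapse = ","),
    x$hidden_activation, x$epochs, x$batch_size, x$learning_rate,
    x$decay_rate, x$outcome_model, x$seed))
  invisible(x)
}

# initialize all network components for given input dimensions;
# assumes the calling code has already seeded the RNG
dlvm_init_nets <- function(cfg, d1, d2, n_y_levels = NULL) {
  h <- cfg$hidden_sizes
  act <- cfg$hidden_activation
  y_out <- if (cfg$outcome_model == "gaussian") 1L else n_y_levels
  nets <- list(
    enc_z1  = mlp_new(c(d1, h, cfg$dim_z1), act),
    enc_z2  = mlp_new(c(d2, h, 2L * cfg$dim_z2), act),
    enc_Z   = mlp_new(c(d1 + d2 + 2L, h, 2L * cfg$dim_Z), act),
    dec_x1  = mlp_new(c(cfg$dim_z1, h, d1), act),
    dec_x2  = mlp_new(c(cfg$dim_z2, h, d2), act),
    prior_Z = mlp_new(c(cfg$dim_z1 + cfg$dim_z2, h, 2L * cfg$dim_Z), act),
    dec_t   = mlp_new(c(cfg$dim_Z, h, 1L), act),
    dec_y   = mlp_new(c(cfg$dim_Z + 1L, h, y_out), act),
    aux_t   = mlp_new(c(d1 + d2, h, 1L), act),
    aux_y   = mlp_new(c(d1 + d2 + 1L, h, y_out), act)
  )
  nets$loose <- list(lv_x2 = numeric(d2),
                     lv_y = if (cfg$outcome_model == "gaussian") 0 else NULL)
  nets
}

dlvm_get_params <- function(nets) {
  out <- lapply(nets[setdiff(names(nets), "loose")], net_params)
  out$loose <- nets$loose[!vapply(nets$loose, is.null, TRUE)]
  out
}

dlvm_set_params <- function(nets, params) {
  for (nm in setdiff(names(nets), "loose"))
    nets[[nm]] <- net_set_params(nets[[nm]], params[[nm]])
  for (nm in names(params$loose)) nets$loose[[nm]] <- params$loose[[nm]]
  nets
}

# schema fingerprint used to refuse loading checkpoints against a
# different feature layout
schema_fingerprint <- function(schema) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  write_schema(schema, tf)
  unname(tools::md5sum(tf))
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single-file archive embedding the fitted parameters,
#' the configuration and a fingerprint of the feature schema;
#' \code{load_dlvm} refuses to load a checkpoint whose schema fingerprint
#' does not match the supplied schema.
#'
#' @param model a \code{trained_dlvm}.
#' @param path file path for the checkpoint.
#' @param schema the \code{feature_schema} the model is expected to match.
#' @return \code{load_dlvm} returns the \code{trained_dlvm}.
#' @export
save_dlvm <- function(model, path) {
  stopifnot(inherits(model, "trained_dlvm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_dlvm
#' @export
load_dlvm <- function(path, schema = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "trained_dlvm")) stopf("not a dlvm checkpoint: %s", path)
  if (!is.null(schema) &&
      !identical(model$schema_fingerprint, schema_fingerprint(schema)))
    stopf("checkpoint schema fingerprint does not match the supplied schema")
  model
}
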