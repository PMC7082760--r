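#' Configuration for the race/ethnicity imputation network
#'
#' A multilayer perceptron classifier mapping the encoded feature table to
#' race-label probabilities: two PReLU hidden layers (512 nodes each by
#' default, mirroring the 112-input reference architecture) and a softmax
#' output over the label classes. The input dimension is inferred from the
#' encoded feature matrix at fit time. \code{imputer_config_desk()} is a
#' small profile for simulation studies and tests.
#'
#' @param hidden_sizes integer pair of hidden-layer widths.
#' @param hidden_activation hidden activation (default \code{"prelu"}).
#' @param classes label vocabulary the classifier predicts over
#'   (lexicographic order fixes the output layout and the argmax
#'   tie-break).
#' @param epochs,batch_size,learning_rate,decay_rate optimizer settings
#'   (ADAM), following the same conventions as \code{\link{dlvm_config}}.
#' @param class_weights \code{"none"} (default) or \code{"inverse"}
#'   (inverse-frequency loss weights for imbalanced training labels).
#' @param seed master seed.
#' @return An object of class \code{imputer_config}.
#' @export
imputer_config <- function(hidden_sizes = c(512L, 512L),
                           hidden_activation = "prelu",
                           classes = c("AA", "Asian", "EA"),
                           epochs = 300L, batch_size = 10L,
                           learning_rate = 1e-5, decay_rate = 1e-5,
                           class_weights = c("none", "inverse"),
                           seed = 1L) {
  class_weights <- match.arg(class_weights)
  if (length(classes) < 2L) stopf("need at least 2 label classes")
  if (!all(vapply(hidden_sizes, is_count, TRUE)))
    stopf("hidden_sizes must be positive integers")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 hidden_activation = hidden_activation,
                 classes = sort(unique(classes)),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, decay_rate = decay_rate,
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "imputer_config")
}

#' @rdname imputer_config
#' @param ... overrides passed on to \code{imputer_config}.
#' @export
imputer_config_desk <- function(...) {
  defaults <- list(hidden_sizes = c(32L, 16L), epochs = 80L,
                   batch_size = 64L, learning_rate = 5e-3)
  do.call(imputer_config, utils::modifyList(defaults, list(...)))
}

# feature matrix the imputer consumes: encoded proxies plus the
# intervention and (standardized) outcome columns
imputer_features <- function(cohort, schema, stats = NULL) {
  enc <- encode_proxies(cohort, schema,
                        levels_map = stats$levels_map,
                        cont_center = stats$cont_center,
                        cont_scale = stats$cont_scale,
                        cont_impute = stats$cont_impute)
  y <- cohort[[schema$outcome_column]]
  y_center <- stats$y_center %||% mean(y)
  y_scale <- stats$y_scale %||% max(stats::sd(y), 1e-8)
  X <- cbind(enc$x1, enc$x2,
             t = as.numeric(cohort[[schema$treatment_column]]),
             y = (y - y_center) / y_scale)
  list(X = X,
       stats = list(levels_map = enc$levels_map,
                    cont_center = enc$cont_center,
                    cont_scale = enc$cont_scale,
                    cont_impute = enc$cont_impute,
                    y_center = y_center, y_scale = y_scale))
}

#' Fit the race/ethnicity imputer on labeled patients
#'
#' Trains the softmax MLP with categorical cross-entropy on all cohort
#' rows whose race label is in the configured class vocabulary.
#' Deterministic given \code{config$seed}.
#'
#' @param labeled a \code{\link{cohort_table}} whose rows carry known race
#'   labels (rows labeled \code{unknown} are rejected; split them off
#'   first).
#' @param config an \code{\link{imputer_config}}.
#' @return An object of class \code{race_imputer}.
#' @export
fit_race_imputer <- function(labeled, config = imputer_config_desk()) {
  stopifnot(is_cohort_table(labeled), inherits(config, "imputer_config"))
  schema <- cohort_schema(labeled)
  lab <- labeled[[schema$race_column]]
  if (any(!lab %in% config$classes))
    stopf("training rows carry labels outside the class vocabulary (%s): %s",
          paste(config$classes, collapse = ", "),
          paste(setdiff(unique(lab), config$classes), collapse = ", "))
  absent <- setdiff(config$classes, lab)
  if (length(absent))
    warnf("class(es) absent from training labels: %s; they can never be predicted with calibrated probability",
          paste(absent, collapse = ", "))

  set.seed(child_seed(config$seed, 21L))
  ft <- imputer_features(labeled, schema)
  X <- ft$X; n <- nrow(X); K <- length(config$classes)
  ycls <- match(lab, config$classes)
  w_class <- if (config$class_weights == "inverse") {
    tab <- tabulate(ycls, nbins = K)
    w <- ifelse(tab > 0, n / (K * tab), 0)
    w
  } else rep(1, K)

  net <- mlp_new(c(ncol(X), config$hidden_sizes, K),
                 config$hidden_activation)
  params <- net_params(net)
  state <- adam_new(params)
  bs <- min(config$batch_size, n)
  set.seed(child_seed(config$seed, 22L))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (st in seq(1L, n, by = bs)) {
      idx <- ord[st:min(st + bs - 1L, n)]
      fw <- mlp_forward(net, X[idx, , drop = FALSE])
      p <- softmax_rows(fw$out)
      onehot <- matrix(0, length(idx), K)
      onehot[cbind(seq_along(idx), ycls[idx])] <- 1
      wr <- w_class[ycls[idx]]
      dlogits <- (p - onehot) * wr / length(idx)
      bk <- mlp_backward(net, fw, dlogits)
      upd <- adam_step(params, bk$grads, state, lr = config$learning_rate,
                       weight_decay = config$decay_rate)
      params <- upd$params; state <- upd$state
      net <- net_set_params(net, params)
    }
  }
  structure(list(config = config, net = net, classes = config$classes,
                 feature_stats = ft$stats, input_dim = ncol(X),
                 schema_fingerprint = schema_fingerprint(schema)),
            class = "race_imputer")
}

#' Predict race labels and class probabilities for unlabeled patients
#'
#' @param imputer a fitted \code{race_imputer}.
#' @param cohort a \code{cohort_table} with the training schema.
#' @return Data frame with one row per patient: \code{label} (argmax
#'   class, lexicographic tie-break) and one \code{prob_<class>} column
#'   per class (rows on the probability simplex).
#' @export
impute_race <- function(imputer, cohort) {
  stopifnot(inherits(imputer, "race_imputer"), is_cohort_table(cohort))
  schema <- cohort_schema(cohort)
  if (!identical(schema_fingerprint(schema), imputer$schema_fingerprint))
    stopf("cohort schema does not match the schema the imputer was fitted on")
  X <- imputer_features(cohort, schema, imputer$feature_stats)$X
  if (ncol(X) != imputer$input_dim)
    stopf("encoded feature count (%d) does not match the imputer input dimension (%d)",
          ncol(X), imputer$input_dim)
  p <- softmax_rows(mlp_forward(imputer$net, X)$out)
  colnames(p) <- paste0("prob_", imputer$classes)
  label <- imputer$classes[apply(p, 1L, which.max)]
  cbind(data.frame(label = label, stringsAsFactors = FALSE),
        as.data.frame(p))
}

#' Write imputed labels back into a cohort
#'
#' Adds the predicted labels to the race column for rows whose label was
#' \code{unknown}, appends the class-probability columns, and a
#' \code{race_provenance} flag distinguishing self-reported from imputed
#' labels.
#'
#' @param cohort a \code{cohort_table}.
#' @param imputer a fitted \code{race_imputer}.
#' @return The augmented \code{cohort_table}.
#' @export
augment_with_imputed_race <- function(cohort, imputer) {
  schema <- cohort_schema(cohort)
  pred <- impute_race(imputer, cohort)
  unknown <- cohort[[schema$race_column]] == "unknown"
  df <- as.data.frame(cohort)
  df$race_provenance <- ifelse(unknown, "imputed", "self-reported")
  df[[schema$race_column]][unknown] <- pred$label[unknown]
  for (cn in grep("^prob_", names(pred), value = TRUE)) df[[cn]] <- pred[[cn]]
  cohort_table(df, schema)
}
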