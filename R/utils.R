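# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}

# derive a child seed from a master seed; keeps results within 32-bit range
child_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

logistic <- function(x) 1 / (1 + exp(-x))

# numerically safe log(sigmoid(x)) and log(1 - sigmoid(x))
log_sigmoid <- function(x) ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))

clip01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)
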