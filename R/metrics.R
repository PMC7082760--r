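#' Individual causal effect of a binary intervention
#'
#' For a treated patient (t = 1) the ICE is the factual outcome minus the
#' estimated counterfactual outcome under no intervention,
#' \code{y(1) - y_hat(0)}; for an untreated patient it is the estimated
#' outcome under intervention minus the factual outcome,
#' \code{y_hat(1) - y(0)}. All arguments are vectorized.
#'
#' @param y_factual observed outcome(s).
#' @param y_hat_other_arm model estimate(s) of the unobserved arm.
#' @param t_factual factual intervention indicator(s), 0 or 1.
#' @return Numeric vector of individual causal effects.
#' @examples
#' ice(8, 6, 1)  # treated: y(1) - y_hat(0) = 2
#' ice(7, 7, 0)  # untreated, estimate equals factual: 0
#' @export
ice <- function(y_factual, y_hat_other_arm, t_factual) {
  if (!all(t_factual %in% c(0, 1)))
    stopf("t_factual must be binary (0/1)")
  ifelse(t_factual == 1, y_factual - y_hat_other_arm,
         y_hat_other_arm - y_factual)
}

get_ice_terms <- function(estimates) {
  if (inherits(estimates, "counterfactual_estimates") ||
      (is.data.frame(estimates) && "ice" %in% names(estimates)))
    estimates$ice
  else if (is.numeric(estimates)) estimates
  else stopf("estimates must be a counterfactual_estimates object or a numeric vector of ICE terms")
}

#' Average individual causal effect of a patient group
#'
#' Aggregates squared ICE terms over a group of n patients:
#' \code{sum over untreated of (y_hat(1) - y(0))^2 plus sum over treated of
#' (y(1) - y_hat(0))^2, divided by n}. Under the default \code{"root"}
#' convention the square root of this mean is returned, keeping the value
#' on the Gleason Score scale; \code{"mean-square"} returns the mean of
#' squares itself. The convention used is attached as an attribute.
#'
#' @param estimates a \code{counterfactual_estimates} data frame for one
#'   group, or a numeric vector of ICE terms.
#' @param convention \code{"root"} (default) or \code{"mean-square"}.
#' @return Scalar AICE with attribute \code{"convention"}.
#' @examples
#' aice(c(2, 1))             # sqrt((4 + 1) / 2)
#' aice(c(2, 1), "mean-square")
#' @export
aice <- function(estimates, convention = c("root", "mean-square")) {
  convention <- match.arg(convention)
  terms <- get_ice_terms(estimates)
  n <- length(terms)
  if (n == 0L) stopf("AICE of an empty group is undefined")
  ms <- sum(terms^2) / n
  structure(if (convention == "root") sqrt(ms) else ms,
            convention = convention)
}

#' Signed mean individual causal effect
#'
#' The plain mean of the ICE terms. Unlike \code{\link{aice}} (which
#' aggregates squared terms and therefore measures effect magnitude), this
#' retains direction; it is reported alongside AICE wherever directional
#' statements are needed.
#'
#' @inheritParams aice
#' @return Scalar mean ICE.
#' @export
mean_ice <- function(estimates) {
  terms <- get_ice_terms(estimates)
  if (!length(terms)) stopf("mean ICE of an empty group is undefined")
  mean(terms)
}

#' Root mean square error of factual-arm reconstruction
#'
#' Measures the precision of the inference process: each patient
#' contributes the squared difference between the model's factual-arm
#' estimate and the observed outcome, i.e.
#' \code{sqrt((sum over untreated of (y_hat(0) - y(0))^2 + sum over
#' treated of (y_hat(1) - y(1))^2) / n)}.
#'
#' @param estimates a \code{counterfactual_estimates} data frame for one
#'   group.
#' @param convention \code{"root"} (default) or \code{"mean-square"}.
#' @return Scalar RMSE (>= 0).
#' @export
rmse <- function(estimates, convention = c("root", "mean-square")) {
  convention <- match.arg(convention)
  if (!is.data.frame(estimates) ||
      !all(c("y_hat_0", "y_hat_1", "t_factual", "y_factual") %in%
             names(estimates)))
    stopf("estimates must carry y_hat_0, y_hat_1, t_factual, y_factual")
  n <- nrow(estimates)
  if (n == 0L) stopf("RMSE of an empty group is undefined")
  y_hat_f <- ifelse(estimates$t_factual == 1,
                    estimates$y_hat_1, estimates$y_hat_0)
  ms <- sum((y_hat_f - estimates$y_factual)^2) / n
  structure(if (convention == "root") sqrt(ms) else ms,
            convention = convention)
}
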