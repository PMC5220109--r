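#' Risk-sensitive utility of a state or action
#'
#' Combines an expected-reward estimate (Value, `Q`) with a reward-variance
#' estimate (Risk, `h`) into the decision variable the model's actors climb:
#' \deqn{U = Q - \alpha\,\mathrm{sign}(Q)\,h}
#' The sign weighting makes the risk term a penalty for positively valued
#' states and a bonus for negatively valued ones (non-linear risk
#' sensitivity). `sign(0)` is taken as 0, so an untrained state with `Q = 0`
#' carries no risk adjustment.
#'
#' @param Q numeric vector of Value estimates (dimensionless expected reward).
#' @param h numeric vector of Risk estimates; must be non-negative.
#' @param alpha risk sensitivity, a single non-negative number. `alpha = 0`
#'   reduces utility to Value. Proposed correlate of striatal serotonin.
#' @return numeric vector of utilities, recycled to the common length of
#'   `Q` and `h`.
#' @examples
#' utility(0.8, 0.5, 0)  # 0.8
#' utility(0.8, 0.5, 1)  # 0.3
#' utility(-0.4, 0.5, 1) # 0.1
#' @export
utility <- function(Q, h, alpha) {
  stopifnot(is.numeric(Q), is.numeric(h), is.numeric(alpha), length(alpha) == 1L)
  if (any(h < 0)) stop("risk 'h' must be non-negative")
  if (alpha < 0) stop("risk sensitivity 'alpha' must be non-negative")
  Q - alpha * sign(Q) * h
}

#' Dopamine condition of a simulated subject group
#'
#' Describes how temporal-difference (TD) errors -- the model's dopamine
#' correlate -- are limited for a subject group. Healthy controls leave the
#' TD error untouched. The Parkinsonian OFF-medication state clamps the TD
#' error to a ceiling `delta_star`; the ON-medication state additionally adds
#' a medication term `delta_med` to the (possibly clamped) error.
#'
#' @param label one of `"control"`, `"pd_off"`, `"pd_on"`.
#' @param delta_star TD ceiling (required for the PD conditions).
#' @param delta_med additive medication term (PD ON; defaults to 0).
#' @return an object of class `dopamine_condition`.
#' @seealso [clamp_dopamine()]
#' @export
dopamine_condition <- function(label = c("control", "pd_off", "pd_on"),
                               delta_star = NULL, delta_med = 0) {
  label <- match.arg(label)
  if (label != "control") {
    if (is.null(delta_star) || !is.finite(delta_star))
      stop("PD conditions require a finite TD ceiling 'delta_star'")
  } else {
    delta_star <- NULL
  }
  if (label != "pd_on") delta_med <- 0
  structure(list(label = label, delta_star = delta_star,
                 delta_med = delta_med),
            class = "dopamine_condition")
}

#' @export
print.dopamine_condition <- function(x, ...) {
  cat("<dopamine_condition:", x$label)
  if (!is.null(x$delta_star)) cat(", delta* =", x$delta_star)
  if (x$label == "pd_on") cat(", delta_med =", x$delta_med)
  cat(">\n")
  invisible(x)
}

#' Clamp a TD error under a dopamine condition
#'
#' Applies the Parkinsonian dopamine ceiling to a temporal-difference error:
#' controls pass `delta` through unchanged; PD OFF returns
#' `min(delta, delta_star)`; PD ON returns `min(delta, delta_star) +
#' delta_med`, the medication term being added whether or not the ceiling was
#' hit. Only an upper clamp is applied; negative errors pass through. The
#' clamp is applied at every site where a TD error is computed, in both
#' training and evaluation.
#'
#' @param delta numeric vector of TD errors.
#' @param condition a [dopamine_condition()].
#' @return clamped TD errors, same length as `delta`.
#' @examples
#' off <- dopamine_condition("pd_off", delta_star = 0.02)
#' clamp_dopamine(0.3, off) # 0.02
#' @export
clamp_dopamine <- function(delta, condition) {
  if (!inherits(condition, "dopamine_condition"))
    stop("'condition' must be a dopamine_condition")
  switch(condition$label,
    control = delta,
    pd_off  = pmin(delta, condition$delta_star),
    pd_on   = pmin(delta, condition$delta_star) + condition$delta_med
  )
}

#' Risk prediction error
#'
#' The error driving the Risk (reward-variance) estimate:
#' \eqn{\xi = \delta^2 - h}. A Risk updated by `h <- h + eta * xi` tracks the
#' variance of the TD error.
#'
#' @param delta TD error (numeric vector).
#' @param h current Risk estimate, non-negative.
#' @return numeric vector \eqn{\delta^2 - h}.
#' @export
risk_prediction_error <- function(delta, h) {
  if (any(h < 0)) stop("risk 'h' must be non-negative")
  delta^2 - h
}
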