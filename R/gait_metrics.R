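#' Step latencies from the intent-accumulator
#'
#' The model's footstep generator: a decision variable `s` ("intent for
#' walking") accumulates `kappa(t) * speed(t)` each time step and a footstep
#' is executed whenever `s` crosses the threshold (`th = 1`); the step
#' latency is the number of time steps since the previous crossing, and `s`
#' resets to 0 without overshoot carry-over. `kappa` is the cognitive
#' drive: the walk Utility of a pending cue plus the baseline `b`, or `b`
#' alone when no cue response is pending. Negative per-step increments
#' (possible when a cue's walk Utility is strongly negative) contribute
#' nothing rather than draining the accumulator.
#'
#' @param speed per-step velocity magnitudes `||dZ(t)||`.
#' @param kappa per-step drive values, same length as `speed` (scalar is
#'   recycled).
#' @param th decision threshold (default 1).
#' @return integer vector of step latencies (time steps per footstep), with
#'   attribute `residual_steps`: trailing steps that had not yet produced a
#'   crossing when the series ended.
#' @export
accumulate_latency <- function(speed, kappa = 1, th = 1) {
  n <- length(speed)
  kappa <- rep_len(kappa, n)
  stopifnot(n == length(kappa))
  inc <- pmax(kappa * speed, 0)
  lat <- integer(0)
  s <- 0; since <- 0L
  for (t in seq_len(n)) {
    s <- s + inc[t]
    since <- since + 1L
    if (s >= th) {
      lat <- c(lat, since)
      s <- 0; since <- 0L
    }
  }
  structure(lat, residual_steps = since)
}

#' Modal (preferred) step latency
#'
#' The mode of the integer latency distribution: the subject's baseline
#' footstep pace, against which motor arrests are defined. Ties are broken
#' toward the smaller latency. Capped (censored) latencies are excluded.
#'
#' @param latencies integer step latencies.
#' @param capped optional logical vector flagging censored latencies.
#' @return the modal latency (integer-valued numeric).
#' @export
modal_latency <- function(latencies, capped = NULL) {
  if (!is.null(capped)) latencies <- latencies[!capped]
  if (length(latencies) == 0L) stop("no latencies to take the mode of")
  tab <- table(latencies)
  as.numeric(names(tab)[which.max(tab)]) # which.max: first max = smallest value
}

#' Count motor arrests
#'
#' A motor arrest is a step latency strictly greater than twice the modal
#' latency (a latency of exactly twice the mode is not an arrest). Capped
#' segments -- where the accumulator never crossed threshold before the
#' per-segment step cap -- always count as arrests.
#'
#' @param latencies integer step latencies.
#' @param modal the modal latency, see [modal_latency()].
#' @param capped optional logical vector flagging capped latencies.
#' @return integer arrest count.
#' @export
count_motor_arrests <- function(latencies, modal, capped = NULL) {
  stopifnot(modal >= 1)
  if (is.null(capped)) capped <- rep(FALSE, length(latencies))
  sum(latencies > 2 * modal | capped)
}

#' Maximum scaled footstep latency after a cue (MFSL)
#'
#' The maximum latency among the first one to three footsteps completed
#' after a cue presentation, scaled by (divided by) the modal latency.
#'
#' @param latencies_after_cue latencies of the first 1-3 post-cue
#'   footsteps.
#' @param modal the modal latency.
#' @return `max(latencies_after_cue) / modal`, or `NA` for an empty window.
#' @export
mfsl <- function(latencies_after_cue, modal) {
  stopifnot(modal >= 1)
  if (length(latencies_after_cue) == 0L) return(NA_real_)
  max(latencies_after_cue) / modal
}

#' Maximum step latency near a doorway
#'
#' The region within `window` length units of a doorway plane isolates the
#' doorway's effect on footstep timing. Returns, per doorway, the maximum
#' latency among footsteps whose completion position lies inside the
#' window.
#'
#' @param trial a trial record: data.frame with at least columns `latency`,
#'   `y` (completion position) and `doorway` (nearest doorway index).
#' @param corridor the [build_corridor()] the trial ran on.
#' @param window half-width of the doorway region (default 0.1).
#' @return data.frame with columns `doorway`, `width`, `max_latency`
#'   (`NA` where no footstep completed inside the window).
#' @export
doorway_latency <- function(trial, corridor, window = 0.1) {
  out <- data.frame(doorway = corridor$doorway, width = corridor$width,
                    max_latency = NA_real_)
  if (nrow(trial) == 0L) return(out)
  for (i in seq_len(nrow(corridor))) {
    sel <- abs(trial$y - corridor$center_y[i]) <= window
    if (any(sel)) out$max_latency[i] <- max(trial$latency[sel])
  }
  out
}
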