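#' Create an untrained motor critic
#'
#' The motor loop's Critic: two linear-sigmoidal function approximators
#' over the 100-dimensional view vector, one for the Value (expected
#' reward of the current view) and one for the Risk (variance of the TD
#' error), each squashed into `(0, gain)`.
#'
#' @param lambda sigmoid slope (default 0.1; the view vector's summed
#'   input is of order tens, so a shallow slope keeps the sigmoid in its
#'   operating range).
#' @param A_Q,A_h output gains of the Value and Risk approximators.
#' @param eta learning rate (default 0.05).
#' @param gamma discount factor (default 0.9).
#' @param w0 half-width of the uniform weight initialisation (default 0.01).
#' @param n view-vector dimension (default 100).
#' @return an object of class `motor_critic` with weight vectors
#'   `W_value` and `W_risk`.
#' @export
motor_critic <- function(lambda = 0.1, A_Q = 1, A_h = 1, eta = 0.05,
                         gamma = 0.9, w0 = 0.01, n = 100) {
  structure(list(
    W_value = stats::runif(n, -w0, w0),
    W_risk  = stats::runif(n, -w0, w0),
    lambda = lambda, A_Q = A_Q, A_h = A_h, eta = eta, gamma = gamma),
    class = "motor_critic")
}

#' Go/Explore/NoGo actor parameters
#'
#' Gains and sensitivities of the three action-selection regimes, the
#' exploration width, and the slope of the anti-backward velocity clamp.
#'
#' @param A_G,A_N,A_E gains of the Go, NoGo and Explore terms.
#' @param lambda_G,lambda_N sensitivities of the Go and NoGo sigmoids.
#' @param sigma_E exploration width: the Explore term is scaled by
#'   `exp(-dU^2 / sigma_E^2)`, so exploration is strongest when the
#'   Utility gradient vanishes. Group-specific (Table of group regimes).
#' @param lambda_vel slope of the sigmoid applied to the forward velocity
#'   component.
#' @return an object of class `gen_params`.
#' @export
gen_params <- function(A_G = 1, A_N = 1, A_E = 0.3, lambda_G = 5,
                       lambda_N = 5, sigma_E = 0.5, lambda_vel = 5) {
  stopifnot(A_G >= 0, A_N >= 0, A_E >= 0, sigma_E > 0)
  structure(list(A_G = A_G, A_N = A_N, A_E = A_E, lambda_G = lambda_G,
                 lambda_N = lambda_N, sigma_E = sigma_E,
                 lambda_vel = lambda_vel),
            class = "gen_params")
}

#' Motor Value of a view
#' @param critic a [motor_critic()].
#' @param phi a 100-dimensional view vector in \{-1, +1\}.
#' @return Value in `(0, A_Q)`.
#' @export
motor_value <- function(critic, phi) {
  if (length(phi) != length(critic$W_value))
    stop("view vector dimension mismatch")
  critic$A_Q * logistic(sum(critic$W_value * phi), critic$lambda)
}

#' Motor Risk of a view
#' @inheritParams motor_value
#' @return Risk in `(0, A_h)`.
#' @export
motor_risk <- function(critic, phi) {
  if (length(phi) != length(critic$W_risk))
    stop("view vector dimension mismatch")
  critic$A_h * logistic(sum(critic$W_risk * phi), critic$lambda)
}

#' Motor-loop TD error under a dopamine condition
#'
#' `delta = r + gamma * Q_t - Q_prev`, clamped by [clamp_dopamine()].
#'
#' @param r reward received this step.
#' @param Q_t Value of the current view.
#' @param Q_prev Value of the previous step's view.
#' @param gamma discount factor.
#' @param condition a [dopamine_condition()].
#' @return the clamped TD error.
#' @export
motor_td_error <- function(r, Q_t, Q_prev, gamma,
                           condition = dopamine_condition("control")) {
  clamp_dopamine(r + gamma * Q_t - Q_prev, condition)
}

#' Update the motor critic's weight vectors
#'
#' Value weights move by `eta * delta * phi`; Risk weights by
#' `eta * delta^2 * phi` (the default), or by the residual form
#' `eta * (delta^2 - h) * phi` when `risk_residual = TRUE`, which makes
#' the Risk weights track the TD-error variance rather than grow
#' monotonically.
#'
#' @param critic a [motor_critic()].
#' @param delta the (clamped) TD error.
#' @param phi the view vector the error was computed for.
#' @param risk_residual use the variance-residual Risk update.
#' @return the updated `motor_critic`.
#' @export
update_critic <- function(critic, delta, phi, risk_residual = FALSE) {
  critic$W_value <- critic$W_value + critic$eta * delta * phi
  rerr <- if (risk_residual) delta^2 - motor_risk(critic, phi) else delta^2
  critic$W_risk <- critic$W_risk + critic$eta * rerr * phi
  critic
}

#' Go/Explore/NoGo velocity update
#'
#' Stochastic hill-climbing over the motor Utility: with
#' `dU = U(t) - U(t-1)`,
#' \deqn{\Delta Z = A_G\,\sigma(\lambda_G dU)\,\Delta Z_{prev}
#'   + A_E\,\chi\,e^{-dU^2/\sigma_E^2}
#'   - A_N\,\sigma(-\lambda_N dU)\,\Delta Z_{prev}}
#' A rising Utility (`dU > 0`) saturates the Go term and reproduces the
#' previous velocity (`dU -> +Inf` gives `A_G * dZ_prev`); a falling
#' Utility engages NoGo and reverses it (`dU -> -Inf` gives
#' `-A_N * dZ_prev`); at `dU = 0` the Go and NoGo terms cancel for
#' `A_G = A_N` and the Gaussian exploration term is at full strength.
#' (The NoGo sigmoid takes the negated gradient; with a common sign the
#' two saturating terms would cancel identically at equal gains, leaving
#' no hill-climbing at all.)
#'
#' @param dU Utility difference between consecutive visited states.
#' @param dZ_prev previous applied velocity `c(dx, dy)`.
#' @param params a [gen_params()].
#' @param chi optional 2-vector of exploration noise; drawn fresh from a
#'   standard normal when omitted.
#' @return the raw velocity `c(dx, dy)` (before [clamp_forward()]).
#' @export
gen_policy <- function(dU, dZ_prev, params, chi = NULL) {
  stopifnot(all(is.finite(dZ_prev)))
  if (is.null(chi)) chi <- stats::rnorm(2)
  go <- params$A_G * logistic(params$lambda_G * dU)
  nogo <- params$A_N * logistic(-params$lambda_N * dU)
  explore <- if (is.finite(dU)) params$A_E * exp(-dU^2 / params$sigma_E^2) else 0
  (go - nogo) * dZ_prev + explore * chi
}

#' Prevent backward motion
#'
#' The forward (along-track) velocity component is passed through a
#' sigmoid, mapping it into `(0, 1)`: the agent can stall but never move
#' backward. The lateral component passes through unchanged.
#'
#' @param dZ raw velocity `c(dx, dy)` from [gen_policy()].
#' @param params a [gen_params()] (supplies `lambda_vel`).
#' @return the applied velocity.
#' @export
clamp_forward <- function(dZ, params) {
  c(dZ[1], logistic(params$lambda_vel * dZ[2]))
}

#' Navigate the corridor under the full per-time-step loop
#'
#' The workhorse simulation: at every time step the agent computes the
#' view vector of the nearest upcoming doorway, the Critic's Value, Risk
#' and Utility, the TD error of the transition just completed (clamped by
#' the dopamine condition and, when `learn = TRUE`, applied to the
#' weights), and the Utility gradient `dU`; the Go/Explore/NoGo actor
#' then produces a velocity, the forward component is clamped positive,
#' and the environment advances, emitting passage/collision rewards.
#' In parallel the intent accumulator converts speeds into footstep
#' latencies: its drive is `b`, raised (or lowered) to `b + U_w` from the
#' onset of a scheduled cue with walk Utility `U_w` until the next
#' completed footstep. A segment (one doorway) that exceeds `step_cap`
#' time steps is closed as capped -- the pending footstep is recorded as
#' censored and the agent is placed past the doorway.
#'
#' @param critic a [motor_critic()].
#' @param gen a [gen_params()].
#' @param corridor a [build_corridor()] object.
#' @param condition motor-loop [dopamine_condition()].
#' @param alpha_mot motor risk sensitivity.
#' @param schedule optional [cue_schedule()]; cues affect only the
#'   latency accumulator, never the navigation itself.
#' @param cue_uw named numeric vector of walk Utilities per cue label
#'   (from [cue_utilities()]); required when `schedule` has cues.
#' @param b baseline accumulator drive (default 1).
#' @param th accumulator threshold (default 1).
#' @param learn update the critic weights during the run.
#' @param risk_residual see [update_critic()].
#' @param step_cap per-segment time-step cap (default 500).
#' @param record_steps also return the per-time-step log.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference); both
#'   consume the RNG stream identically and give identical results.
#' @return list with elements:
#'   \describe{
#'     \item{critic}{the updated critic.}
#'     \item{footsteps}{data.frame, one row per completed (or censored)
#'       footstep: `step`, `latency`, `y`, `segment`, `width`, `cue`,
#'       `post_cue` (footstep ordinal since the last cue onset), `cued`
#'       (drive still held the cue's Utility), `capped`, `u_mot`,
#'       `u_wcog`.}
#'     \item{segments}{data.frame, one row per doorway: `doorway`,
#'       `width`, `steps`, `collisions`, `passed`, `capped`.}
#'     \item{steps}{per-time-step log (`NULL` unless `record_steps`):
#'       `t`, `x`, `y`, `dx`, `dy`, `speed`, `Q`, `h`, `U`, `dU`,
#'       `reward`, `event`, `kappa`.}
#'   }
#' @export
navigate <- function(critic, gen, corridor,
                     condition = dopamine_condition("control"),
                     alpha_mot = 0, schedule = NULL, cue_uw = NULL,
                     b = 1, th = 1, learn = TRUE, risk_residual = FALSE,
                     step_cap = 500, record_steps = FALSE,
                     engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  n_door <- nrow(corridor)
  onset_y <- rep(NA_real_, n_door)
  drive <- rep(NA_real_, n_door)
  cue_lab <- rep(NA_character_, n_door)
  if (!is.null(schedule)) {
    m <- match(schedule$doorway, corridor$doorway)
    onset_y[m] <- schedule$onset_y
    cue_lab[m] <- schedule$cue
    has <- !is.na(cue_lab)
    if (any(has)) {
      if (is.null(cue_uw)) stop("'cue_uw' required when the schedule has cues")
      drive[has] <- cue_uw[cue_lab[has]]
      if (any(is.na(drive[has]))) stop("missing cue Utility for a scheduled cue")
    }
  }
  run <- if (engine == "cpp") .navigate_cpp else .navigate_r
  out <- run(critic, gen, corridor, condition, alpha_mot, onset_y, drive,
             b, th, learn, risk_residual, step_cap, record_steps)
  out$footsteps$cue <- ifelse(out$footsteps$cue_seg > 0 &
                                out$footsteps$post_cue >= 1,
                              cue_lab[pmax(out$footsteps$cue_seg, 1L)],
                              NA_character_)
  out$footsteps$width <- corridor$width[out$footsteps$segment]
  out$segments <- data.frame(doorway = corridor$doorway,
                             width = corridor$width,
                             steps = out$segments$steps,
                             collisions = out$segments$collisions,
                             passed = out$segments$passed,
                             capped = out$segments$capped)
  out
}

.navigate_cpp <- function(critic, gen, corridor, condition, alpha_mot,
                          onset_y, drive, b, th, learn, risk_residual,
                          step_cap, record_steps) {
  ds <- if (is.null(condition$delta_star)) Inf else condition$delta_star
  res <- motor_run_cpp(
    critic$W_value, critic$W_risk,
    corridor$center_y, corridor$width / 2,
    attr(corridor, "height"), attr(corridor, "half_width"),
    onset_y, drive,
    c(critic$lambda, critic$A_Q, critic$A_h, critic$eta, critic$gamma,
      alpha_mot,
      gen$A_G, gen$A_N, gen$A_E, gen$lambda_G, gen$lambda_N,
      gen$sigma_E, gen$lambda_vel,
      b, th, ds, condition$delta_med),
    learn, risk_residual, as.integer(step_cap), record_steps)
  critic$W_value <- res$W_value
  critic$W_risk <- res$W_risk
  fs <- as.data.frame(res$footsteps)
  names(fs) <- c("step", "latency", "y", "segment", "cue_seg", "post_cue",
                 "cued", "capped", "u_mot", "u_wcog")
  fs$segment <- as.integer(fs$segment)
  fs$cue_seg <- as.integer(fs$cue_seg)
  fs$post_cue <- as.integer(fs$post_cue)
  fs$latency <- as.integer(fs$latency)
  fs$cued <- fs$cued > 0
  fs$capped <- fs$capped > 0
  sg <- as.data.frame(res$segments)
  names(sg) <- c("steps", "collisions", "passed", "capped")
  sg$passed <- sg$passed > 0
  sg$capped <- sg$capped > 0
  steps <- NULL
  if (record_steps) {
    steps <- as.data.frame(res$steps)
    names(steps) <- c("t", "x", "y", "dx", "dy", "speed", "Q", "h", "U",
                      "dU", "reward", "event", "kappa")
  }
  list(critic = critic, footsteps = fs, segments = sg, steps = steps)
}

# Pure-R reference engine; mirrors the compiled loop draw for draw.
.navigate_r <- function(critic, gen, corridor, condition, alpha_mot,
                        onset_y, drive, b, th, learn, risk_residual,
                        step_cap, record_steps) {
  n_door <- nrow(corridor)
  agent <- agent_state()
  seg_steps <- integer(n_door); seg_coll <- integer(n_door)
  seg_pass <- logical(n_door); seg_cap <- logical(n_door)
  fs <- list(); steps_log <- list()
  Q_prev <- NA_real_; U_prev <- NA_real_
  r_pending <- 0; fresh <- TRUE
  s_acc <- 0; since <- 0L
  cue_live <- FALSE; cue_u <- NA_real_; post_cue <- -1L; cue_seg <- 0L
  t <- 0L
  while (TRUE) {
    target <- next_doorway(agent$position[2], corridor)
    if (is.na(target)) break
    t <- t + 1L
    phi <- compute_view_vector(agent, corridor)
    Q <- motor_value(critic, phi)
    h <- motor_risk(critic, phi)
    U <- utility(Q, h, alpha_mot)
    if (!fresh) {
      delta <- clamp_dopamine(r_pending + critic$gamma * Q - Q_prev, condition)
      if (learn) critic <- update_critic(critic, delta, phi, risk_residual)
      dU <- U - U_prev
    } else {
      dU <- 0
      fresh <- FALSE
    }
    dZ_raw <- gen_policy(dU, agent$velocity, gen)
    dZ <- clamp_forward(dZ_raw, gen)
    y_before <- agent$position[2]
    stepped <- step_environment(agent, dZ, corridor)
    agent <- stepped$agent
    r_pending <- stepped$reward
    speed <- sqrt(sum(dZ^2))
    kappa <- if (cue_live) b + cue_u else b
    s_acc <- s_acc + max(kappa * speed, 0)
    since <- since + 1L
    seg_steps[target] <- seg_steps[target] + 1L
    if (stepped$event == "collided") seg_coll[target] <- seg_coll[target] + 1L
    crossed <- s_acc >= th
    capped_now <- seg_steps[target] >= step_cap && !crossed &&
      stepped$event != "passed"
    if (crossed || capped_now) {
      if (post_cue >= 0L) post_cue <- post_cue + 1L
      fs[[length(fs) + 1L]] <- data.frame(
        step = t, latency = since, y = agent$position[2],
        segment = target, cue_seg = cue_seg, post_cue = post_cue,
        cued = cue_live, capped = capped_now,
        u_mot = U, u_wcog = if (cue_live) cue_u else NA_real_)
      s_acc <- 0; since <- 0L
      cue_live <- FALSE
    }
    if (record_steps) {
      steps_log[[t]] <- data.frame(
        t = t, x = agent$position[1], y = agent$position[2],
        dx = dZ[1], dy = dZ[2], speed = speed, Q = Q, h = h, U = U,
        dU = dU, reward = stepped$reward,
        event = match(stepped$event, c("none", "passed", "collided")) - 1,
        kappa = kappa)
    }
    # cue onset crossed during this movement takes effect from the next step;
    # a still-pending previous cue is censored here: its gated footstep never
    # completed, so a capped latency is recorded (one decision per cue)
    if (!is.na(onset_y[target]) &&
        onset_y[target] > y_before && onset_y[target] <= agent$position[2]) {
      if (cue_live && since > 0L) {
        fs[[length(fs) + 1L]] <- data.frame(
          step = t, latency = since, y = agent$position[2],
          segment = target, cue_seg = cue_seg, post_cue = 1L,
          cued = TRUE, capped = TRUE, u_mot = U, u_wcog = cue_u)
        s_acc <- 0; since <- 0L
      }
      cue_live <- TRUE; cue_u <- drive[target]; post_cue <- 0L
      cue_seg <- target
    }
    if (stepped$event == "passed") {
      seg_pass[target] <- TRUE
    } else if (capped_now) {
      seg_cap[target] <- TRUE
      agent <- agent_state(c(0, corridor$center_y[target] + 0.01))
      fresh <- TRUE; r_pending <- 0
    }
    Q_prev <- Q; U_prev <- U
  }
  if (cue_live && since > 0L) { # run ended with the last cue still pending
    fs[[length(fs) + 1L]] <- data.frame(
      step = t, latency = since, y = agent$position[2],
      segment = cue_seg, cue_seg = cue_seg, post_cue = 1L,
      cued = TRUE, capped = TRUE, u_mot = U_prev, u_wcog = cue_u)
  }
  fs <- if (length(fs)) do.call(rbind, fs) else
    data.frame(step = integer(0), latency = integer(0), y = numeric(0),
               segment = integer(0), cue_seg = integer(0),
               post_cue = integer(0), cued = logical(0), capped = logical(0),
               u_mot = numeric(0), u_wcog = numeric(0))
  fs$latency <- as.integer(fs$latency)
  list(critic = critic, footsteps = fs,
       segments = data.frame(steps = seg_steps, collisions = seg_coll,
                             passed = seg_pass, capped = seg_cap),
       steps = if (record_steps) do.call(rbind, steps_log) else NULL)
}

#' Pre-train the motor critic on cue-free corridor segments
#'
#' Convenience wrapper around [navigate()] with learning on and no cue
#' schedule.
#'
#' @inheritParams navigate
#' @param n_segments number of doorway segments to train on (a corridor of
#'   this many doorways is consumed).
#' @return as [navigate()].
#' @export
train_motor <- function(critic, gen, corridor,
                        condition = dopamine_condition("control"),
                        alpha_mot = 0, n_segments = nrow(corridor), ...) {
  if (n_segments < nrow(corridor)) {
    sub <- as.data.frame(corridor)[seq_len(n_segments), , drop = FALSE]
    corridor <- structure(sub, class = c("corridor", "data.frame"),
                          spacing = attr(corridor, "spacing"),
                          height = attr(corridor, "height"),
                          half_width = attr(corridor, "half_width"))
  }
  navigate(critic, gen, corridor, condition, alpha_mot, schedule = NULL, ...)
}
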