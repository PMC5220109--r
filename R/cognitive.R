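#' The 13 word-colour cues
#'
#' The cue inventory of the virtual-reality Stroop gait task: 4 simple cues
#' (the instruction words WALK and STOP in neutral ink or in their primed
#' colours), 3 congruent colour words (ink matches the word) and 6
#' incongruent colour words (ink is a different non-neutral colour). Cues
#' are written `WORD(colour)`.
#'
#' @return a data.frame with columns `label`, `word`, `color`, `class`.
#' @export
cue_table <- function() {
  simple <- data.frame(
    word  = c("WALK", "STOP", "WALK", "STOP"),
    color = c("neutral", "neutral", "green", "red"),
    class = "simple", stringsAsFactors = FALSE)
  colors <- c("red", "green", "blue")
  words <- c("RED", "GREEN", "BLUE")
  cong <- data.frame(word = words, color = colors, class = "congruent",
                     stringsAsFactors = FALSE)
  incong <- expand.grid(word = words, color = colors,
                        stringsAsFactors = FALSE)
  incong <- incong[tolower(incong$word) != incong$color, ]
  incong$class <- "incongruent"
  out <- rbind(simple, cong, incong)
  out <- data.frame(label = sprintf("%s(%s)", out$word, out$color), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.cog_words <- c("STOP", "WALK", "RED", "GREEN", "BLUE")
.cog_colors <- c("red", "green", "blue", "neutral")

#' Encode a cue as the cognitive network's 9-bit input
#'
#' Bits 1-5 are a one-hot code of the word (STOP, WALK, RED, GREEN, BLUE);
#' bits 6-9 a one-hot code of the ink colour (red, green, blue, neutral).
#'
#' @param cue a cue label like `"RED(green)"`, or a list/row with `word`
#'   and `color` entries.
#' @return numeric 0/1 vector of length 9 with exactly two bits set.
#' @export
encode_cue <- function(cue) {
  if (is.character(cue) && length(cue) == 1L) {
    m <- regmatches(cue, regexec("^([A-Z]+)\\(([a-z]+)\\)$", cue))[[1]]
    if (length(m) != 3L) stop("malformed cue label: ", cue)
    word <- m[2]; color <- m[3]
  } else {
    word <- cue$word; color <- cue$color
  }
  wi <- match(word, .cog_words)
  ci <- match(color, .cog_colors)
  if (is.na(wi)) stop("unknown cue word: ", word)
  if (is.na(ci)) stop("unknown cue colour: ", color)
  s <- numeric(9)
  s[wi] <- 1
  s[5L + ci] <- 1
  s
}

#' Correct walk/stop response for each cue under a protocol mapping
#'
#' Simple cues map directly (WALK -> walk, STOP -> stop). Complex cues are
#' counterbalanced across subjects: under `"congruent_walk"` congruent cues
#' demand walking and incongruent cues stopping; `"congruent_stop"` is the
#' reverse.
#'
#' @param mapping `"congruent_walk"` or `"congruent_stop"`.
#' @return character vector (`"walk"`/`"stop"`) named by cue label, in
#'   [cue_table()] order.
#' @export
cue_actions <- function(mapping = c("congruent_walk", "congruent_stop")) {
  mapping <- match.arg(mapping)
  cues <- cue_table()
  act <- ifelse(cues$class == "simple",
                ifelse(cues$word == "WALK", "walk", "stop"),
                ifelse(cues$class == "congruent",
                       if (mapping == "congruent_walk") "walk" else "stop",
                       if (mapping == "congruent_walk") "stop" else "walk"))
  stats::setNames(act, cues$label)
}

logistic <- function(x, lambda = 1) 1 / (1 + exp(-lambda * x))

#' Create an untrained cognitive network
#'
#' A two-layer action-value network: 9 input bits, an association layer of
#' 5 sigmoidal nodes, and 2 outputs -- the action Values for walking and
#' stopping, each squashed into `(0, A_Q)`. Weights are initialised
#' uniformly on `(-w0, w0)` from the current RNG stream.
#'
#' @param lambda sigmoid slope (default 4).
#' @param A_Q output gain: upper bound of the action Values (default 1).
#' @param eta learning rate (default 0.2).
#' @param tau softmax temperature of the training-time action competition
#'   (default 0.2).
#' @param w0 half-width of the uniform weight initialisation (default 0.3).
#' @return an object of class `cognitive_net` with weight matrices
#'   `W1` (5 x 9) and `W2` (2 x 5); output row 1 is walk, row 2 is stop.
#' @export
cognitive_net <- function(lambda = 4, A_Q = 1, eta = 0.2, tau = 0.2,
                          w0 = 0.3) {
  structure(list(
    W1 = matrix(stats::runif(45, -w0, w0), 5, 9),
    W2 = matrix(stats::runif(10, -w0, w0), 2, 5),
    lambda = lambda, A_Q = A_Q, eta = eta, tau = tau),
    class = "cognitive_net")
}

#' Forward pass of the cognitive network
#'
#' @param net a [cognitive_net()].
#' @param s a 9-bit cue encoding from [encode_cue()].
#' @return list with `M` (association activations, length 5) and `Q`
#'   (action Values, `c(walk, stop)`).
#' @export
cog_forward <- function(net, s) {
  M <- logistic(drop(net$W1 %*% s), net$lambda)
  Q <- net$A_Q * logistic(drop(net$W2 %*% M), net$lambda)
  list(M = M, Q = stats::setNames(Q, c("walk", "stop")))
}

# cue sampling probabilities of the two training phases
.training_mix <- function(cues, phase2 = FALSE) {
  p <- numeric(nrow(cues))
  if (!phase2) {
    p[cues$class == "simple"] <- 1 / 4
  } else {
    sc <- cues$class %in% c("simple", "congruent")
    p[sc] <- (2 / 3) / sum(sc)
    p[!sc] <- (1 / 3) / sum(!sc)
  }
  p
}

#' Greedy cue-action accuracy of a cognitive network
#'
#' Fraction of cues whose higher-valued action equals the protocol's
#' correct action, weighted by a cue-presentation distribution.
#'
#' @param net a [cognitive_net()].
#' @param mapping protocol mapping, see [cue_actions()].
#' @param weights cue weights; defaults to the phase-2 training mix
#'   (simple+congruent : incongruent at 2:1). Use equal weights for a
#'   uniform evaluation.
#' @return accuracy in `[0, 1]`.
#' @export
greedy_accuracy <- function(net, mapping = "congruent_walk", weights = NULL) {
  cues <- cue_table()
  if (is.null(weights)) weights <- .training_mix(cues, phase2 = TRUE)
  acts <- cue_actions(mapping)
  hit <- vapply(seq_len(nrow(cues)), function(i) {
    Q <- cog_forward(net, encode_cue(cues$label[i]))$Q
    c("walk", "stop")[which.max(Q)] == acts[[cues$label[i]]]
  }, logical(1))
  sum(weights * hit) / sum(weights)
}

#' Train the cognitive network on the two-phase cue protocol
#'
#' Phase 1 presents only the four simple cues (uniformly) for `n_simple`
#' trials, priming the word and colour responses; phase 2 presents all 13
#' cues for `n_mixed` trials with the simple-plus-congruent pool twice as
#' frequent as the incongruent pool. Each trial samples a cue, selects an
#' output node by a softmax competition over the action Values
#' (temperature `net$tau`), receives reward 1 for the correct action and 0
#' otherwise, and applies the reward-prediction-error update: the selected
#' node's output weights move by `eta * delta * M`, and all hidden weights
#' by the backpropagated error `W2[sel, ] * g'(net) * delta`. The
#' prediction error `delta = r - Q_sel` is clamped by the dopamine
#' condition before both updates.
#'
#' @param net a [cognitive_net()].
#' @param condition a [dopamine_condition()] (its `delta_star` here is the
#'   cognitive-loop ceiling).
#' @param mapping protocol mapping, see [cue_actions()].
#' @param n_simple phase-1 trials (default 600).
#' @param n_mixed phase-2 trials (default 1000).
#' @param eval_every evaluate greedy accuracy every this many trials.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference); both
#'   consume the RNG stream identically and give identical results.
#' @return the trained `cognitive_net`, with an `accuracy_trace` attribute
#'   (data.frame `trial`, `accuracy`).
#' @export
train_cognitive <- function(net, condition = dopamine_condition("control"),
                            mapping = "congruent_walk",
                            n_simple = 600, n_mixed = 1000,
                            eval_every = 200, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cues <- cue_table()
  S <- vapply(cues$label, encode_cue, numeric(9)) # 9 x 13
  correct <- as.integer(cue_actions(mapping) == "walk") # 1 = walk
  p1 <- .training_mix(cues, phase2 = FALSE)
  p2 <- .training_mix(cues, phase2 = TRUE)
  ds <- if (is.null(condition$delta_star)) Inf else condition$delta_star
  dmed <- condition$delta_med

  n_total <- n_simple + n_mixed
  marks <- sort(unique(c(seq(0, n_total, by = eval_every), n_simple, n_total)))
  trace <- data.frame(trial = integer(0), accuracy = numeric(0))
  for (i in seq_len(length(marks) - 1L)) {
    n1 <- max(0L, min(marks[i + 1L], n_simple) - marks[i])
    n2 <- (marks[i + 1L] - marks[i]) - n1
    net <- .cog_train_chunk(net, S, correct, p1, p2, n1, n2, ds, dmed, engine)
    trace <- rbind(trace, data.frame(
      trial = marks[i + 1L],
      accuracy = greedy_accuracy(net, mapping)))
  }
  attr(net, "accuracy_trace") <- trace
  net
}

# one block of training trials: n1 phase-1 draws followed by n2 phase-2 draws
.cog_train_chunk <- function(net, S, correct, p1, p2, n1, n2, ds, dmed,
                             engine) {
  if (engine == "cpp") {
    res <- cog_train_cpp(net$W1, net$W2, S, correct, p1, p2,
                         as.integer(n1), as.integer(n2),
                         net$lambda, net$A_Q, net$eta, net$tau, ds, dmed)
    net$W1 <- res$W1; net$W2 <- res$W2
    return(net)
  }
  W1 <- net$W1; W2 <- net$W2
  lam <- net$lambda; A_Q <- net$A_Q; eta <- net$eta; tau <- net$tau
  c1 <- cumsum(p1); c2 <- cumsum(p2)
  for (t in seq_len(n1 + n2)) {
    cp <- if (t <= n1) c1 else c2
    k <- min(findInterval(stats::runif(1), cp) + 1L, ncol(S))
    s <- S[, k]
    net1 <- drop(W1 %*% s)
    M <- logistic(net1, lam)
    Q <- A_Q * logistic(drop(W2 %*% M), lam)
    ex <- exp((Q - max(Q)) / tau)
    sel <- if (stats::runif(1) < ex[1] / sum(ex)) 1L else 2L
    r <- as.numeric((sel == 1L) == (correct[k] == 1L))
    delta <- min(r - Q[sel], ds) + dmed
    gp <- lam * M * (1 - M)
    W1 <- W1 + eta * (W2[sel, ] * gp * delta) %o% s
    W2[sel, ] <- W2[sel, ] + eta * delta * M
  }
  net$W1 <- W1; net$W2 <- W2
  net
}

#' Probability of walking implied by the two action Values
#'
#' `p_w = Q_w / (Q_w + Q_s)`; the uncertainty of a cue is read off this
#' probability. Both Values zero is a degenerate, untrained state and falls
#' back to maximal uncertainty `p_w = 0.5`.
#'
#' @param Q_w,Q_s non-negative action Values.
#' @return walk probability in `[0, 1]`.
#' @export
walk_probability <- function(Q_w, Q_s) {
  if (any(Q_w < 0) || any(Q_s < 0)) stop("action Values must be non-negative")
  tot <- Q_w + Q_s
  ifelse(tot > 0, Q_w / tot, 0.5)
}

#' Cue Risk from the walk probability
#'
#' `h = p_w (1 - p_w) / a_p` with `a_p = 0.25`, so the maximum Risk (at
#' `p_w = 0.5`) is exactly 1.
#'
#' @param p_w walk probability in `[0, 1]`.
#' @param a_p scaling constant (default 0.25).
#' @return Risk in `[0, 1]`.
#' @export
cognitive_risk <- function(p_w, a_p = 0.25) {
  if (any(p_w < 0 | p_w > 1)) stop("'p_w' must lie in [0, 1]")
  p_w * (1 - p_w) / a_p
}

#' Cue-level Values, Risk and Utility of a trained cognitive network
#'
#' For every cue: the action Values, walk probability, Risk, and the
#' risk-sensitive Utilities `U_i = Q_i - alpha * sign(Q_i) * h` for walking
#' and stopping. `U_w` is the cognitive evidence passed to the latency
#' accumulator when the cue is presented.
#'
#' @param net a trained [cognitive_net()].
#' @param alpha cognitive risk sensitivity `alpha^cog`.
#' @return a data.frame with one row per cue: `label`, `class`, `Q_w`,
#'   `Q_s`, `p_w`, `h`, `U_w`, `U_s`.
#' @export
cue_utilities <- function(net, alpha) {
  cues <- cue_table()
  out <- do.call(rbind, lapply(cues$label, function(lb) {
    Q <- cog_forward(net, encode_cue(lb))$Q
    p <- walk_probability(Q[["walk"]], Q[["stop"]])
    h <- cognitive_risk(p)
    data.frame(label = lb, Q_w = Q[["walk"]], Q_s = Q[["stop"]],
               p_w = p, h = h,
               U_w = utility(Q[["walk"]], h, alpha),
               U_s = utility(Q[["stop"]], h, alpha),
               stringsAsFactors = FALSE)
  }))
  out$class <- cues$class
  out
}

#' Serialize a cognitive network to a flat numeric table
#'
#' @param net a [cognitive_net()].
#' @param path file to write (tab-separated `name value` pairs).
#' @return `path`, invisibly.
#' @export
write_cognitive_net <- function(net, path) {
  vals <- c(stats::setNames(as.vector(net$W1),
                            sprintf("W1_%d_%d", row(net$W1), col(net$W1))),
            stats::setNames(as.vector(net$W2),
                            sprintf("W2_%d_%d", row(net$W2), col(net$W2))),
            lambda = net$lambda, A_Q = net$A_Q, eta = net$eta, tau = net$tau)
  utils::write.table(data.frame(name = names(vals), value = unname(vals)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cognitive network written by [write_cognitive_net()]
#' @param path file written by [write_cognitive_net()].
#' @return a `cognitive_net`.
#' @export
read_cognitive_net <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  v <- stats::setNames(tab$value, tab$name)
  net <- cognitive_net()
  net$W1 <- matrix(v[grep("^W1_", names(v))], 5, 9)
  net$W2 <- matrix(v[grep("^W2_", names(v))], 2, 5)
  net$lambda <- v[["lambda"]]; net$A_Q <- v[["A_Q"]]
  net$eta <- v[["eta"]]; net$tau <- v[["tau"]]
  net
}
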