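test_that("the cue inventory has 13 cues in the three classes", {
  cues <- cue_table()
  expect_equal(nrow(cues), 13)
  expect_equal(sum(cues$class == "simple"), 4)
  expect_equal(sum(cues$class == "congruent"), 3)
  expect_equal(sum(cues$class == "incongruent"), 6)
  expect_false(any(duplicated(cues$label)))
})

test_that("cue encoding sets one word bit and one colour bit", {
  s <- encode_cue("WALK(neutral)")
  expect_equal(which(s[1:5] == 1), 2) # WALK
  expect_equal(which(s[6:9] == 1), 4) # neutral
  expect_equal(which(encode_cue("RED(red)") == 1), c(3, 6))
  expect_equal(which(encode_cue("GREEN(blue)") == 1), c(4, 8))
  for (lb in cue_table()$label) expect_equal(sum(encode_cue(lb)), 2)
  expect_error(encode_cue("PURPLE(red)"), "unknown cue word")
  expect_error(encode_cue("nonsense"), "malformed")
})

test_that("cue-action mappings are counterbalanced over complex cues", {
  aw <- cue_actions("congruent_walk")
  as_ <- cue_actions("congruent_stop")
  expect_equal(unname(aw["RED(red)"]), "walk")
  expect_equal(unname(as_["RED(red)"]), "stop")
  expect_equal(unname(aw["RED(blue)"]), "stop")
  expect_equal(unname(aw["WALK(neutral)"]), "walk")
  expect_equal(unname(as_["WALK(neutral)"]), "walk") # simple cues fixed
})

test_that("the forward pass follows the two-layer sigmoid architecture", {
  set.seed(3)
  net <- cognitive_net()
  net$W1[] <- 0; net$W2[] <- 0
  out <- cog_forward(net, encode_cue("RED(red)"))
  expect_equal(out$M, rep(0.5, 5))
  expect_equal(unname(out$Q), rep(net$A_Q / 2, 2))
  # saturation under a steep sigmoid
  net$W2[1, ] <- 5
  steep <- net; steep$lambda <- 100
  expect_gt(cog_forward(steep, encode_cue("RED(red)"))$Q[["walk"]], 0.999)
})

test_that("training is reproducible, inert at zero learning rate, and
           suppressed by the dopamine clamp", {
  set.seed(11); n0 <- cognitive_net()
  set.seed(12); a <- train_cognitive(n0, n_simple = 100, n_mixed = 100)
  set.seed(12); b <- train_cognitive(n0, n_simple = 100, n_mixed = 100)
  expect_identical(a$W1, b$W1)

  frozen <- n0; frozen$eta <- 0
  set.seed(13); f <- train_cognitive(frozen, n_simple = 200, n_mixed = 200)
  expect_identical(f$W1, n0$W1)
  expect_identical(f$W2, n0$W2)

  set.seed(14)
  ctrl <- train_cognitive(n0)
  set.seed(14)
  clmp <- train_cognitive(n0, dopamine_condition("pd_off", 0.04))
  q_of <- function(net) {
    mean(sapply(cue_table()$label,
                function(lb) max(cog_forward(net, encode_cue(lb))$Q)))
  }
  expect_lt(q_of(clmp), q_of(ctrl))
})

test_that("control-condition training reaches the 95% accuracy criterion", {
  accs <- sapply(1:3, function(s) {
    set.seed(s)
    net <- train_cognitive(cognitive_net(), eval_every = 1600)
    tail(attr(net, "accuracy_trace")$accuracy, 1)
  })
  expect_true(all(accs >= 0.95))
})

test_that("walk probability and cue Risk follow their closed forms", {
  expect_equal(walk_probability(0.5, 0.5), 0.5)
  expect_equal(walk_probability(1, 0), 1)
  expect_equal(walk_probability(0.6, 0.2), 0.75)
  expect_equal(walk_probability(0, 0), 0.5) # degenerate untrained fallback
  expect_error(walk_probability(-0.1, 0.5), "non-negative")
  expect_equal(cognitive_risk(0.5), 1)
  expect_equal(cognitive_risk(c(0, 1)), c(0, 0))
  expect_equal(cognitive_risk(0.75), 0.75)
  expect_error(cognitive_risk(1.2), "\\[0, 1\\]")
})

test_that("cue utilities scale the risk penalty by alpha", {
  set.seed(21)
  net <- train_cognitive(cognitive_net())
  u0 <- cue_utilities(net, 0)
  u1 <- cue_utilities(net, 0.5)
  u2 <- cue_utilities(net, 1)
  expect_equal(u0$U_w, u0$Q_w)
  expect_true(all(u2$U_w <= u1$U_w)) # Q_w > 0 so larger alpha penalises more
  expect_equal(u1$U_w, u1$Q_w - 0.5 * sign(u1$Q_w) * u1$h)
})

test_that("complex cues carry more Risk than simple cues in every dopamine
           condition", {
  conds <- list(dopamine_condition("control"),
                dopamine_condition("pd_off", 0.15),
                dopamine_condition("pd_off", 0.04))
  cls <- cue_table()$class
  for (ci in seq_along(conds)) {
    h_s <- h_c <- 0
    for (s in 1:4) {
      set.seed(100 * ci + s)
      u <- cue_utilities(train_cognitive(cognitive_net(), conds[[ci]]), 1)
      h_s <- h_s + mean(u$h[cls == "simple"])
      h_c <- h_c + mean(u$h[cls != "simple"])
    }
    expect_gt(h_c, h_s)
  }
})

test_that("the red congruent cue carries more Risk than the green one for
           freezers (conflict with the primed red-stop association)", {
  fr <- dopamine_condition("pd_off", 0.04)
  hs <- sapply(1:20, function(s) {
    set.seed(s)
    u <- cue_utilities(train_cognitive(cognitive_net(), fr), 1)
    u$h[match(c("RED(red)", "GREEN(green)"), u$label)]
  })
  expect_gt(mean(hs[1, ]), mean(hs[2, ]))
})

test_that("freezers value walking less than non-freezers for the same
           congruent cue at equal Value and Risk", {
  expect_lt(utility(0.7, 0.8, 1), utility(0.7, 0.8, 0.5))
})

test_that("trained networks survive a serialization round trip", {
  set.seed(33)
  net <- train_cognitive(cognitive_net(), n_simple = 100, n_mixed = 100)
  f <- tempfile(fileext = ".tsv")
  write_cognitive_net(net, f)
  back <- read_cognitive_net(f)
  expect_equal(back$W1, net$W1)
  expect_equal(back$W2, net$W2)
  expect_equal(back$lambda, net$lambda)
  s <- encode_cue("BLUE(red)")
  expect_equal(cog_forward(back, s)$Q, cog_forward(net, s)$Q)
})
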