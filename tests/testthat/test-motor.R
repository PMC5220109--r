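test_that("motor Value and Risk are sigmoidal readouts of the view vector", {
  set.seed(1)
  cr <- motor_critic()
  cr$W_value[] <- 0; cr$W_risk[] <- 0
  phi <- rep(c(1, -1), 50)
  expect_equal(motor_value(cr, phi), cr$A_Q / 2)
  expect_equal(motor_risk(cr, phi), cr$A_h / 2)
  cr$W_value <- 1000 * phi
  expect_equal(motor_value(cr, phi), cr$A_Q) # saturation
  expect_error(motor_value(cr, phi[1:10]), "dimension")
})

test_that("motor TD error follows the discounted form and the group clamps", {
  ctl <- dopamine_condition("control")
  expect_equal(motor_td_error(0, 0.5, 0.5, 1, ctl), 0)
  expect_equal(motor_td_error(1, 0, 0.5, 0.9, ctl), 0.5)
  fz <- dopamine_condition("pd_off", 0.005)
  expect_equal(motor_td_error(1, 0, 0.5, 0.9, fz), 0.005)
  nf <- dopamine_condition("pd_off", 0.02)
  expect_equal(motor_td_error(1, 0, 0.5, 0.9, nf), 0.02)
})

test_that("critic updates move weights along the view vector", {
  set.seed(2)
  cr <- motor_critic()
  phi <- rep(1, 100)
  same <- update_critic(cr, 0, phi)
  expect_equal(same$W_value, cr$W_value)
  expect_equal(same$W_risk, cr$W_risk)
  cr$eta <- 0.1
  up <- update_critic(cr, 0.5, phi)
  expect_equal(up$W_value, cr$W_value + 0.05)
  expect_equal(up$W_risk, cr$W_risk + 0.025)
  # residual form shrinks risk weights when delta^2 < h
  res <- update_critic(cr, 0, phi, risk_residual = TRUE)
  expect_true(all(res$W_risk < cr$W_risk))
})

test_that("the Go/Explore/NoGo policy has the stated closed-form limits", {
  gp <- gen_params(A_E = 0)
  v <- c(0.3, 0.6)
  expect_equal(gen_policy(50, v, gp), gp$A_G * v, tolerance = 1e-12)
  expect_equal(gen_policy(-50, v, gp), -gp$A_N * v, tolerance = 1e-12)
  expect_equal(gen_policy(0, v, gp), c(0, 0)) # Go and NoGo cancel
  # at zero gradient exploration is at full strength
  gp2 <- gen_params(A_E = 0.7)
  chi <- c(1.5, -2)
  expect_equal(gen_policy(0, v, gp2, chi = chi), 0.7 * chi)
  # deterministic when exploration is off
  expect_identical(gen_policy(0.2, v, gp), gen_policy(0.2, v, gp))
})

test_that("the forward-velocity clamp prevents backward motion", {
  gp <- gen_params(lambda_vel = 1)
  expect_equal(clamp_forward(c(0.4, 0), gp), c(0.4, 0.5))
  out <- clamp_forward(c(-3, -10), gp)
  expect_equal(out[1], -3) # lateral untouched
  expect_gt(out[2], 0)
  expect_equal(out[2], 1 / (1 + exp(10)))
  set.seed(3)
  for (i in 1:100) {
    expect_gt(clamp_forward(rnorm(2, sd = 5), gen_params())[2], 0)
  }
})

test_that("a trained control agent passes doorways reliably", {
  set.seed(7)
  corr <- build_corridor(300)
  cr <- motor_critic()
  out <- train_motor(cr, gen_params(), corr)
  expect_gt(mean(out$segments$passed[251:300]), 0.8)
  expect_true(all(out$segments$passed | out$segments$capped))
})

test_that("a rewarded doorway raises Value along the approach path", {
  set.seed(8)
  corr <- build_corridor(100)
  cr0 <- motor_critic()
  trained <- train_motor(cr0, gen_params(), corr)$critic
  probe <- function(cr, d) {
    ag <- agent_state(c(0, 4 - d))
    motor_value(cr, compute_view_vector(ag, tiny_corridor(1, 3)))
  }
  d <- 1.0
  expect_gt(probe(trained, d), probe(cr0, d))
})

test_that("trained motor Risk concentrates near the doorway, where
           collisions happen", {
  for (s in 1:6) {
    set.seed(400 + s)
    cr <- train_motor(motor_critic(), gen_params(), build_corridor(300))$critic
    h_of <- function(d) {
      motor_risk(cr, compute_view_vector(agent_state(c(0, 4 - d)),
                                         tiny_corridor(1, 2)))
    }
    expect_gt(h_of(0.4), h_of(3.0))
  }
})

test_that("compiled and reference navigation engines are interchangeable", {
  set.seed(10); corr <- build_corridor(12)
  set.seed(11); cr <- motor_critic()
  sch <- cue_schedule(corr, cue_table()$label, method = "blocks",
                      block_length = 2)
  uw <- stats::setNames(rep(c(-4, 0.4), length.out = 13), cue_table()$label)
  set.seed(12)
  a <- navigate(cr, gen_params(), corr, dopamine_condition("pd_off", 0.02),
                alpha_mot = 0.3, schedule = sch, cue_uw = uw,
                record_steps = TRUE, engine = "cpp")
  set.seed(12)
  b <- navigate(cr, gen_params(), corr, dopamine_condition("pd_off", 0.02),
                alpha_mot = 0.3, schedule = sch, cue_uw = uw,
                record_steps = TRUE, engine = "r")
  expect_equal(a$critic$W_value, b$critic$W_value, tolerance = 1e-12)
  expect_equal(a$critic$W_risk, b$critic$W_risk, tolerance = 1e-12)
  expect_equal(a$footsteps, b$footsteps, tolerance = 1e-12)
  expect_equal(a$segments, b$segments)
  expect_equal(a$steps, b$steps, tolerance = 1e-12)
})

test_that("compiled and reference cognitive training engines are
           interchangeable", {
  set.seed(20); n0 <- cognitive_net()
  set.seed(21)
  a <- train_cognitive(n0, dopamine_condition("pd_off", 0.08),
                       n_simple = 300, n_mixed = 300, engine = "cpp")
  set.seed(21)
  b <- train_cognitive(n0, dopamine_condition("pd_off", 0.08),
                       n_simple = 300, n_mixed = 300, engine = "r")
  expect_equal(a$W1, b$W1, tolerance = 1e-12)
  expect_equal(a$W2, b$W2, tolerance = 1e-12)
  expect_equal(attr(a, "accuracy_trace"), attr(b, "accuracy_trace"),
               tolerance = 1e-12)
})
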