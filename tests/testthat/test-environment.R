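test_that("corridor geometry follows the task layout", {
  set.seed(1)
  corr <- build_corridor(300)
  expect_equal(nrow(corr), 300)
  expect_equal(corr$center_y, seq(4, 1200, by = 4))
  expect_true(all(corr$width %in% c(2, 3)))
  expect_equal(attr(corr, "height"), 1.6)
  set.seed(9); a <- build_corridor(10)
  set.seed(9); b <- build_corridor(10)
  expect_identical(a$width, b$width)
  expect_equal(build_corridor(1, narrow_fraction = 0)$width, 3)
  expect_error(build_corridor(5, spacing = 0), "positive")
})

test_that("view vector is empty past the last doorway and symmetric on the
           midline", {
  corr <- tiny_corridor()
  far <- agent_state(c(0, 100))
  expect_equal(compute_view_vector(far, corr), rep(-1, 100))

  mid <- agent_state(c(0, 1.5)) # heading straight down-track
  phi <- compute_view_vector(mid, corr)
  hbits <- phi[1:50]
  expect_equal(hbits, rev(hbits)) # symmetric about the field centre
  expect_equal(phi, view_vector_oracle(mid, corr))
})

test_that("horizontal code is scale-invariant while the height code
           disambiguates distance", {
  narrow <- tiny_corridor(1, 2)
  d1 <- 2
  ag1 <- agent_state(c(0, narrow$center_y[1] - d1))
  wide <- tiny_corridor(1, 3)
  ag2 <- agent_state(c(0, wide$center_y[1] - 1.5 * d1))
  phi1 <- compute_view_vector(ag1, narrow)
  phi2 <- compute_view_vector(ag2, wide)
  expect_equal(sum(phi1[1:50] == 1), sum(phi2[1:50] == 1))
  expect_gt(sum(phi1[51:100] == 1), sum(phi2[51:100] == 1))
})

test_that("view vector matches the ray-intersection oracle on random poses", {
  set.seed(42)
  corr <- build_corridor(10)
  for (i in 1:300) {
    pos <- c(runif(1, -1, 1), runif(1, 0, 41))
    ang <- runif(1, -pi / 3, pi / 3)
    ag <- agent_state(pos, heading = c(sin(ang), cos(ang)),
                      velocity = c(sin(ang), cos(ang)))
    expect_identical(compute_view_vector(ag, corr),
                     view_vector_oracle(ag, corr))
  }
})

test_that("horizontal on-bits grow as the agent approaches on the midline", {
  corr <- tiny_corridor(1, 3)
  counts <- sapply(seq(3.8, 0.3, by = -0.25), function(d) {
    sum(compute_view_vector(agent_state(c(0, 4 - d)), corr)[1:50] == 1)
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("stepping the environment scores passage and collision correctly", {
  corr <- tiny_corridor(1, 3)
  ag <- agent_state(c(0, 3.5))
  out <- step_environment(ag, c(0, 1), corr)
  expect_equal(out$event, "passed")
  expect_equal(out$reward, 1)

  narrow <- tiny_corridor(1, 2)
  ag2 <- agent_state(c(1, 3.5)) # lateral clamp keeps |x| <= 1
  out2 <- step_environment(ag2, c(0.2, 1), narrow)
  expect_equal(out2$event, "collided")
  expect_equal(out2$reward, -1)
  expect_equal(out2$agent$position, ag2$position) # bounced back

  out3 <- step_environment(ag, c(0, 0.2), corr)
  expect_equal(out3$event, "none")
  expect_equal(out3$reward, 0)
})

test_that("cues fire exactly once when their onset is crossed", {
  corr <- tiny_corridor(2, 3)
  sch <- cue_schedule(corr, c("WALK(neutral)", "STOP(red)"),
                      method = "blocks", block_length = 1)
  expect_equal(sch$onset_y, corr$center_y - 2)
  ag <- agent_state(c(0, 1.0))
  expect_true(is.na(active_cue(ag, sch, 0.5)))
  ag2 <- agent_state(c(0, 2.3))
  expect_equal(active_cue(ag2, sch, 1.8), "WALK(neutral)")
  expect_true(is.na(active_cue(agent_state(c(0, 2.6)), sch, 2.3)))
})

test_that("cue schedules are reproducible and serializable", {
  corr <- tiny_corridor(6)
  set.seed(5); a <- cue_schedule(corr, cue_table()$label)
  set.seed(5); b <- cue_schedule(corr, cue_table()$label)
  expect_identical(a, b)
  tab <- corridor_table(corr, a)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$cue, a$cue)
})

test_that("every segment of a navigation run ends in exactly one passage or
           cap", {
  set.seed(31)
  corr <- build_corridor(15)
  cr <- motor_critic()
  out <- navigate(cr, gen_params(), corr)
  expect_true(all(out$segments$passed | out$segments$capped))
  expect_true(all(out$segments$steps >= 1))
})
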