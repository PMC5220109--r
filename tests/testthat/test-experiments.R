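test_that("group parameter sets carry the published regime values", {
  fz <- group_params("pd_freezer", "matar")
  expect_equal(fz$motor$condition$delta_star, 0.005)
  expect_equal(fz$motor$sigma_E, 0.2)
  expect_equal(fz$motor$alpha, 0.1)
  expect_equal(fz$cognitive$condition$delta_star, 0.04)
  expect_equal(fz$cognitive$alpha, 1)

  nf <- group_params("pd_nonfreezer", "matar")
  expect_equal(nf$motor$condition$delta_star, 0.02)
  expect_equal(nf$cognitive$condition$delta_star, 0.15)
  expect_equal(nf$cognitive$alpha, 0.5)

  ct <- group_params("control", "matar")
  expect_equal(ct$motor$condition$label, "control")
  expect_equal(ct$cognitive$alpha, 0.1)

  so <- group_params("pd_freezer", "shine", "off")
  expect_equal(so$motor$condition$delta_star, 0.003)
  expect_equal(so$motor$sigma_E, 0.1)
  expect_equal(so$cognitive$condition$delta_star, 0.08)
  expect_equal(so$cognitive$alpha, 7)

  sn <- group_params("pd_freezer", "shine", "on")
  expect_equal(sn$cognitive$alpha, 1)
  expect_equal(sn$motor$condition$delta_med, 0.001)
  expect_equal(sn$cognitive$condition$delta_med, 0.001)
  expect_equal(sn$motor$condition$label, "pd_on")

  expect_error(group_params("control", "shine"), "no control group")
  expect_error(group_params("control", "matar", "on"), "OFF-medication")
})

test_that("a small conflict-protocol run emits every metric table and is
           seed-reproducible", {
  res <- run_matar_protocol(n_subjects = 2, seed = 7)
  expect_s3_class(res, "fog_experiment")
  m <- res$metrics
  expect_setequal(unique(m$metric),
                  c("modal_latency", "arrests", "mfsl_cue", "mfsl_doorway"))
  expect_setequal(unique(m$group),
                  c("control", "pd_nonfreezer", "pd_freezer"))
  expect_equal(sum(m$metric == "modal_latency"), 6)
  res2 <- run_matar_protocol(n_subjects = 2, seed = 7)
  expect_identical(res$metrics, res2$metrics)
  res3 <- run_matar_protocol(n_subjects = 2, seed = 8)
  expect_false(identical(res$metrics$value, res3$metrics$value))
})

test_that("a small load-protocol run crosses groups, loads and medication", {
  res <- run_shine_protocol(n_subjects = 2, seed = 7)
  a <- res$metrics[res$metrics$metric == "arrests", ]
  expect_setequal(unique(a$condition), c("low", "high"))
  expect_setequal(unique(a$medication), c("off", "on"))
  expect_equal(nrow(a), 2 * 2 * 2 * 2) # group x subject x med x load
})

test_that("per-subject metrics do not depend on how many subjects run", {
  big <- run_matar_protocol(n_subjects = 3, seed = 5,
                            groups = "pd_freezer")$metrics
  small <- run_matar_protocol(n_subjects = 2, seed = 5,
                              groups = "pd_freezer")$metrics
  shared <- intersect(unique(big$subject), unique(small$subject))
  expect_length(shared, 2)
  for (sid in shared) {
    expect_equal(big$value[big$subject == sid],
                 small$value[small$subject == sid])
  }
})

test_that("arrest snapshots average the logged arrest instants exactly", {
  fake <- list(
    design = "matar",
    metrics = data.frame(subject = c("a", "b"),
                         group = c("g1", "g2"),
                         medication = "off", metric = "arrests",
                         condition = NA, value = c(1, 1)),
    arrest_events = data.frame(subject = c("a", "a", "b"),
                               group = c("g1", "g1", "g2"),
                               medication = "off",
                               u_wcog = c(-1, -3, -0.5),
                               u_mot = c(0.2, 0.4, 0.1),
                               cue = "RED(red)"))
  snap <- arrest_utility_snapshot(fake)
  expect_equal(snap$mean_u_wcog[snap$group == "g1"], -2)
  expect_equal(snap$mean_u_mot[snap$group == "g1"], 0.3)
  expect_equal(snap$n_events[snap$group == "g2"], 1L)

  none <- fake
  none$arrest_events <- NULL
  expect_warning(s2 <- arrest_utility_snapshot(none), "without logged")
  expect_true(all(is.na(s2$mean_u_wcog)))
})

test_that("repeated-measures statistics flag injected effects and not null
           ones", {
  set.seed(91)
  null_d <- data.frame(subject = rep(sprintf("s%02d", 1:40), each = 2),
                       group = rep(c("g1", "g2"), each = 40),
                       condition = rep(c("c1", "c2"), 40),
                       value = rnorm(80))
  st <- run_statistics(null_d, within = "condition")
  expect_true(all(st$p_bonferroni[st$effect == "group"] > 0.05))

  eff <- null_d
  eff$value[eff$group == "g2"] <- eff$value[eff$group == "g2"] + 3
  st2 <- run_statistics(eff, within = "condition")
  expect_lt(st2$p_bonferroni[st2$effect == "group"], 0.05)

  flat <- null_d; flat$value <- 2
  st3 <- run_statistics(flat, within = "condition")
  expect_true(all(st3$p == 1)) # degenerate: no variance, no evidence

  bad <- null_d[-1, ]
  expect_error(run_statistics(bad, within = "condition"), "unbalanced")
})

test_that("planned contrasts are Bonferroni-corrected Welch tests", {
  set.seed(92)
  d <- data.frame(group = rep(c("a", "b"), each = 30),
                  value = c(rnorm(30), rnorm(30, mean = 2)))
  out <- planned_t_tests(d, list(c("b", "a")), alternative = "greater")
  expect_lt(out$p, 0.001)
  expect_equal(out$p_bonferroni, out$p) # single contrast: no correction
  two <- planned_t_tests(d, list(c("b", "a"), c("a", "b")))
  expect_equal(two$p_bonferroni, pmin(two$p * 2, 1))
})

test_that("grid-search calibration recovers a planted optimum and respects
           its budget", {
  obj <- function(p, seed) -(p$x - 0.3)^2 - (p$y - 2)^2
  out <- calibrate(list(x = c(0.1, 0.3, 0.5), y = 1:3), obj)
  expect_equal(out$best$x, 0.3)
  expect_equal(out$best$y, 2)
  expect_equal(nrow(out$log), 9)
  one <- calibrate(list(x = c(0.1, 0.3), y = 1:2), obj, budget = 1, seed = 4)
  expect_equal(nrow(one$log), 1)
  obj1 <- function(p, seed) -(p$x - 0.3)^2
  grid <- list(x = seq(0, 1, by = 0.1))
  a <- calibrate(grid, obj1, budget = 3, seed = 9)
  b <- calibrate(grid, obj1, budget = 3, seed = 9)
  expect_equal(nrow(a$log), 3)
  expect_identical(a$log, b$log) # same seed, same search trajectory
})

test_that("a minimal sensitivity sweep normalises to its grid maximum", {
  sw <- sensitivity_sweep(alpha_mot = 0.1, alpha_cog = 7,
                          delta_med = c(0, 0.001), n_subjects = 1,
                          seed = 3, n_eval = 8)
  expect_equal(nrow(sw$grid), 1)
  expect_equal(sw$grid$normalised, 1)
  expect_equal(nrow(sw$med), 4) # two cases x two medication levels
  expect_true(all(sw$med$normalised <= 1))
})
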