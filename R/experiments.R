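#' Parameter set of a simulated subject group
#'
#' Bundles the dopamine conditions, risk sensitivities and exploration
#' width that distinguish healthy controls, PD non-freezers and PD
#' freezers, for the two published task regimes. The motor and cognitive
#' loops carry separate TD-error ceilings; the motor ceiling is the
#' stronger (putamen-dominant dopamine loss), and freezers have the
#' strongest clamps, reduced motor risk sensitivity and exploration, and
#' raised cognitive risk sensitivity. Medication (`"on"`, Shine regime)
#' adds 0.001 to both loops' TD errors and drops the freezer cognitive
#' risk sensitivity back to 1.
#'
#' @param group `"control"`, `"pd_nonfreezer"` or `"pd_freezer"`.
#' @param regime `"matar"` (three groups, OFF medication) or `"shine"`
#'   (two PD groups, OFF and ON).
#' @param medication `"off"` or `"on"` (Shine regime only).
#' @param b baseline drive of the latency accumulator (default 1.3).
#' @param n_train_segments motor pre-training doorways (default 300).
#' @return an object of class `group_params`: a list with entries `label`,
#'   `regime`, `medication`, `cognitive` (`condition`, `alpha`), `motor`
#'   (`condition`, `alpha`, `sigma_E`), `b`, `n_train_segments`.
#' @export
group_params <- function(group = c("control", "pd_nonfreezer", "pd_freezer"),
                         regime = c("matar", "shine"),
                         medication = c("off", "on"),
                         b = 1.3, n_train_segments = 300) {
  group <- match.arg(group)
  regime <- match.arg(regime)
  medication <- match.arg(medication)
  if (regime == "matar" && medication == "on")
    stop("the Matar regime is OFF-medication only")
  if (regime == "shine" && group == "control")
    stop("the Shine regime has no control group")
  tab <- list(
    matar = list(
      control       = list(ds_mot = NA, sigma_E = 0.5, a_mot = 0.5,
                           ds_cog = NA, a_cog = 0.1),
      pd_nonfreezer = list(ds_mot = 0.02, sigma_E = 0.5, a_mot = 0.3,
                           ds_cog = 0.15, a_cog = 0.5),
      pd_freezer    = list(ds_mot = 0.005, sigma_E = 0.2, a_mot = 0.1,
                           ds_cog = 0.04, a_cog = 1)),
    shine = list(
      pd_nonfreezer = list(ds_mot = 0.02, sigma_E = 0.5, a_mot = 0.3,
                           ds_cog = 0.15, a_cog = 1, a_cog_on = 1),
      pd_freezer    = list(ds_mot = 0.003, sigma_E = 0.1, a_mot = 0.1,
                           ds_cog = 0.08, a_cog = 7, a_cog_on = 1)))
  p <- tab[[regime]][[group]]
  dmed <- if (regime == "shine" && medication == "on") 0.001 else 0
  mk_cond <- function(ds) {
    if (is.na(ds)) dopamine_condition("control")
    else if (dmed > 0) dopamine_condition("pd_on", ds, dmed)
    else dopamine_condition("pd_off", ds)
  }
  a_cog <- if (regime == "shine" && medication == "on") p$a_cog_on else p$a_cog
  structure(list(
    label = group, regime = regime, medication = medication,
    cognitive = list(condition = mk_cond(p$ds_cog), alpha = a_cog),
    motor = list(condition = mk_cond(p$ds_mot), alpha = p$a_mot,
                 sigma_E = p$sigma_E),
    b = b, n_train_segments = n_train_segments),
    class = "group_params")
}

# deterministic per-subject seed derived from the master seed
.subject_seed <- function(master, group_idx, subject, salt = 0) {
  ((master %% 1000000) * 1009 + group_idx * 101 + subject * 13 +
     salt * 7919) %% 2147483646 + 1
}

# train one subject's cognitive net and motor critic under its group params
.train_subject <- function(params, mapping) {
  net <- train_cognitive(cognitive_net(), params$cognitive$condition,
                         mapping = mapping,
                         eval_every = 1600)
  gen <- gen_params(sigma_E = params$motor$sigma_E)
  corr <- build_corridor(params$n_train_segments)
  tr <- navigate(motor_critic(), gen, corr,
                 condition = params$motor$condition,
                 alpha_mot = params$motor$alpha)
  list(net = net, critic = tr$critic, gen = gen,
       train_segments = tr$segments)
}

# one measured corridor run with cues; returns footsteps + corridor
.eval_subject <- function(trained, params, n_eval, cues, method,
                          block_length = 10) {
  corr <- build_corridor(n_eval)
  sch <- cue_schedule(corr, cues, method = method,
                      block_length = block_length)
  cu <- cue_utilities(trained$net, params$cognitive$alpha)
  uw <- stats::setNames(cu$U_w, cu$label)
  ev <- navigate(trained$critic, trained$gen, corr,
                 condition = params$motor$condition,
                 alpha_mot = params$motor$alpha,
                 schedule = sch, cue_uw = uw, b = params$b)
  list(footsteps = ev$footsteps, segments = ev$segments, corridor = corr,
       schedule = sch, cue_utilities = cu)
}

#' Per-subject gait metrics from a measured corridor run
#'
#' Computes the modal latency, motor-arrest count, per-cue maximum scaled
#' footstep latency (MFSL: the largest of the first three post-cue
#' latencies divided by the modal latency, averaged over presentations of
#' the cue), per-doorway-width scaled latency (maximum latency completed
#' within 0.1 length units of a doorway plane, divided by the modal
#' latency, averaged over doorways of that width), and the utilities at
#' cue-triggered arrest instants.
#'
#' @param footsteps the `footsteps` table of a [navigate()] run.
#' @param corridor the corridor the run used.
#' @param window doorway window half-width (default 0.1).
#' @return list with `modal`, `arrests`, `mfsl_cue` (data.frame
#'   `cue`, `value`), `mfsl_doorway` (data.frame `type`, `value`),
#'   `arrest_events` (data.frame `u_wcog`, `u_mot`, `cue`).
#' @export
gait_summary <- function(footsteps, corridor, window = 0.1) {
  fs <- footsteps
  modal <- modal_latency(fs$latency, fs$capped)
  arrests <- count_motor_arrests(fs$latency, modal, fs$capped)
  pc <- fs[!is.na(fs$cue) & fs$post_cue >= 1 & fs$post_cue <= 3, ]
  mf <- if (nrow(pc)) {
    per_pres <- tapply(pc$latency, pc$cue_seg, max)
    cue_of <- tapply(pc$cue, pc$cue_seg, `[`, 1)
    agg <- tapply(as.numeric(per_pres) / modal, as.character(cue_of), mean)
    data.frame(cue = names(agg), value = as.numeric(agg),
               stringsAsFactors = FALSE)
  } else data.frame(cue = character(0), value = numeric(0))
  dl <- doorway_latency(fs[, c("latency", "y")], corridor, window)
  dl$scaled <- dl$max_latency / modal
  dw <- stats::aggregate(scaled ~ width, dl, mean)
  dw <- data.frame(type = ifelse(dw$width <= 2, "narrow", "wide"),
                   width = dw$width, value = dw$scaled,
                   stringsAsFactors = FALSE)
  arr <- fs[(fs$latency > 2 * modal | fs$capped) & fs$cued, ]
  list(modal = modal, arrests = arrests, mfsl_cue = mf, mfsl_doorway = dw,
       arrest_events = data.frame(u_wcog = arr$u_wcog, u_mot = arr$u_mot,
                                  cue = arr$cue, stringsAsFactors = FALSE))
}

.metric_rows <- function(subject, group, medication, metric, condition,
                         value) {
  if (length(value) == 0L) return(NULL)
  data.frame(subject = subject, group = group, medication = medication,
             metric = metric, condition = condition, value = value,
             stringsAsFactors = FALSE)
}

#' Run the conflict-cue (Matar-style) protocol
#'
#' Simulates `n_subjects` independent subjects per group (controls, PD
#' non-freezers, PD freezers, OFF medication): each subject trains its
#' cognitive network on the two-phase cue protocol (congruent cues mapped
#' to walk, incongruent to stop) and its motor critic on a cue-free
#' corridor, then walks a measured corridor in which every doorway carries
#' one of the 13 cues (balanced schedule, presented 2 length units before
#' the doorway). Emits modal latency, per-cue MFSL, per-width doorway
#' latency, arrest counts, and arrest-instant utilities.
#'
#' @param n_subjects subjects per group (default 50).
#' @param seed master seed; every subject's RNG stream is derived from it.
#' @param n_eval measured doorways per subject (default 52: each cue 4
#'   times).
#' @param groups character vector of groups to include.
#' @return an object of class `fog_experiment`: list with `design`,
#'   `metrics` (tidy data.frame: `subject`, `group`, `medication`,
#'   `metric`, `condition`, `value`), `arrest_events`, `cue_utilities`
#'   (per-subject cue table), and the call parameters.
#' @export
run_matar_protocol <- function(n_subjects = 50, seed = 1, n_eval = 52,
                               groups = c("control", "pd_nonfreezer",
                                          "pd_freezer")) {
  cues <- cue_table()$label
  metrics <- list(); arrests_ev <- list(); cu_all <- list()
  for (gi in seq_along(groups)) {
    params <- group_params(groups[gi], "matar")
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("%s_%02d", groups[gi], s)
      set.seed(.subject_seed(seed, gi, s))
      tr <- .train_subject(params, "congruent_walk")
      ev <- .eval_subject(tr, params, n_eval, cues, "balanced")
      gs <- gait_summary(ev$footsteps, ev$corridor)
      metrics[[length(metrics) + 1L]] <- rbind(
        .metric_rows(sid, groups[gi], "off", "modal_latency", NA, gs$modal),
        .metric_rows(sid, groups[gi], "off", "arrests", NA, gs$arrests),
        .metric_rows(sid, groups[gi], "off", "mfsl_cue", gs$mfsl_cue$cue,
                     gs$mfsl_cue$value),
        .metric_rows(sid, groups[gi], "off", "mfsl_doorway",
                     gs$mfsl_doorway$type, gs$mfsl_doorway$value))
      if (nrow(gs$arrest_events))
        arrests_ev[[length(arrests_ev) + 1L]] <-
          data.frame(subject = sid, group = groups[gi], medication = "off",
                     gs$arrest_events, stringsAsFactors = FALSE)
      cu <- ev$cue_utilities
      cu_all[[length(cu_all) + 1L]] <-
        data.frame(subject = sid, group = groups[gi], medication = "off",
                   cu, stringsAsFactors = FALSE)
    }
  }
  structure(list(design = "matar",
                 metrics = do.call(rbind, metrics),
                 arrest_events = if (length(arrests_ev))
                   do.call(rbind, arrests_ev) else NULL,
                 cue_utilities = do.call(rbind, cu_all),
                 n_subjects = n_subjects, seed = seed, n_eval = n_eval),
            class = "fog_experiment")
}

#' Run the cognitive-load (Shine-style) protocol
#'
#' Simulates PD non-freezers and freezers, each subject measured both OFF
#' and ON medication (same subject seed, so the two conditions share
#' initial weights and corridors). Subjects are counterbalanced: half map
#' congruent cues to walk and incongruent to stop, half the reverse. The
#' measured corridor alternates blocks of `block_length` low-load (simple)
#' and high-load (complex Stroop) cues; motor arrests are counted per
#' load level against the subject's overall modal latency.
#'
#' @param n_subjects subjects per group (default 50).
#' @param seed master seed.
#' @param n_blocks number of blocks per load level (default 2).
#' @param block_length doorways per block (default 10).
#' @return a `fog_experiment` (see [run_matar_protocol()]); metric
#'   `arrests` carries the load level (`"low"`/`"high"`) in `condition`.
#' @export
run_shine_protocol <- function(n_subjects = 50, seed = 1, n_blocks = 2,
                               block_length = 10) {
  cues <- cue_table()
  simple <- cues$label[cues$class == "simple"]
  complex_ <- cues$label[cues$class != "simple"]
  groups <- c("pd_nonfreezer", "pd_freezer")
  n_eval <- 2 * n_blocks * block_length
  load_of_block <- rep(c("low", "high"), n_blocks)
  metrics <- list(); arrests_ev <- list()
  for (gi in seq_along(groups)) {
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("%s_%02d", groups[gi], s)
      mapping <- if (s %% 2 == 0) "congruent_walk" else "congruent_stop"
      for (med in c("off", "on")) {
        params <- group_params(groups[gi], "shine", med)
        set.seed(.subject_seed(seed, gi, s))
        tr <- .train_subject(params, mapping)
        corr <- build_corridor(n_eval)
        block_id <- rep(seq_len(2 * n_blocks), each = block_length)
        labs <- unlist(lapply(seq_len(2 * n_blocks), function(bl) {
          pool <- if (load_of_block[bl] == "low") simple else complex_
          sample(pool, block_length, replace = TRUE)
        }))
        sch <- structure(data.frame(doorway = corr$doorway, cue = labs,
                                    onset_y = corr$center_y - 2,
                                    stringsAsFactors = FALSE),
                         class = c("cue_schedule", "data.frame"))
        cu <- cue_utilities(tr$net, params$cognitive$alpha)
        uw <- stats::setNames(cu$U_w, cu$label)
        ev <- navigate(tr$critic, tr$gen, corr,
                       condition = params$motor$condition,
                       alpha_mot = params$motor$alpha,
                       schedule = sch, cue_uw = uw, b = params$b)
        fs <- ev$footsteps
        modal <- modal_latency(fs$latency, fs$capped)
        seg_load <- load_of_block[block_id]
        for (ld in c("low", "high")) {
          sel <- fs$segment >= 1 & seg_load[fs$segment] == ld
          metrics[[length(metrics) + 1L]] <- .metric_rows(
            sid, groups[gi], med, "arrests", ld,
            count_motor_arrests(fs$latency[sel], modal, fs$capped[sel]))
        }
        metrics[[length(metrics) + 1L]] <-
          .metric_rows(sid, groups[gi], med, "modal_latency", NA, modal)
        arr <- fs[(fs$latency > 2 * modal | fs$capped) & fs$cued, ]
        if (nrow(arr))
          arrests_ev[[length(arrests_ev) + 1L]] <-
            data.frame(subject = sid, group = groups[gi], medication = med,
                       u_wcog = arr$u_wcog, u_mot = arr$u_mot,
                       cue = arr$cue, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(design = "shine",
                 metrics = do.call(rbind, metrics),
                 arrest_events = if (length(arrests_ev))
                   do.call(rbind, arrests_ev) else NULL,
                 n_subjects = n_subjects, seed = seed,
                 n_blocks = n_blocks, block_length = block_length),
            class = "fog_experiment")
}

#' Mean utilities at cue-triggered motor arrests
#'
#' Extracts the instants at which a motor arrest coincided with a pending
#' word cue and averages the cognitive walk Utility and the motor Utility
#' per group (and medication state, when present). The cognitive
#' contribution at freezes is expected to be lower (more negative) in
#' freezers than in non-freezers.
#'
#' @param result a `fog_experiment`.
#' @return data.frame `group`, `medication`, `n_events`, `mean_u_wcog`,
#'   `mean_u_mot`; groups without any logged arrest get `NA` means (with
#'   a warning).
#' @export
arrest_utility_snapshot <- function(result) {
  ev <- result$arrest_events
  groups <- unique(result$metrics[, c("group", "medication")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    e <- if (is.null(ev)) NULL
         else ev[ev$group == groups$group[i] &
                   ev$medication == groups$medication[i], ]
    if (is.null(e) || nrow(e) == 0L)
      data.frame(group = groups$group[i], medication = groups$medication[i],
                 n_events = 0L, mean_u_wcog = NA_real_,
                 mean_u_mot = NA_real_, stringsAsFactors = FALSE)
    else
      data.frame(group = groups$group[i], medication = groups$medication[i],
                 n_events = nrow(e), mean_u_wcog = mean(e$u_wcog),
                 mean_u_mot = mean(e$u_mot), stringsAsFactors = FALSE)
  }))
  if (any(out$n_events == 0L))
    warning("groups without logged cue-triggered arrests: ",
            paste(out$group[out$n_events == 0L], collapse = ", "))
  out
}

#' Sensitivity of motor arrests to risk sensitivities and medication
#'
#' Sweeps the freezer (Shine regime, OFF) parameter set over a grid of
#' motor and cognitive risk sensitivities, counting motor arrests in the
#' measured run and normalising by the grid maximum; and sweeps the
#' medication term for two printed regimes -- the dopamine-responsive case
#' (`alpha_mot = 0.1, alpha_cog = 7`) and the dopamine-insensitive case
#' (`alpha_mot = 7, alpha_cog = 7`).
#'
#' @param alpha_mot,alpha_cog grids of risk sensitivities.
#' @param delta_med grid of medication terms (applied to both loops).
#' @param n_subjects subjects averaged per cell (default 20).
#' @param seed master seed.
#' @param n_eval measured doorways per subject (default 40, high-load
#'   cues).
#' @return list with `grid` (data.frame `alpha_mot`, `alpha_cog`,
#'   `arrests`, `normalised`) and `med` (data.frame `case`, `alpha_mot`,
#'   `alpha_cog`, `delta_med`, `arrests`, `normalised`).
#' @export
sensitivity_sweep <- function(alpha_mot = c(0.1, 1, 7),
                              alpha_cog = c(0.1, 1, 7),
                              delta_med = c(0, 0.001, 0.002, 0.005, 0.01),
                              n_subjects = 20, seed = 1, n_eval = 40) {
  base <- group_params("pd_freezer", "shine", "off")
  cues <- cue_table()
  complex_ <- cues$label[cues$class != "simple"]
  eval_cell <- function(params, salt) {
    arr <- 0
    for (s in seq_len(n_subjects)) {
      set.seed(.subject_seed(seed, 1, s, salt))
      tr <- .train_subject(params, "congruent_walk")
      ev <- .eval_subject(tr, params, n_eval, complex_, "uniform")
      fs <- ev$footsteps
      modal <- modal_latency(fs$latency, fs$capped)
      arr <- arr + count_motor_arrests(fs$latency, modal, fs$capped)
    }
    arr / n_subjects
  }
  grid <- expand.grid(alpha_mot = alpha_mot, alpha_cog = alpha_cog)
  grid$arrests <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- base
    p$motor$alpha <- grid$alpha_mot[i]
    p$cognitive$alpha <- grid$alpha_cog[i]
    grid$arrests[i] <- eval_cell(p, salt = 0)
  }
  mx <- max(grid$arrests)
  grid$normalised <- if (mx > 0) grid$arrests / mx else grid$arrests

  cases <- data.frame(case = c(1, 2), alpha_mot = c(0.1, 7),
                      alpha_cog = c(7, 7))
  med <- do.call(rbind, lapply(seq_len(nrow(cases)), function(ci) {
    do.call(rbind, lapply(delta_med, function(dm) {
      p <- base
      p$motor$alpha <- cases$alpha_mot[ci]
      p$cognitive$alpha <- cases$alpha_cog[ci]
      if (dm > 0) {
        p$motor$condition <- dopamine_condition(
          "pd_on", p$motor$condition$delta_star, dm)
        p$cognitive$condition <- dopamine_condition(
          "pd_on", p$cognitive$condition$delta_star, dm)
      }
      data.frame(case = cases$case[ci], alpha_mot = cases$alpha_mot[ci],
                 alpha_cog = cases$alpha_cog[ci], delta_med = dm,
                 arrests = eval_cell(p, salt = ci))
    }))
  }))
  mxm <- max(med$arrests)
  med$normalised <- if (mxm > 0) med$arrests / mxm else med$arrests
  list(grid = grid, med = med)
}

#' Repeated-measures ANOVA over a tidy metric table
#'
#' Fits `value ~ between * within + Error(subject / within)` via
#' [stats::aov()] (or a one-way between-subject ANOVA when no within
#' factor applies) and returns the F tests with Bonferroni-corrected
#' p-values. Degenerate tables (zero residual variance, e.g. an identical
#' modal latency in every subject) yield `p = 1` rather than an error:
#' there is no evidence of any effect.
#'
#' @param data tidy data.frame with columns `subject`, `value`, the
#'   `between` column and optionally the `within` column.
#' @param between name of the between-subject factor (default "group").
#' @param within optional name of the within-subject factor.
#' @return data.frame `effect`, `df1`, `df2`, `F`, `p`, `p_bonferroni`.
#' @export
run_statistics <- function(data, between = "group", within = NULL) {
  stopifnot(all(c("subject", "value", between) %in% names(data)))
  data$subject <- factor(data$subject)
  data[[between]] <- factor(data[[between]])
  if (!is.null(within)) {
    tab <- table(data$subject, data[[within]])
    if (any(tab != max(tab))) {
      off <- which(tab != max(tab), arr.ind = TRUE)[1, ]
      stop("unbalanced design: subject '", rownames(tab)[off[1]],
           "' x ", within, " '", colnames(tab)[off[2]],
           "' has a deviant cell count")
    }
  }
  if (stats::var(data$value) < 1e-12) {
    eff <- if (is.null(within)) between
           else c(between, within, paste0(between, ":", within))
    return(data.frame(effect = eff, df1 = NA, df2 = NA, F = 0, p = 1,
                      p_bonferroni = 1))
  }
  if (is.null(within)) {
    fit <- stats::aov(stats::as.formula(paste("value ~", between)),
                      data = data)
    sm <- summary(fit)[[1]]
    out <- data.frame(effect = between, df1 = sm[1, "Df"],
                      df2 = sm[2, "Df"], F = sm[1, "F value"],
                      p = sm[1, "Pr(>F)"])
  } else {
    data[[within]] <- factor(data[[within]])
    f <- stats::as.formula(sprintf("value ~ %s * %s + Error(subject/%s)",
                                   between, within, within))
    sm <- summary(stats::aov(f, data = data))
    rows <- list()
    for (stratum in sm) {
      st <- stratum[[1]]
      terms <- trimws(rownames(st))
      for (i in seq_len(nrow(st))) {
        if (terms[i] == "Residuals") next
        rows[[length(rows) + 1L]] <- data.frame(
          effect = terms[i], df1 = st[i, "Df"],
          df2 = st[nrow(st), "Df"], F = st[i, "F value"],
          p = st[i, "Pr(>F)"])
      }
    }
    out <- do.call(rbind, rows)
  }
  out$p[is.na(out$p)] <- 1
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  rownames(out) <- NULL
  out
}

#' Planned pairwise t-tests between groups
#'
#' Two-sample Welch t-tests for stated group contrasts on one metric,
#' with Bonferroni correction across the planned set.
#'
#' @param data tidy data.frame with `value` and a grouping column.
#' @param contrasts list of 2-element character vectors of group levels.
#' @param group name of the grouping column (default "group").
#' @param alternative passed to [stats::t.test()]; `"greater"` tests the
#'   directional hypothesis first-listed > second-listed.
#' @return data.frame `contrast`, `t`, `df`, `p`, `p_bonferroni`.
#' @export
planned_t_tests <- function(data, contrasts, group = "group",
                            alternative = "two.sided") {
  out <- do.call(rbind, lapply(contrasts, function(cn) {
    x <- data$value[data[[group]] == cn[1]]
    y <- data$value[data[[group]] == cn[2]]
    tt <- stats::t.test(x, y, alternative = alternative)
    data.frame(contrast = paste(cn, collapse = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out
}

#' Grid-search calibration of free model parameters
#'
#' Exhaustively (or randomly, within a budget) evaluates an objective
#' over the cross product of candidate parameter values and returns the
#' best-scoring cell with the full evaluation log. Used to fix the
#' hyperparameters that the group tables do not pin down, against
#' behavioral criteria such as the control group's cue-training accuracy.
#'
#' @param param_grid named list of candidate value vectors.
#' @param objective `function(params, seed)` returning a single numeric
#'   score (larger is better).
#' @param budget maximum number of evaluations (default all cells).
#' @param seed seed passed to the objective and used to subsample cells.
#' @return list with `best` (named list of parameter values), `score`,
#'   and `log` (data.frame of all evaluated cells and scores).
#' @export
calibrate <- function(param_grid, objective, budget = Inf, seed = 1) {
  stopifnot(length(param_grid) > 0, all(lengths(param_grid) > 0))
  cells <- expand.grid(param_grid, stringsAsFactors = FALSE)
  if (nrow(cells) > budget) {
    set.seed(seed)
    cells <- cells[sample.int(nrow(cells), budget), , drop = FALSE]
  }
  scores <- vapply(seq_len(nrow(cells)), function(i) {
    objective(as.list(cells[i, , drop = FALSE]), seed)
  }, numeric(1))
  best <- which.max(scores)
  list(best = as.list(cells[best, , drop = FALSE]), score = scores[best],
       log = data.frame(cells, score = scores))
}
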