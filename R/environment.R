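#' Build the virtual corridor
#'
#' The track is a straight corridor punctuated by doorways: vertical planes
#' with a centred gap. Doorways appear at a fixed along-track spacing
#' (default 4 length units) and are independently drawn narrow (2 units) or
#' wide (3 units); door height is constant (1.6 units). Lateral walls sit
#' flush with the posts of the widest doorway.
#'
#' The along-track forward axis is `y`; `x` is lateral. Doorway gaps are
#' centred on `x = 0`.
#'
#' @param n_doorways number of doorways (default 300).
#' @param spacing along-track distance between consecutive doorways
#'   (length units, default 4).
#' @param widths named numeric vector `c(narrow = 2, wide = 3)`.
#' @param narrow_fraction probability that a doorway is narrow (default 0.5).
#' @param height door height in length units (default 1.6).
#' @return an object of class `corridor`: a data.frame with columns
#'   `doorway`, `center_y`, `width`, `type`, plus attributes `spacing`,
#'   `height` and `half_width`. Widths are drawn from the current RNG
#'   stream, so runs are reproducible under [set.seed()].
#' @export
build_corridor <- function(n_doorways = 300, spacing = 4,
                           widths = c(narrow = 2, wide = 3),
                           narrow_fraction = 0.5, height = 1.6) {
  stopifnot(n_doorways >= 1, narrow_fraction >= 0, narrow_fraction <= 1)
  if (spacing <= 0) stop("doorway 'spacing' must be positive")
  narrow <- stats::runif(n_doorways) < narrow_fraction
  out <- data.frame(
    doorway  = seq_len(n_doorways),
    center_y = spacing * seq_len(n_doorways),
    width    = ifelse(narrow, widths[["narrow"]], widths[["wide"]]),
    type     = ifelse(narrow, "narrow", "wide"),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("corridor", "data.frame"),
            spacing = spacing, height = height,
            half_width = max(widths) / 2)
}

#' Agent state on the track
#'
#' The agent is a disc of radius 0.5 (about 1 unit diameter). Its heading is
#' the unit vector of its velocity; when the velocity is zero the last
#' nonzero heading is reused (initially straight down-track).
#'
#' @param position numeric `c(x, y)` (lateral, along-track), length units.
#' @param velocity numeric `c(dx, dy)`, length units per time step.
#' @param radius disc radius (default 0.5).
#' @param heading optional unit heading; derived from `velocity` if omitted.
#' @return an object of class `agent_state`.
#' @export
agent_state <- function(position = c(0, 0), velocity = c(0, 0.1),
                        radius = 0.5, heading = NULL) {
  stopifnot(length(position) == 2, length(velocity) == 2, radius > 0)
  if (is.null(heading)) {
    n <- sqrt(sum(velocity^2))
    heading <- if (n > 0) velocity / n else c(0, 1)
  }
  structure(list(position = as.numeric(position),
                 velocity = as.numeric(velocity),
                 radius = radius,
                 heading = as.numeric(heading)),
            class = "agent_state")
}

#' Index of the nearest doorway still ahead of the agent
#' @param y along-track position.
#' @param corridor a [build_corridor()] object.
#' @return integer doorway index, or `NA` if the agent is past the last one.
#' @keywords internal
next_doorway <- function(y, corridor) {
  i <- which(corridor$center_y > y)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

#' Retina-like view vector of the upcoming doorway
#'
#' The motor loop's state: a 100-dimensional vector with entries in
#' \{-1, +1\}. The agent sees 120 degrees horizontally and 90 degrees
#' vertically, each field split into 50 equal sectors. A horizontal sector
#' is on (+1) when its centre ray, traced from the agent's position along
#' the field centred on the heading, passes through the open gap of the
#' nearest not-yet-passed doorway. A vertical sector is on when its centre
#' elevation lies below the elevation subtended by the door top (height 1.6)
#' at the doorway's along-track distance. All other entries are -1, so the
#' number of on-bits grows as the agent nears a doorway: the code is an
#' implicit representation of position. The first 50 bits code width, the
#' last 50 height; the height code disambiguates a close narrow doorway
#' from a distant wide one subtending the same horizontal angle.
#'
#' @param agent an [agent_state()].
#' @param corridor a [build_corridor()] object.
#' @param hfov,vfov horizontal and vertical fields of view in degrees.
#' @param n_sectors sectors per field (default 50).
#' @return numeric vector of length `2 * n_sectors` with entries -1 or +1.
#' @export
compute_view_vector <- function(agent, corridor, hfov = 120, vfov = 90,
                                n_sectors = 50) {
  phi <- rep(-1, 2L * n_sectors)
  d_idx <- next_doorway(agent$position[2], corridor)
  if (is.na(d_idx)) return(phi)
  yd <- corridor$center_y[d_idx]
  half_gap <- corridor$width[d_idx] / 2
  height <- attr(corridor, "height")
  x <- agent$position[1]; y <- agent$position[2]

  # horizontal: sector-centre rays across the field centred on the heading
  th0 <- atan2(agent$heading[1], agent$heading[2]) # angle from +y, toward +x
  off <- (pi / 180) * (-hfov / 2 + hfov * (seq_len(n_sectors) - 0.5) / n_sectors)
  ang <- th0 + off
  dy <- cos(ang); dx <- sin(ang)
  tt <- ifelse(dy > 0, (yd - y) / dy, Inf)
  xi <- x + tt * dx
  phi[seq_len(n_sectors)][is.finite(xi) & abs(xi) < half_gap] <- 1

  # vertical: elevation sectors over [0, vfov] against the door-top angle
  d_along <- yd - y
  if (d_along > 0) {
    elev <- (pi / 180) * vfov * (seq_len(n_sectors) - 0.5) / n_sectors
    top <- atan2(height, d_along)
    phi[n_sectors + seq_len(n_sectors)][elev < top] <- 1
  }
  phi
}

#' Advance the agent one time step
#'
#' Moves the agent by `dZ`. If the disc's centre path crosses the plane of
#' the nearest upcoming doorway inside the open gap (gap half-width minus
#' agent radius), the outcome is a passage with reward +1 and the trial
#' segment ends. If the crossing point overlaps a doorpost, the outcome is a
#' collision with reward -1 and the agent bounces back to its pre-step
#' position. Otherwise the outcome is `none` with reward 0. The lateral
#' position is kept inside the corridor walls.
#'
#' @param agent an [agent_state()].
#' @param dZ velocity `c(dx, dy)` applied this step.
#' @param corridor a [build_corridor()] object.
#' @return list with elements `agent` (updated state), `reward`
#'   (+1, -1 or 0), `event` (`"passed"`, `"collided"`, `"none"`) and
#'   `doorway` (index of the doorway involved, or `NA`).
#' @export
step_environment <- function(agent, dZ, corridor) {
  stopifnot(all(is.finite(dZ)), length(dZ) == 2)
  p0 <- agent$position
  p1 <- p0 + dZ
  d_idx <- next_doorway(p0[2], corridor)
  event <- "none"; reward <- 0
  if (!is.na(d_idx) && p1[2] >= corridor$center_y[d_idx]) {
    yd <- corridor$center_y[d_idx]
    xc <- if (p1[2] > p0[2]) p0[1] + (p1[1] - p0[1]) * (yd - p0[2]) / (p1[2] - p0[2])
          else p0[1]
    if (abs(xc) < corridor$width[d_idx] / 2 - agent$radius) {
      event <- "passed"; reward <- 1
    } else {
      event <- "collided"; reward <- -1
      p1 <- p0
    }
  }
  lat_max <- attr(corridor, "half_width") - agent$radius
  p1[1] <- min(max(p1[1], -lat_max), lat_max)
  n <- sqrt(sum(dZ^2))
  heading <- if (n > 0 && event != "collided") dZ / n else agent$heading
  list(agent = agent_state(p1, dZ, agent$radius, heading),
       reward = reward, event = event,
       doorway = if (event == "none") NA_integer_ else d_idx)
}

#' Cue schedule over the corridor
#'
#' Assigns one word cue to each of a set of doorways; the cue is presented
#' 2 length units before the doorway plane. Cues are drawn from the active
#' cue set -- uniformly, or balanced so that every cue appears equally often
#' (shuffled), or in blocks of same-class cues.
#'
#' @param corridor a [build_corridor()] object.
#' @param cues character vector of cue labels (see [cue_table()]); may be
#'   `NULL` for a cue-free schedule.
#' @param doorways integer indices of doorways that receive a cue
#'   (default: all).
#' @param offset along-track distance before the doorway at which the cue
#'   appears (default 2).
#' @param method `"balanced"` (equal counts, shuffled), `"uniform"`
#'   (independent draws) or `"blocks"` (consecutive runs of
#'   `block_length` repetitions per cue-set cycle).
#' @param block_length run length for `method = "blocks"`.
#' @return a data.frame of class `cue_schedule` with columns `doorway`,
#'   `cue`, `onset_y`.
#' @export
cue_schedule <- function(corridor, cues, doorways = corridor$doorway,
                         offset = 2, method = c("balanced", "uniform", "blocks"),
                         block_length = 10) {
  method <- match.arg(method)
  n <- length(doorways)
  assigned <- if (is.null(cues) || n == 0L) rep(NA_character_, n)
  else switch(method,
    uniform  = sample(cues, n, replace = TRUE),
    balanced = sample(rep(cues, length.out = max(n, length(cues))))[seq_len(n)],
    blocks   = rep(rep(cues, each = block_length), length.out = n)
  )
  structure(data.frame(doorway = doorways,
                       cue = assigned,
                       onset_y = corridor$center_y[doorways] - offset,
                       stringsAsFactors = FALSE),
            class = c("cue_schedule", "data.frame"))
}

#' Cue presented between two successive agent positions
#'
#' A cue fires exactly once: at the first time step whose movement interval
#' `(y_prev, y_now]` contains the cue's presentation position.
#'
#' @param agent an [agent_state()] (its along-track position is `y_now`).
#' @param schedule a [cue_schedule()].
#' @param y_prev along-track position at the previous time step.
#' @return the cue label (character) or `NA` if no cue onset was crossed.
#' @export
active_cue <- function(agent, schedule, y_prev) {
  y_now <- agent$position[2]
  hit <- which(schedule$onset_y > y_prev & schedule$onset_y <= y_now &
                 !is.na(schedule$cue))
  if (length(hit) == 0L) NA_character_ else schedule$cue[hit[1L]]
}

#' Tabular form of a corridor and its cue schedule
#'
#' One row per doorway: index, centre, width, cue (or `NA`) and cue
#' presentation position, suitable for writing to a delimited file.
#'
#' @param corridor a [build_corridor()] object.
#' @param schedule optional [cue_schedule()].
#' @return a plain data.frame.
#' @export
corridor_table <- function(corridor, schedule = NULL) {
  out <- as.data.frame(corridor)
  out$cue <- NA_character_
  out$onset_y <- NA_real_
  if (!is.null(schedule)) {
    m <- match(schedule$doorway, out$doorway)
    out$cue[m] <- schedule$cue
    out$onset_y[m] <- schedule$onset_y
  }
  out
}
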