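# Independent brute-force oracles used to cross-check the implementation.

# Per-sector ray/segment intersection: each sector-centre ray is intersected
# with the doorway gap segment by an explicit parametric solve (a different
# formulation from the implementation's plane-crossing arithmetic).
view_vector_oracle <- function(agent, corridor, hfov = 120, vfov = 90,
                               n_sectors = 50) {
  phi <- rep(-1, 2 * n_sectors)
  ahead <- which(corridor$center_y > agent$position[2])
  if (length(ahead) == 0) return(phi)
  d <- ahead[1]
  yd <- corridor$center_y[d]
  g <- corridor$width[d] / 2
  # gap segment endpoints
  p <- agent$position
  a <- c(-g, yd); bseg <- c(g, yd)
  th0 <- atan2(agent$heading[1], agent$heading[2])
  for (i in seq_len(n_sectors)) {
    ang <- th0 + (pi / 180) * (-hfov / 2 + hfov * (i - 0.5) / n_sectors)
    dir <- c(sin(ang), cos(ang))
    # solve p + t*dir = a + u*(b-a) for t>0, 0<u<1
    M <- cbind(dir, -(bseg - a))
    if (abs(det(M)) < 1e-14) next
    tu <- solve(M, a - p)
    if (tu[1] > 0 && tu[2] > 0 && tu[2] < 1) phi[i] <- 1
  }
  dal <- yd - p[2]
  if (dal > 0) {
    for (j in seq_len(n_sectors)) {
      elev <- (pi / 180) * vfov * (j - 0.5) / n_sectors
      # sector centre is below the door top iff a ray at that elevation,
      # traced to the doorway plane, passes under the lintel
      if (dal * tan(elev) < attr(corridor, "height"))
        phi[n_sectors + j] <- 1
    }
  }
  phi
}

# Running-sum accumulator oracle: vectorised cumulative sums restarted after
# every threshold crossing (the implementation uses a scalar loop).
accumulate_oracle <- function(speed, kappa = 1, th = 1) {
  inc <- pmax(rep_len(kappa, length(speed)) * speed, 0)
  lat <- integer(0)
  i <- 0L
  n <- length(inc)
  while (i < n) {
    cs <- cumsum(inc[(i + 1L):n])
    j <- match(TRUE, cs >= th)
    if (is.na(j)) break
    lat <- c(lat, j)
    i <- i + j
  }
  structure(lat, residual_steps = n - i)
}

# small corridor for unit tests
tiny_corridor <- function(n = 3, widths = c(3, 2, 3)) {
  corr <- data.frame(doorway = seq_len(n), center_y = 4 * seq_len(n),
                     width = rep_len(widths, n),
                     type = ifelse(rep_len(widths, n) <= 2, "narrow", "wide"),
                     stringsAsFactors = FALSE)
  structure(corr, class = c("corridor", "data.frame"),
            spacing = 4, height = 1.6, half_width = 1.5)
}
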