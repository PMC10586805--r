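# Shared fixtures: small hand-built trajectories and record tables.

FPS <- 15

# Straight constant-speed run along +x.
make_run_trajectory <- function(duration = 20, speed = 0.5, id = 1L) {
  t <- seq(0, duration, by = 1 / FPS)
  trajectory(id, t, x = speed * t, y = rep(0, length(t)),
             head_dx = rep(1, length(t)), head_dy = rep(0, length(t)))
}

# Run -> stop (low speed) -> resume with a given heading change (degrees).
make_stop_trajectory <- function(stop_start = 8, stop_len = 2, dtheta = 0,
                                 speed = 0.5, low_speed = 0.02,
                                 duration = 20, id = 1L) {
  t <- seq(0, duration, by = 1 / FPS)
  n <- length(t)
  spd <- ifelse(t >= stop_start & t < stop_start + stop_len, low_speed, speed)
  hd <- ifelse(t < stop_start + stop_len, 0, dtheta * pi / 180)
  dt <- 1 / FPS
  x <- cumsum(c(0, spd[-n] * cos(hd[-n]) * dt))
  y <- cumsum(c(0, spd[-n] * sin(hd[-n]) * dt))
  trajectory(id, t, x, y, cos(hd), sin(hd))
}

# Run -> stop -> backward crawl (head still forward) -> stop -> run off.
make_rev_trajectory <- function(stop_start = 8, duration = 20, speed = 0.5,
                                id = 1L) {
  t <- seq(0, duration, by = 1 / FPS)
  n <- length(t)
  dt <- 1 / FPS
  spd <- rep(speed, n)
  mh <- rep(0, n)              # motion heading
  hh <- rep(0, n)              # head heading
  spd[t >= stop_start & t < stop_start + 0.8] <- 0
  back <- t >= stop_start + 0.8 & t < stop_start + 2
  spd[back] <- 0.3
  mh[back] <- pi
  after <- t >= stop_start + 2
  mh[after] <- pi; hh[after] <- pi   # turns around and crawls away
  x <- cumsum(c(0, spd[-n] * cos(mh[-n]) * dt))
  y <- cumsum(c(0, spd[-n] * sin(mh[-n]) * dt))
  trajectory(id, t, x, y, cos(hh), sin(hh))
}

make_records <- function(labels_by_larva) {
  do.call(rbind, lapply(seq_along(labels_by_larva), function(i) {
    lab <- labels_by_larva[[i]]
    data.frame(larva_id = i, pulse_n = seq_along(lab) - 1L,
               label = factor(lab, levels = c("CONT", "PAUSE", "TURN", "REV")))
  })) -> df
  class(df) <- c("response_records", "data.frame")
  df
}

default_pulse_protocol <- function(n_pulses = 10)
  stimulus_protocol(500, 2, t_on = 10, t_off = 20, n_pulses = n_pulses)

# Brute-force double-loop convolution oracle.
conv_oracle <- function(s, h) {
  out <- numeric(length(s) + length(h) - 1)
  for (i in seq_along(s))
    for (j in seq_along(h))
      out[i + j - 1] <- out[i + j - 1] + s[i] * h[j]
  out
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration: sum of
# P(tables) with probability <= observed, margins fixed.
fisher_oracle <- function(k1, n1, k2, n2) {
  m <- k1 + k2                 # total successes
  lo <- max(0, m - n2); hi <- min(n1, m)
  ks <- lo:hi
  probs <- dhyper(ks, n1, n2, m)
  p_obs <- dhyper(k1, n1, n2, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
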