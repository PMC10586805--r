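# Seeded synthetic-data generator.
#
# Produces per-larva behavioral response records, binned count time series
# and geometric trajectories with the statistical structure the downstream
# analysis assumes, so the whole pipeline is testable without recordings.
#
# Sequencing model for stimulated populations (see the methods vignette):
#   pulse 0:        P(REV) = F0_REV (floored at the baseline)
#   pulse n >= 1:   P(REV | REV at n-1)     = rho * (1 - exp(-T_OFF / tau_res(n-1)))
#                   P(REV | non-REV at n-1) = 0    (one-way habituation)
# with rho the reverse-crawl repeat probability (default 0.85). The marginal
# reversal fraction is therefore F0 * rho^n * prod(r_k), declining across
# the train, while the pulse-(n)/pulse-(n-1) ratio isolates rho * r_n, whose
# T_OFF dependence recovers tau_res.

#' Default behavioral transition kernel (lag 1)
#'
#' Row-stochastic 4x4 matrix of conditional response probabilities between
#' consecutive pulses, rows = behavior at pulse n, columns = behavior at
#' pulse n+1. Continuation is absorbing and no row other than REV enters
#' REV (one-way habituation). The REV row's diagonal is the repeat
#' probability \code{rev_repeat}; at generation time it is additionally
#' scaled by the re-sensitization recovery factor, with the exit mass
#' redistributed proportionally.
#'
#' @param rev_repeat probability that a reversal is followed by another
#'   reversal at the next pulse (default 0.85).
#' @return 4x4 numeric matrix with dimnames CONT/PAUSE/TURN/REV.
#' @export
default_transition_kernel <- function(rev_repeat = 0.85) {
  stopifnot(rev_repeat > 0, rev_repeat <= 1)
  lv <- behavior_levels()
  k <- matrix(0, 4, 4, dimnames = list(from = lv, to = lv))
  k["CONT", ] <- c(1, 0, 0, 0)
  k["PAUSE", ] <- c(0.55, 0.30, 0.15, 0)
  k["TURN", ] <- c(0.35, 0.25, 0.40, 0)
  exit <- c(0.25, 0.30, 0.45)                 # CONT, PAUSE, TURN shares
  k["REV", ] <- c((1 - rev_repeat) * exit, rev_repeat)
  k
}

#' Synthetic-generator configuration
#'
#' @param n_larvae number of larvae to simulate (>= 0).
#' @param seed integer seed; mandatory, all generator randomness derives
#'   from it.
#' @param strain strain preset name passed to [strain_preset()] when
#'   \code{habituation} is not supplied.
#' @param habituation a \code{habituation_params} object.
#' @param baseline_rev spontaneous reversal probability per response window
#'   (default 0.03).
#' @param baseline_stop spontaneous probability of any avoidance behavior
#'   (pause, turn or reversal) per window (default 0.24).
#' @param f0_stop naive stop fraction at a strong stimulus onset
#'   (default 0.90: nearly all larvae interrupt crawling at the reference
#'   intensity).
#' @param pause_turn_split length-2 vector, shares of PAUSE and TURN among
#'   non-reversal stops (default c(0.35, 0.65)).
#' @param transition_kernel 4x4 row-stochastic kernel, see
#'   [default_transition_kernel()]. Non-REV rows must not enter REV.
#' @param gamma_min,f_min sensitivity threshold in stimulus space: the
#'   population responds above baseline only when \code{gamma >= gamma_min}
#'   and \code{frequency_hz >= f_min} (defaults 1 and 100).
#' @param dt bin resolution (s) for count time series (default 1).
#' @param run_speed forward crawl speed for trajectory realization (mm/s).
#' @param strain_name label recorded in outputs.
#' @return an object of class \code{generator_config}.
#' @export
generator_config <- function(n_larvae, seed, strain = "wildtype",
                             habituation = strain_preset(strain),
                             baseline_rev = 0.03, baseline_stop = 0.24,
                             f0_stop = 0.90,
                             pause_turn_split = c(0.35, 0.65),
                             transition_kernel = default_transition_kernel(),
                             gamma_min = 1, f_min = 100,
                             dt = 1, run_speed = 0.5,
                             strain_name = strain) {
  stopifnot(n_larvae >= 0, n_larvae == round(n_larvae))
  if (missing(seed) || !is.numeric(seed))
    stop_domain("seed is mandatory and must be numeric")
  probs <- c(baseline_rev, baseline_stop, f0_stop, pause_turn_split)
  if (any(probs < 0) || any(probs > 1))
    stop_domain("probabilities must lie in [0, 1]")
  if (baseline_rev > baseline_stop)
    stop_domain("baseline_rev must not exceed baseline_stop")
  if (abs(sum(pause_turn_split) - 1) > 1e-8)
    stop_domain("pause_turn_split must sum to 1")
  stopifnot(inherits(habituation, "habituation_params"))
  k <- transition_kernel
  if (!is.matrix(k) || any(dim(k) != 4) || any(k < 0) ||
      any(abs(rowSums(k) - 1) > 1e-8))
    stop_domain("transition_kernel must be a 4x4 row-stochastic matrix")
  if (any(k[c("CONT", "PAUSE", "TURN"), "REV"] > 0))
    stop_domain("transition_kernel must have no entries into REV from non-REV rows")
  structure(
    list(n_larvae = as.integer(n_larvae), seed = as.integer(seed),
         habituation = habituation, baseline_rev = baseline_rev,
         baseline_stop = baseline_stop, f0_stop = f0_stop,
         pause_turn_split = pause_turn_split, transition_kernel = k,
         gamma_min = gamma_min, f_min = f_min, dt = dt,
         run_speed = run_speed, strain_name = strain_name),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("generator_config: %d larvae, strain %s, seed %d\n",
              x$n_larvae, x$strain_name, x$seed))
  invisible(x)
}

#' Stimulus sensitivity factor for a protocol
#'
#' Reversal behavior requires the vibration to cross a rough threshold in
#' (f, Gamma) space; below it the population responds at baseline only.
#'
#' @param config a \code{generator_config}.
#' @param protocol a \code{stimulus_protocol}.
#' @return 1 if the protocol is above threshold, else 0.
#' @export
sensitivity_factor <- function(config, protocol) {
  stopifnot(inherits(config, "generator_config"),
            inherits(protocol, "stimulus_protocol"))
  as.numeric(protocol$gamma >= config$gamma_min &&
               protocol$frequency_hz >= config$f_min)
}

# Recovery factor for pulse n (>=1) of a protocol under config's habituation.
#' @noRd
recovery_factors <- function(config, protocol) {
  n <- protocol$n_pulses
  vapply(seq_len(n) - 1L, function(k)
    resensitization_curve(config$habituation, protocol$t_off, k), numeric(1))
}

#' Generate per-larva behavioral response records
#'
#' Draws one behavior label per larva per pulse. Above the sensitivity
#' threshold, reversals follow the one-way sequencing model described in
#' the package vignette (REV repeats with probability
#' \code{rev_repeat * recovery}, never re-enters from weaker behaviors);
#' weaker behaviors follow the transition kernel. Below threshold all
#' draws are independent at the configured baselines.
#'
#' @param config a \code{generator_config}.
#' @param protocol a \code{stimulus_protocol} with >= 1 pulse.
#' @return data.frame of class \code{response_records} with columns
#'   \code{larva_id}, \code{pulse_n} (0-based) and \code{label} (factor
#'   CONT/PAUSE/TURN/REV).
#' @export
generate_response_records <- function(config, protocol) {
  stopifnot(inherits(config, "generator_config"),
            inherits(protocol, "stimulus_protocol"))
  n_larvae <- config$n_larvae
  n_pulse <- protocol$n_pulses
  if (n_larvae == 0) {
    out <- data.frame(larva_id = integer(0), pulse_n = integer(0),
                      label = as_behavior(character(0)))
    class(out) <- c("response_records", "data.frame")
    return(out)
  }
  set.seed(derive_seed(config$seed, 1))
  sens <- sensitivity_factor(config, protocol)
  hp <- config$habituation
  labels <- matrix(NA_character_, n_larvae, n_pulse)

  if (sens == 0) {
    # below threshold: independent baseline draws per window
    p_rev <- config$baseline_rev
    p_stop_given_not_rev <-
      clip01((config$baseline_stop - p_rev) / (1 - p_rev))
    for (j in seq_len(n_pulse)) {
      u <- stats::runif(n_larvae)
      lab <- rep("CONT", n_larvae)
      rev <- u < p_rev
      lab[rev] <- "REV"
      v <- stats::runif(n_larvae)
      stopped <- !rev & v < p_stop_given_not_rev
      w <- stats::runif(n_larvae)
      lab[stopped & w < config$pause_turn_split[1]] <- "PAUSE"
      lab[stopped & w >= config$pause_turn_split[1]] <- "TURN"
      labels[, j] <- lab
    }
  } else {
    r <- recovery_factors(config, protocol)     # r[1] = 1 for pulse 0
    rho <- config$transition_kernel["REV", "REV"]
    exit_w <- config$transition_kernel["REV", c("CONT", "PAUSE", "TURN")]
    exit_w <- if (sum(exit_w) > 0) exit_w / sum(exit_w) else
      c(CONT = 0.25, PAUSE = 0.30, TURN = 0.45)
    p0_rev <- max(config$baseline_rev, hp$f0_rev * sens)
    s0_stop <- max(config$baseline_stop, config$f0_stop * sens)
    p_stop_given_not_rev <- clip01((s0_stop - p0_rev) / (1 - p0_rev))
    if (p0_rev > 1 || s0_stop > 1)
      stop_domain("composed response probabilities exceed 1; check config")
    # pulse 0: marginal draw
    u <- stats::runif(n_larvae)
    lab <- rep("CONT", n_larvae)
    lab[u < p0_rev] <- "REV"
    v <- stats::runif(n_larvae)
    stopped <- lab != "REV" & v < p_stop_given_not_rev
    w <- stats::runif(n_larvae)
    lab[stopped & w < config$pause_turn_split[1]] <- "PAUSE"
    lab[stopped & w >= config$pause_turn_split[1]] <- "TURN"
    labels[, 1] <- lab
    # subsequent pulses: kernel-driven sequencing
    if (n_pulse > 1) {
      for (j in 2:n_pulse) {
        prev <- labels[, j - 1]
        cur <- character(n_larvae)
        kappa <- clip01(rho * r[j])    # REV repeat prob at this pulse
        is_rev <- prev == "REV"
        if (any(is_rev)) {
          u <- stats::runif(sum(is_rev))
          rep_rev <- u < kappa
          cur[is_rev][rep_rev] <- "REV"
          if (any(!rep_rev)) {
            cur[is_rev][!rep_rev] <- sample(c("CONT", "PAUSE", "TURN"),
                                            sum(!rep_rev), replace = TRUE,
                                            prob = exit_w)
          }
        }
        for (from in c("CONT", "PAUSE", "TURN")) {
          sel <- prev == from
          if (any(sel)) {
            cur[sel] <- sample(behavior_levels(), sum(sel), replace = TRUE,
                               prob = config$transition_kernel[from, ])
          }
        }
        labels[, j] <- cur
      }
    }
  }

  out <- data.frame(
    larva_id = rep(seq_len(n_larvae), times = n_pulse),
    pulse_n = rep(seq_len(n_pulse) - 1L, each = n_larvae),
    label = as_behavior(as.vector(labels))
  )
  class(out) <- c("response_records", "data.frame")
  attr(out, "strain") <- config$strain_name
  out
}

#' Generate a binned count time series of reversal and stop states
#'
#' Emulates the instantaneous population fraction traces F_REV(t),
#' F_STOP(t): per bin, the number of reversing (stopping) larvae is a
#' binomial draw around a deterministic expectation curve. Each pulse
#' onset resets the reversal expectation to that pulse's peak, from which
#' it relaxes toward the baseline with time constant tau_des through the
#' ON window and the following OFF gap. Peaks follow the same sequencing
#' law as
#' [generate_response_records()] (peak_n = F0 * rho^n * prod r_k, floored
#' at the baseline).
#'
#' @param config a \code{generator_config}.
#' @param protocol a \code{stimulus_protocol}.
#' @param duration total duration to simulate (s); must cover the protocol
#'   span.
#' @return data.frame of class \code{count_timeseries} with columns
#'   \code{t} (bin centers, s), \code{n_active}, \code{n_rev},
#'   \code{n_stop}, and the zero-noise expectations \code{p_rev},
#'   \code{p_stop}.
#' @export
generate_count_timeseries <- function(config, protocol, duration) {
  stopifnot(inherits(config, "generator_config"),
            inherits(protocol, "stimulus_protocol"))
  if (config$dt <= 0) stop_domain("dt must be > 0")
  if (duration < protocol_span(protocol) - 1e-9)
    stop_domain("duration must cover the protocol span")
  dt <- config$dt
  t <- seq(0, duration - dt / 2, by = dt) + dt / 2
  exp_curves <- expectation_curves(config, protocol, t)
  set.seed(derive_seed(config$seed, 2))
  n <- config$n_larvae
  n_rev <- stats::rbinom(length(t), n, exp_curves$p_rev)
  # stops include reversals; draw the non-rev stop component conditionally
  p_extra <- clip01((exp_curves$p_stop - exp_curves$p_rev) /
                      pmax(1 - exp_curves$p_rev, 1e-12))
  n_stop <- n_rev + stats::rbinom(length(t), n - n_rev, p_extra)
  out <- data.frame(t = t, n_active = n, n_rev = n_rev, n_stop = n_stop,
                    p_rev = exp_curves$p_rev, p_stop = exp_curves$p_stop)
  class(out) <- c("count_timeseries", "data.frame")
  attr(out, "dt") <- dt
  attr(out, "strain") <- config$strain_name
  out
}

# Deterministic expectation curves for the instantaneous REV / STOP state
# fractions under a protocol. Each pulse onset resets the response to that
# pulse's peak, after which the expectation relaxes toward the baseline
# with time constant tau_des — through the remainder of the ON window and
# the following OFF gap alike, so a near-delta burst still produces the
# slow return to baseline seen in impulse-response experiments.
#' @noRd
expectation_curves <- function(config, protocol, t) {
  hp <- config$habituation
  sens <- sensitivity_factor(config, protocol)
  p_rev <- rep(config$baseline_rev, length(t))
  p_stop <- rep(config$baseline_stop, length(t))
  if (sens > 0) {
    onsets <- pulse_onsets(protocol)
    r <- recovery_factors(config, protocol)
    rho <- config$transition_kernel["REV", "REV"]
    g <- cumprod(r) * rho^(seq_along(r) - 1L)   # habituation scaling per pulse
    peak_rev <- pmax(config$baseline_rev, hp$f0_rev * g)
    peak_stop <- pmax(config$baseline_stop,
                      config$baseline_stop + (config$f0_stop - config$baseline_stop) * g)
    post <- t >= onsets[1]
    if (any(post)) {
      idx <- pmax(1L, pmin(protocol$n_pulses,
        floor((t[post] - protocol$t_start) / protocol_period(protocol)) + 1L))
      decay <- exp(-(t[post] - onsets[idx]) / hp$tau_des)
      p_rev[post] <- config$baseline_rev +
        (peak_rev[idx] - config$baseline_rev) * decay
      p_stop[post] <- config$baseline_stop +
        (peak_stop[idx] - config$baseline_stop) * decay
    }
  }
  list(p_rev = clip01(p_rev), p_stop = clip01(p_stop))
}

#' Write/read response-record CSV
#'
#' Dialect: header row \code{larva_id,pulse_n,label}, UTF-8, "." decimal
#' separator.
#'
#' @param records a \code{response_records} data.frame.
#' @param path file path.
#' @return \code{path} (write) or the records (read).
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records)[c("larva_id", "pulse_n", "label")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$label <- as_behavior(df$label)
  class(df) <- c("response_records", "data.frame")
  df
}
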