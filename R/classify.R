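# Behavior classification from trajectories.
#
# A stop is flagged where the smoothed speed drops below a per-larva
# threshold for a sustained interval. From a stop, the event resolves to
# REV if the head-orientation vector and the velocity vector point in
# opposing directions (negative dot product) over a sustained window during
# or immediately after the stop; otherwise to PAUSE or TURN by comparing
# the heading change across the stop against a 30-degree threshold. One
# response per larva per stimulus pulse is assigned from the 3 s following
# the pulse onset under the mid-action rule.

#' Detect stop intervals in a trajectory
#'
#' Maximal intervals where the smoothed speed stays below
#' \code{speed_frac} times the larva's median smoothed speed (with a small
#' absolute floor so that an entirely stationary record still registers)
#' for at least \code{min_duration} seconds.
#'
#' @param traj a \code{trajectory}.
#' @param speed_frac stop threshold as a fraction of the larva's median
#'   smoothed speed (default 0.2).
#' @param min_duration minimum stop duration in seconds (default 0.5).
#' @param abs_threshold optional absolute speed threshold in mm/s,
#'   overriding the per-larva fraction.
#' @param floor_speed absolute lower bound on the threshold (mm/s,
#'   default 0.05), the degenerate-input guard for near-stationary records.
#' @return data.frame with columns \code{start_t, end_t, start_idx,
#'   end_idx}, non-overlapping and ordered; zero rows if no stops.
#' @export
detect_stops <- function(traj, speed_frac = 0.2, min_duration = 0.5,
                         abs_threshold = NULL, floor_speed = 0.05) {
  kin <- trajectory_kinematics(traj)
  thr <- if (!is.null(abs_threshold)) abs_threshold else
    max(speed_frac * stats::median(kin$speed_smooth), floor_speed)
  below <- kin$speed_smooth < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  out <- data.frame(start_idx = starts[keep], end_idx = ends[keep])
  if (nrow(out) > 0) {
    out$start_t <- kin$t[out$start_idx]
    out$end_t <- kin$t[out$end_idx]
    out <- out[out$end_t - out$start_t >= min_duration, , drop = FALSE]
  } else {
    out$start_t <- numeric(0); out$end_t <- numeric(0)
  }
  rownames(out) <- NULL
  out[, c("start_t", "end_t", "start_idx", "end_idx")]
}

# Longest run (in seconds) of negative head.velocity dot product among
# frames of kin selected by sel.
#' @noRd
longest_negative_dot <- function(kin, sel) {
  neg <- kin$head_dot_vel < 0 & sel
  neg[is.na(neg)] <- FALSE
  r <- rle(neg)
  if (!any(r$values)) return(0)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values)
  max(kin$t[ends[runs]] - kin$t[starts[runs]])
}

# Circular mean heading over frames selected by sel; NA if fewer than 2
# moving frames.
#' @noRd
mean_heading <- function(kin, sel, thr) {
  sel <- sel & kin$speed_smooth >= thr
  if (sum(sel, na.rm = TRUE) < 2) return(NA_real_)
  atan2(mean(sin(kin$heading[sel])), mean(cos(kin$heading[sel])))
}

#' Classify the behavior resolved from one stop
#'
#' @param traj a \code{trajectory}.
#' @param stop one row of [detect_stops()] output (or a list with
#'   \code{start_t}, \code{end_t}).
#' @param theta_threshold heading-change threshold in degrees separating
#'   PAUSE from TURN (default 30; a change of exactly 30 degrees counts as
#'   the stronger behavior, TURN).
#' @param rev_min_duration minimum sustained duration (s) of negative
#'   head-vector/velocity dot product required to call REV (default 0.5).
#' @param rev_lookahead seconds after the stop end inside which backward
#'   motion still attributes to this stop (default 2).
#' @param avg_window seconds over which pre-stop and post-resumption
#'   headings are averaged (default 1).
#' @param margin seconds excluded on either side of the stop before
#'   averaging headings (default 0.2, about one speed-smoothing
#'   half-width), so frames smeared across the stop boundary do not
#'   contaminate the heading estimate.
#' @return one of \code{"PAUSE", "TURN", "REV", "UNRESOLVED"}
#'   (\code{UNRESOLVED}: the trajectory ends before motion resumes).
#' @export
classify_event <- function(traj, stop, theta_threshold = 30,
                           rev_min_duration = 0.5, rev_lookahead = 2,
                           avg_window = 1, margin = 0.2) {
  kin <- trajectory_kinematics(traj)
  thr <- max(0.2 * stats::median(kin$speed_smooth), 0.05)
  in_scope <- kin$t >= stop$start_t & kin$t <= stop$end_t + rev_lookahead
  if (longest_negative_dot(kin, in_scope) >= rev_min_duration) return("REV")
  pre <- mean_heading(kin, kin$t >= stop$start_t - margin - avg_window &
                        kin$t < stop$start_t - margin, thr)
  post <- mean_heading(kin, kin$t > stop$end_t + margin &
                         kin$t <= stop$end_t + margin + avg_window, thr)
  if (is.na(post)) return("UNRESOLVED")
  if (is.na(pre)) return("UNRESOLVED")
  dth <- abs(atan2(sin(post - pre), cos(post - pre))) * 180 / pi
  # the threshold itself counts as the stronger behavior; the epsilon
  # absorbs floating-point round-off in the angle reconstruction
  if (dth >= theta_threshold - 1e-9) "TURN" else "PAUSE"
}

#' Assign one behavioral response to a stimulus pulse
#'
#' Examines the \code{window} seconds following the onset of pulse
#' \code{pulse_n}. An action already in progress at onset counts; forward
#' crawling that transitions into a pause, turn or reversal inside the
#' window is relabeled to the new action; when several actions resolve,
#' the strongest (REV > TURN > PAUSE) is kept. CONT is assigned iff no stop
#' begins or continues in the window.
#'
#' @param traj a \code{trajectory}.
#' @param protocol a \code{stimulus_protocol}.
#' @param pulse_n pulse index, 0-based, \code{< n_pulses}.
#' @param window response window in seconds (default 3).
#' @param stops optional precomputed [detect_stops()] output for this
#'   trajectory (saves recomputation when looping over pulses).
#' @param ... further arguments passed to [classify_event()].
#' @return a one-row data.frame with \code{larva_id, pulse_n, label,
#'   window_start, window_end}; \code{label} is NA when the trajectory does
#'   not span the window (record excluded from N) and \code{"UNRESOLVED"}
#'   when a stop never resolves.
#' @export
assign_pulse_response <- function(traj, protocol, pulse_n, window = 3,
                                  stops = NULL, ...) {
  stopifnot(inherits(traj, "trajectory"), inherits(protocol, "stimulus_protocol"))
  if (pulse_n < 0 || pulse_n >= protocol$n_pulses)
    stop_domain("pulse_n must be in [0, n_pulses)")
  onset <- pulse_onsets(protocol)[pulse_n + 1]
  wend <- onset + window
  rec <- data.frame(larva_id = traj$larva_id[1], pulse_n = pulse_n,
                    label = NA_character_, window_start = onset,
                    window_end = wend)
  if (min(traj$t) > onset || max(traj$t) < wend) return(rec)  # missing
  if (is.null(stops)) stops <- detect_stops(traj)
  kin <- trajectory_kinematics(traj)
  # mid-reversal at onset or reversal developing inside the window
  in_win <- kin$t >= onset & kin$t <= wend + 0.5
  rev_here <- longest_negative_dot(kin, in_win) >= 0.5
  labs <- character(0)
  if (nrow(stops) > 0) {
    ongoing <- stops$start_t <= onset & stops$end_t > onset
    starting <- stops$start_t >= onset & stops$start_t < wend
    sel <- which(ongoing | starting)
    labs <- vapply(sel, function(i)
      classify_event(traj, stops[i, ], ...), character(1))
  }
  if (rev_here) labs <- c(labs, "REV")
  if (length(labs) == 0) {
    rec$label <- "CONT"
  } else if (any(labs == "REV")) {
    rec$label <- "REV"
  } else if (any(labs == "TURN")) {
    rec$label <- "TURN"
  } else if (any(labs == "PAUSE")) {
    rec$label <- "PAUSE"
  } else {
    rec$label <- "UNRESOLVED"
  }
  rec
}

#' Classify responses of many trajectories to every pulse of a protocol
#'
#' @param trajs a list of \code{trajectory} objects.
#' @param protocol a \code{stimulus_protocol}.
#' @param window response window in seconds (default 3).
#' @param ... further arguments passed to [classify_event()].
#' @return a \code{response_records} data.frame with one row per
#'   (larva, pulse); labels may be NA (window not covered) or
#'   \code{UNRESOLVED} — both are excluded from population fractions.
#' @export
classify_responses <- function(trajs, protocol, window = 3, ...) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    stops <- detect_stops(tr)
    do.call(rbind, lapply(seq_len(protocol$n_pulses) - 1L, function(n)
      assign_pulse_response(tr, protocol, n, window, stops = stops, ...)))
  })
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = c(behavior_levels(), "UNRESOLVED"))
  class(out) <- c("response_records", "data.frame")
  out
}
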