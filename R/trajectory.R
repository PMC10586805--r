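# Trajectory containers and geometric realization of behavior scripts.
#
# A trajectory is a per-larva kinematic time series sampled at the camera
# frame rate (15 frames/s): time, position (mm) and the unit head-orientation
# vector. Velocity, speed and heading are derived by central differences.
#
# The generator realizes a scripted sequence of behavior labels as a
# piecewise path: forward runs at constant speed; a PAUSE or TURN as a
# full stop followed by resumption with a heading change below/above 30
# degrees; a REV as a stop followed by a bout of backward crawling during
# which the head-orientation vector opposes the velocity vector.

#' Construct a trajectory object
#'
#' @param larva_id identifier.
#' @param t frame times (s), strictly increasing.
#' @param x,y positions (mm).
#' @param head_dx,head_dy head-orientation unit vector components.
#' @return data.frame of class \code{trajectory}.
#' @export
trajectory <- function(larva_id, t, x, y, head_dx, head_dy) {
  if (length(t) < 3) stop_domain("a trajectory needs at least 3 frames")
  if (any(diff(t) <= 0)) stop_domain("t must be strictly increasing")
  norm <- sqrt(head_dx^2 + head_dy^2)
  if (any(norm < 1e-9)) stop_domain("head vector must be non-zero")
  out <- data.frame(larva_id = larva_id, t = t, x = x, y = y,
                    head_dx = head_dx / norm, head_dy = head_dy / norm)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Derived kinematics of a trajectory
#'
#' Velocity by central differences, raw and smoothed speed (centered
#' 5-frame moving average), heading angle, and the head-vector/velocity
#' dot product whose negative values indicate reverse crawling.
#'
#' @param traj a \code{trajectory}.
#' @param smooth_frames width of the centered moving average applied to
#'   speed before stop detection (default 5 frames, about 0.33 s at 15 fps).
#' @return data.frame with columns \code{t, vx, vy, speed, speed_smooth,
#'   heading, head_dot_vel}.
#' @export
trajectory_kinematics <- function(traj, smooth_frames = 5) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  t <- traj$t
  vx <- c(NA, (traj$x[3:n] - traj$x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]), NA)
  vy <- c(NA, (traj$y[3:n] - traj$y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]), NA)
  vx[1] <- vx[2]; vy[1] <- vy[2]
  vx[n] <- vx[n - 1]; vy[n] <- vy[n - 1]
  speed <- sqrt(vx^2 + vy^2)
  k <- rep(1 / smooth_frames, smooth_frames)
  sm <- as.numeric(stats::filter(speed, k, sides = 2))
  # shrink the window at the edges instead of dropping frames
  half <- (smooth_frames - 1) %/% 2
  for (i in which(is.na(sm))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sm[i] <- mean(speed[lo:hi])
  }
  data.frame(t = t, vx = vx, vy = vy, speed = speed, speed_smooth = sm,
             heading = atan2(vy, vx),
             head_dot_vel = traj$head_dx * vx + traj$head_dy * vy)
}

#' Realize behavior scripts as geometric trajectories
#'
#' Turns per-larva response records into piecewise crawling paths sampled
#' at \code{fps} frames per second, such that the classifier recovers the
#' scripted labels (round trip). PAUSE resumes with a heading change drawn
#' uniformly from [0, 30) degrees, TURN from (30, 150] degrees; REV is a
#' stop followed by a backward-crawl bout with the head vector opposing the
#' velocity.
#'
#' @param records a \code{response_records} data.frame (one label per larva
#'   per pulse). Must be non-empty.
#' @param protocol the \code{stimulus_protocol} whose pulse onsets the
#'   events are aligned to.
#' @param seed integer seed.
#' @param fps frame rate (default 15, the recording rate).
#' @param run_speed forward crawl speed in mm/s (default 0.5).
#' @param lead seconds of plain crawling recorded before the first onset
#'   (default 5).
#' @param tail seconds recorded after the last response window (default 3).
#' @return a list of \code{trajectory} objects, one per larva.
#' @export
generate_trajectories <- function(records, protocol, seed, fps = 15,
                                  run_speed = 0.5, lead = 5, tail = 3) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (nrow(records) == 0) stop_domain("records must be non-empty")
  if (!all(levels(records$label) == behavior_levels()) &&
      !all(as.character(records$label) %in% behavior_levels()))
    stop_domain("unknown behavior label in records")
  set.seed(derive_seed(seed, 3))
  onsets <- pulse_onsets(protocol)
  tmin <- protocol$t_start - lead
  tmax <- max(onsets) + 3 + tail
  ids <- unique(records$larva_id)
  lapply(ids, function(id) {
    rec <- records[records$larva_id == id, ]
    rec <- rec[order(rec$pulse_n), ]
    script <- as.character(rec$label)
    names(script) <- rec$pulse_n
    realize_one_trajectory(id, script, onsets[rec$pulse_n + 1], tmin, tmax,
                           fps, run_speed)
  })
}

# Build one larva's path from a label script aligned to onset times.
#' @noRd
realize_one_trajectory <- function(id, script, onsets, tmin, tmax, fps,
                                   run_speed) {
  dt <- 1 / fps
  t <- seq(tmin, tmax, by = dt)
  nf <- length(t)
  speed <- rep(run_speed, nf)
  heading <- numeric(nf)          # motion heading per frame
  headvec <- numeric(nf)          # head-orientation heading per frame
  cur <- stats::runif(1, 0, 2 * pi)
  heading[] <- cur
  headvec[] <- cur
  back_speed <- 0.6 * run_speed

  set_range <- function(from, to, spd, mh, hh) {
    sel <- t >= from & t < to
    speed[sel] <<- spd
    heading[sel] <<- mh
    headvec[sel] <<- hh
  }
  set_from <- function(from, mh) {
    sel <- t >= from
    heading[sel] <<- mh
    headvec[sel] <<- mh
    speed[sel] <<- run_speed
  }

  for (i in seq_along(script)) {
    lab <- script[i]
    t0 <- onsets[i]
    if (lab == "CONT") next
    if (lab %in% c("PAUSE", "TURN")) {
      set_range(t0 + 0.2, t0 + 1.4, 0, cur, cur)
      dth <- if (lab == "PAUSE") stats::runif(1, 0, 30) else
        stats::runif(1, 30 + 1e-6, 150)
      dth <- dth * pi / 180 * sample(c(-1, 1), 1)
      cur <- cur + dth
      set_from(t0 + 1.4, cur)
    } else if (lab == "REV") {
      set_range(t0 + 0.2, t0 + 1.0, 0, cur, cur)
      # backward crawl: body retreats while the head keeps pointing forward
      set_range(t0 + 1.0, t0 + 2.2, back_speed, cur + pi, cur)
      set_range(t0 + 2.2, t0 + 2.5, 0, cur, cur)
      cur <- cur + pi + stats::runif(1, -50, 50) * pi / 180
      set_from(t0 + 2.5, cur)
    } else {
      stop_domain("unknown behavior label: ", lab)
    }
  }

  x <- cumsum(c(0, speed[-nf] * cos(heading[-nf]) * dt))
  y <- cumsum(c(0, speed[-nf] * sin(heading[-nf]) * dt))
  trajectory(id, t, x, y, cos(headvec), sin(headvec))
}

#' Write/read trajectory CSV
#'
#' Dialect (one row per frame): \code{larva_id, t_s, x_mm, y_mm, head_dx,
#' head_dy}; mandatory header row; UTF-8; "." decimal separator. Multiple
#' larvae are concatenated and distinguished by \code{larva_id}.
#'
#' @param trajs a list of \code{trajectory} objects (or a single one).
#' @param path file path.
#' @return \code{path} (write); a list of \code{trajectory} objects (read).
#' @export
write_trajectories_csv <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, function(tr)
    data.frame(larva_id = tr$larva_id, t_s = tr$t, x_mm = tr$x, y_mm = tr$y,
               head_dx = tr$head_dx, head_dy = tr$head_dy)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("larva_id", "t_s", "x_mm", "y_mm", "head_dx", "head_dy")
  if (!all(need %in% names(df)))
    stop_domain("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$larva_id), function(d)
    trajectory(d$larva_id[1], d$t_s, d$x_mm, d$y_mm, d$head_dx, d$head_dy))
}
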