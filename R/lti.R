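# Linear time-invariant (LTI) impulse-response prediction.
#
# If the behavioral response were linear and time-invariant, the response
# R to any stimulus S would be the discrete convolution R[t] = sum_tau
# S[tau] h[t - tau] of the stimulus with the impulse response function h,
# measured by delivering a near-delta vibration burst (T_ON = 1 s, long
# period) and recording the baseline-subtracted reversal fraction. The
# package uses this predictor to demonstrate that the measured dynamics
# are NOT LTI: under continuous stimulation the animals return to baseline
# while the LTI prediction stays elevated.

#' Construct an impulse-response object
#'
#' @param h numeric response series on a uniform grid.
#' @param dt grid step in seconds (> 0), default 1 (the convolution time
#'   step used throughout).
#' @param t0 impulse onset time (s), default 0.
#' @return object of class \code{impulse_response}.
#' @export
impulse_response <- function(h, dt = 1, t0 = 0) {
  if (dt <= 0) stop_domain("dt must be > 0")
  if (any(!is.finite(h))) stop_domain("h must be finite")
  structure(list(h = as.numeric(h), dt = dt, t0 = t0),
            class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("impulse_response: %d bins, dt = %g s, peak = %.4f\n",
              length(x$h), x$dt, max(x$h)))
  invisible(x)
}

#' Predict a response by LTI convolution
#'
#' Computes the causal discrete convolution \eqn{R[t] = \sum_\tau S[\tau]
#' h[t - \tau]} of a stimulus series with an impulse response on a common
#' time step.
#'
#' @param h an \code{impulse_response}, or a numeric vector (then
#'   \code{dt} is taken from the stimulus).
#' @param stimulus numeric stimulus series S on the same time step.
#' @param dt time step of \code{stimulus} in seconds (default 1); must
#'   match \code{h$dt} when \code{h} is an \code{impulse_response}.
#' @return numeric response series of length
#'   \code{length(stimulus) + length(h) - 1}.
#' @export
lti_predict <- function(h, stimulus, dt = 1) {
  if (inherits(h, "impulse_response")) {
    if (abs(h$dt - dt) > 1e-12)
      stop_domain("time step mismatch: h$dt = ", h$dt, ", dt = ", dt)
    h <- h$h
  }
  if (length(h) == 0 || length(stimulus) == 0)
    stop_domain("empty series")
  if (length(stimulus) == 1)
    return(stimulus * h)
  stats::convolve(stimulus, rev(h), type = "open")
}

#' Extract an impulse response from impulse-protocol data
#'
#' Averages the baseline-subtracted reversal fraction over the repetitions
#' of a near-delta pulse (T_ON no longer than one bin, long period), then
#' truncates the tail where the average has returned to within one SEM of
#' the baseline.
#'
#' @param timeseries a \code{fraction_timeseries} (columns \code{t},
#'   \code{f_rev}, \code{n}).
#' @param protocol the impulse \code{stimulus_protocol}
#'   (\code{t_on <= dt}).
#' @param baseline baseline reversal fraction; default: mean of
#'   \code{f_rev} before the first onset, or the series minimum when no
#'   pre-onset data exist.
#' @param truncate if TRUE (default), drop trailing bins once the averaged
#'   response stays within one SEM of the baseline for 3 consecutive bins.
#' @return an \code{impulse_response} (h starts at the impulse onset).
#' @export
extract_irf <- function(timeseries, protocol, baseline = NULL,
                        truncate = TRUE) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  dt <- attr(timeseries, "dt")
  if (is.null(dt)) dt <- stats::median(diff(timeseries$t))
  if (protocol$t_on > dt + 1e-9)
    stop_domain("impulse protocol requires t_on <= dt")
  onsets <- pulse_onsets(protocol)
  period <- protocol_period(protocol)
  if (is.null(baseline)) {
    pre <- timeseries$f_rev[timeseries$t < onsets[1]]
    if (length(pre) > 0) {
      baseline <- mean(pre)
    } else {
      # no pre-onset data: use the far tail of each inter-pulse interval,
      # where the response has long since relaxed
      tail_sel <- Reduce(`|`, lapply(onsets, function(o)
        timeseries$t >= o + period / 2 & timeseries$t < o + period))
      baseline <- if (any(tail_sel)) mean(timeseries$f_rev[tail_sel]) else
        min(timeseries$f_rev)
    }
  }
  nbin <- floor(period / dt)
  reps <- lapply(onsets, function(o) {
    sel <- timeseries$t >= o & timeseries$t < o + nbin * dt
    v <- timeseries$f_rev[sel]
    length(v) <- nbin              # pad with NA past the record end
    v
  })
  m <- do.call(cbind, reps)
  have <- rowSums(!is.na(m)) > 0
  if (!any(have)) stop_domain("no post-impulse data")
  m <- m[have, , drop = FALSE]
  avg <- rowMeans(m, na.rm = TRUE) - baseline
  nrep <- rowSums(!is.na(m))
  sdrow <- apply(m, 1, stats::sd, na.rm = TRUE)
  sem <- ifelse(nrep > 1, sdrow / sqrt(nrep),
                sqrt(pmax(baseline * (1 - baseline), 1e-6) /
                       max(timeseries$n)))
  if (truncate && length(avg) > 3) {
    inside <- abs(avg) <= pmax(sem, 1e-12)
    run <- 0; cut <- length(avg)
    for (i in seq_along(inside)) {
      run <- if (inside[i]) run + 1 else 0
      if (run >= 3 && i > 3) { cut <- i - run + 1; break }
    }
    avg <- avg[seq_len(cut)]
  }
  impulse_response(avg, dt = dt, t0 = onsets[1])
}
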