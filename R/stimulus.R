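# Vibration stimulus protocols: pulse-train timing and intensity.
#
# A protocol is parameterized by the vibration frequency f (Hz), the
# dimensionless peak acceleration Gamma = A * omega^2 / g, the pulse
# duration t_on (s), the inter-pulse gap t_off (s) and the number of pulses.
# Pulse n occupies the half-open interval
#   [t_start + n*(t_on + t_off), t_start + n*(t_on + t_off) + t_on).

#' Standard gravity used in the Gamma/amplitude conversion (m/s^2)
#' @export
STANDARD_GRAVITY <- 9.81

#' Construct a vibration stimulus protocol
#'
#' @param frequency_hz vibration frequency in Hz (> 0).
#' @param gamma dimensionless peak acceleration \eqn{\Gamma = A\omega^2/g}
#'   (>= 0). \code{gamma = 0} describes a no-stimulus control.
#' @param t_on pulse duration in seconds (> 0).
#' @param t_off gap between pulses in seconds (>= 0). A continuous stimulus
#'   is represented as \code{t_off = 0, n_pulses = 1} with \code{t_on} equal
#'   to the recording duration.
#' @param n_pulses number of pulses (>= 1).
#' @param t_start onset time of the first pulse in seconds (default 0).
#' @return an object of class \code{stimulus_protocol}.
#' @examples
#' p <- stimulus_protocol(500, 2, t_on = 10, t_off = 20, n_pulses = 10)
#' pulse_onsets(p)
#' @export
stimulus_protocol <- function(frequency_hz, gamma, t_on, t_off, n_pulses,
                              t_start = 0) {
  if (!is.numeric(frequency_hz) || frequency_hz <= 0)
    stop_domain("frequency_hz must be > 0")
  if (!is.numeric(gamma) || gamma < 0)
    stop_domain("gamma must be >= 0")
  if (!is.numeric(t_on) || t_on <= 0)
    stop_domain("t_on must be > 0")
  if (!is.numeric(t_off) || t_off < 0)
    stop_domain("t_off must be >= 0")
  if (!is.numeric(n_pulses) || n_pulses < 1 || n_pulses != round(n_pulses))
    stop_domain("n_pulses must be a positive integer")
  structure(
    list(frequency_hz = frequency_hz, gamma = gamma, t_on = t_on,
         t_off = t_off, n_pulses = as.integer(n_pulses), t_start = t_start),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "stimulus_protocol: f = %g Hz, Gamma = %g, T_ON = %g s, T_OFF = %g s, %d pulse(s), t_start = %g s\n",
    x$frequency_hz, x$gamma, x$t_on, x$t_off, x$n_pulses, x$t_start))
  invisible(x)
}

#' Pulse period T = T_ON + T_OFF of a protocol
#' @param protocol a \code{stimulus_protocol}.
#' @return the period in seconds.
#' @export
protocol_period <- function(protocol) protocol$t_on + protocol$t_off

#' Total time spanned by a protocol
#' @param protocol a \code{stimulus_protocol}.
#' @return time (s) from \code{t_start} to the end of the last pulse's period.
#' @export
protocol_span <- function(protocol) {
  protocol$t_start + protocol$n_pulses * protocol_period(protocol)
}

#' Onset times of all pulses
#'
#' @param protocol a \code{stimulus_protocol}.
#' @return strictly increasing numeric vector
#'   \code{t_start + n * (t_on + t_off)} for \code{n = 0 .. n_pulses - 1}.
#' @export
pulse_onsets <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  protocol$t_start + (seq_len(protocol$n_pulses) - 1) * protocol_period(protocol)
}

#' Is the stimulus ON at time t?
#'
#' ON intervals are half-open: \code{[onset, onset + t_on)}.
#'
#' @param protocol a \code{stimulus_protocol}.
#' @param t numeric vector of times (s).
#' @return logical vector, TRUE where t falls inside some pulse.
#' @export
is_on <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  period <- protocol_period(protocol)
  phase <- t - protocol$t_start
  k <- floor(phase / period)
  within <- phase - k * period
  t >= protocol$t_start & k < protocol$n_pulses & within < protocol$t_on
}

#' Convert dimensionless peak acceleration to displacement amplitude
#'
#' For sinusoidal vertical vibration \eqn{z(t) = A \sin 2\pi f t}, the
#' dimensionless peak acceleration is \eqn{\Gamma = A \omega^2 / g} with
#' \eqn{\omega = 2\pi f}, so \eqn{A = \Gamma g / (2\pi f)^2}.
#'
#' @param gamma dimensionless peak acceleration (>= 0).
#' @param frequency_hz vibration frequency in Hz (> 0).
#' @return displacement amplitude A in meters.
#' @export
amplitude_for_gamma <- function(gamma, frequency_hz) {
  if (any(frequency_hz <= 0)) stop_domain("frequency_hz must be > 0")
  gamma * STANDARD_GRAVITY / (2 * pi * frequency_hz)^2
}

#' Convert displacement amplitude to dimensionless peak acceleration
#'
#' Inverse of [amplitude_for_gamma()].
#'
#' @param amplitude displacement amplitude A in meters.
#' @param frequency_hz vibration frequency in Hz (> 0).
#' @return dimensionless peak acceleration \eqn{\Gamma}.
#' @export
gamma_for_amplitude <- function(amplitude, frequency_hz) {
  if (any(frequency_hz <= 0)) stop_domain("frequency_hz must be > 0")
  amplitude * (2 * pi * frequency_hz)^2 / STANDARD_GRAVITY
}

#' Write a stimulus protocol to JSON
#'
#' Serialized keys: \code{frequency_hz, gamma, t_on_s, t_off_s, n_pulses,
#' t_start_s}.
#'
#' @param protocol a \code{stimulus_protocol}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  obj <- list(frequency_hz = protocol$frequency_hz, gamma = protocol$gamma,
              t_on_s = protocol$t_on, t_off_s = protocol$t_off,
              n_pulses = protocol$n_pulses, t_start_s = protocol$t_start)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stimulus protocol from JSON
#'
#' @param path JSON file written by [write_protocol_json()].
#' @return a \code{stimulus_protocol}.
#' @export
read_protocol_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_protocol(obj$frequency_hz, obj$gamma, obj$t_on_s, obj$t_off_s,
                    obj$n_pulses, if (is.null(obj$t_start_s)) 0 else obj$t_start_s)
}
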