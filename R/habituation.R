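# Habituation kinetics: de-sensitization and re-sensitization models.
#
# During sustained vibration the reversal fraction decays exponentially
# (de-sensitization),
#     F_REV(t) = F0_REV * exp(-t / tau_des)            [OFF -> ON]
# and while the stimulus is off, sensitivity recovers (re-sensitization),
#     F_REV(T_OFF) = F0_REV * (1 - exp(-T_OFF / tau_res))   [ON -> OFF].
# The re-sensitization time constant is pulse-indexed: tau_res(k) governs
# recovery during the OFF gap that follows pulse k, and collapses to well
# under a second after a few pulses.

#' Habituation parameters
#'
#' Bundles the amplitude and time constants of the de-/re-sensitization
#' model for one strain/condition.
#'
#' @param f0_rev naive (fully sensitized) reversal fraction at stimulus
#'   onset. Default 0.55: above half the population reverse-crawls at the
#'   strong reference condition (f = 500 Hz, Gamma = 2).
#' @param tau_des de-sensitization time constant in seconds.
#' @param tau_res0 re-sensitization time constant (s) governing recovery
#'   after the first pulses.
#' @param tau_res_late re-sensitization time constant (s) after repeated
#'   pulses; default 0.8 s, i.e. recovery completes in under a second.
#' @param n_slow number of initial OFF gaps governed by \code{tau_res0}
#'   (default 2: gaps after pulses 0 and 1).
#' @param baseline_rev spontaneous (no stimulus) reversal fraction,
#'   default 0.03.
#' @param tau_res_schedule optional explicit numeric vector overriding the
#'   two-level schedule: element k+1 is tau_res(k) for the gap after pulse k.
#'   Gaps beyond its length reuse the last element.
#' @return an object of class \code{habituation_params}.
#' @export
habituation_params <- function(f0_rev = 0.55, tau_des = 18.9, tau_res0 = 5.3,
                               tau_res_late = 0.8, n_slow = 2,
                               baseline_rev = 0.03, tau_res_schedule = NULL) {
  stopifnot(tau_des > 0, tau_res0 > 0, tau_res_late > 0,
            f0_rev >= 0, f0_rev <= 1, baseline_rev >= 0, baseline_rev <= 1)
  if (!is.null(tau_res_schedule) && any(tau_res_schedule <= 0))
    stop_domain("tau_res_schedule entries must be > 0")
  structure(
    list(f0_rev = f0_rev, tau_des = tau_des, tau_res0 = tau_res0,
         tau_res_late = tau_res_late, n_slow = as.integer(n_slow),
         baseline_rev = baseline_rev, tau_res_schedule = tau_res_schedule),
    class = "habituation_params"
  )
}

#' @export
print.habituation_params <- function(x, ...) {
  cat(sprintf(
    "habituation_params: F0_REV = %g, tau_des = %g s, tau_res(0) = %g s, tau_res(late) = %g s, baseline = %g\n",
    x$f0_rev, x$tau_des, x$tau_res0, x$tau_res_late, x$baseline_rev))
  invisible(x)
}

#' Strain presets for habituation time constants
#'
#' Printed time constants for the Canton-S wild type and three
#' memory-deficient mutants: \emph{rut} (rutabaga), \emph{dnc} (dunce) and
#' \emph{cam0} (calmodulin null).
#'
#' @param name one of \code{"wildtype"}, \code{"rut"}, \code{"dnc"},
#'   \code{"cam0"}.
#' @param ... further arguments passed to [habituation_params()].
#' @return a \code{habituation_params} object for the strain.
#' @export
strain_preset <- function(name = c("wildtype", "rut", "dnc", "cam0"), ...) {
  name <- match.arg(name)
  tab <- list(wildtype = c(18.9, 5.3), rut = c(5.2, 3.6),
              dnc = c(14.3, 9.8), cam0 = c(25.6, 6.5))
  v <- tab[[name]]
  habituation_params(tau_des = v[1], tau_res0 = v[2], ...)
}

#' Re-sensitization time constant for the gap after pulse k
#'
#' @param params a \code{habituation_params}.
#' @param k pulse index (>= 0) whose following OFF gap is queried; vectorized.
#' @return tau_res(k) in seconds.
#' @export
tau_res_at <- function(params, k) {
  stopifnot(inherits(params, "habituation_params"))
  if (any(k < 0) || any(k != round(k)))
    stop_domain("pulse index k must be a non-negative integer")
  if (!is.null(params$tau_res_schedule)) {
    sch <- params$tau_res_schedule
    return(sch[pmin(k + 1, length(sch))])
  }
  ifelse(k < params$n_slow, params$tau_res0, params$tau_res_late)
}

#' De-sensitization decay curve
#'
#' \eqn{F_{REV}(t) = F_{0,REV} e^{-t/\tau_{des}}}, optionally offset by the
#' baseline reversal fraction (the offset form
#' \eqn{y_0 + A e^{-t/\tau}} is the one used for fitting).
#'
#' @param params a \code{habituation_params}.
#' @param t time since stimulus onset (s), vectorized, >= 0.
#' @param offset if TRUE, return
#'   \code{baseline + (f0_rev - baseline) * exp(-t/tau_des)} so the curve
#'   relaxes to the baseline instead of zero.
#' @return reversal fraction.
#' @export
desensitization_curve <- function(params, t, offset = FALSE) {
  stopifnot(inherits(params, "habituation_params"))
  if (any(t < 0)) stop_domain("t must be >= 0")
  if (offset) {
    params$baseline_rev +
      (params$f0_rev - params$baseline_rev) * exp(-t / params$tau_des)
  } else {
    params$f0_rev * exp(-t / params$tau_des)
  }
}

#' Re-sensitization recovery curve
#'
#' Fraction of sensitivity recovered after the stimulus has been off for
#' \code{t_off} seconds preceding pulse \code{pulse_n}:
#' \eqn{1 - e^{-T_{OFF}/\tau_{res}(n-1)}}. The first pulse (\code{pulse_n =
#' 0}) has no preceding gap and is defined as fully recovered (factor 1).
#'
#' @param params a \code{habituation_params}.
#' @param t_off OFF duration in seconds (>= 0), vectorized.
#' @param pulse_n index of the pulse being recovered into (>= 0).
#' @param absolute if TRUE, scale by \code{f0_rev} to give an absolute
#'   reversal fraction rather than a recovery fraction.
#' @return recovery fraction in [0, 1] (or absolute fraction).
#' @export
resensitization_curve <- function(params, t_off, pulse_n, absolute = FALSE) {
  stopifnot(inherits(params, "habituation_params"))
  if (any(t_off < 0)) stop_domain("t_off must be >= 0")
  r <- if (pulse_n == 0) rep(1, length(t_off))
       else 1 - exp(-t_off / tau_res_at(params, pulse_n - 1))
  if (absolute) params$f0_rev * r else r
}

#' Predicted reversal-event fraction for a pulse train
#'
#' Evaluates the predictive habituation model on a uniform grid: during the
#' ON window of pulse n,
#' \deqn{F_{REV}(t) = F_{0,REV}\, r_n\, e^{-(t - nT)/\tau_{des}},}
#' with \eqn{r_0 = 1} and \eqn{r_n = 1 - e^{-T_{OFF}/\tau_{res}(n-1)}}, and
#' \eqn{F_{REV}(t) = 0} while the stimulus is OFF (the model describes the
#' probability of reversal events evoked by the stimulus, not a state).
#'
#' @param params a \code{habituation_params}.
#' @param protocol a \code{stimulus_protocol}.
#' @param dt grid resolution in seconds (default 1).
#' @param cumulative if TRUE, each pulse's recovery factor multiplies the
#'   accumulated factors of all earlier pulses
#'   (\eqn{\prod_{k \le n} r_k}) instead of \eqn{r_n} alone, so incomplete
#'   recoveries compound across the train.
#' @param persistence optional extra per-pulse persistence factor rho in
#'   (0, 1]: peak n is additionally scaled by rho^n. This models the residual
#'   habituation layer that makes successive peaks decline even when OFF
#'   gaps are long enough for full tau_res recovery. Default \code{NULL}
#'   (no extra factor, the bare predictive model).
#' @return data.frame with columns \code{t} (bin centers, s) and
#'   \code{f_rev} (model expectation).
#' @export
predict_pulse_train <- function(params, protocol, dt = 1, cumulative = FALSE,
                                persistence = NULL) {
  stopifnot(inherits(params, "habituation_params"),
            inherits(protocol, "stimulus_protocol"))
  if (dt <= 0) stop_domain("dt must be > 0")
  onsets <- pulse_onsets(protocol)
  n_pulse <- protocol$n_pulses
  r <- vapply(seq_len(n_pulse) - 1L, function(n)
    resensitization_curve(params, protocol$t_off, n), numeric(1))
  amp <- if (cumulative) cumprod(r) else r
  if (!is.null(persistence)) {
    stopifnot(persistence > 0, persistence <= 1)
    amp <- amp * persistence^(seq_len(n_pulse) - 1L)
  }
  t <- seq(protocol$t_start, protocol_span(protocol), by = dt)
  t <- t + dt / 2
  t <- t[t < protocol_span(protocol)]
  f <- numeric(length(t))
  on <- is_on(protocol, t)
  if (any(on)) {
    idx <- pmax(1L, pmin(n_pulse,
      floor((t[on] - protocol$t_start) / protocol_period(protocol)) + 1L))
    f[on] <- params$f0_rev * amp[idx] *
      exp(-(t[on] - onsets[idx]) / params$tau_des)
  }
  data.frame(t = t, f_rev = f)
}
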