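# High-level analysis procedures combining the generator with the fits —
# the standard experiment designs used for time-constant recovery.

#' De-sensitization recovery experiment
#'
#' Simulates binned reversal counts for a population under continuous
#' vibration (single uninterrupted pulse at the reference intensity) and
#' fits the fixed-offset exponential to the reversal-fraction series,
#' recovering the de-sensitization time constant.
#'
#' @param config a \code{generator_config}.
#' @param duration recording duration in seconds (default 120, several
#'   multiples of the slowest preset's time constant).
#' @param frequency_hz,gamma stimulus intensity (defaults 500 Hz, Gamma =
#'   2 — the strong reference condition).
#' @param n_boot bootstrap resamples (default 1000).
#' @return list with \code{fit} (a \code{fit_result}), \code{timeseries}
#'   (the fraction series) and \code{protocol}.
#' @export
desensitization_experiment <- function(config, duration = 120,
                                       frequency_hz = 500, gamma = 2,
                                       n_boot = 1000) {
  protocol <- stimulus_protocol(frequency_hz, gamma, t_on = duration,
                                t_off = 0, n_pulses = 1)
  counts <- generate_count_timeseries(config, protocol, duration)
  fts <- as_fraction_timeseries(counts)
  sem <- binomial_sem(counts$n_rev, counts$n_active)
  y0 <- config$baseline_rev
  # IRLS: model-based binomial weights, so early high-variance bins do not
  # dominate and zero-count baseline bins are not over-weighted
  fit <- fit_exponential(fts$t, fts$f_rev, sem, y0 = y0, n_boot = 0)
  w <- NULL
  for (i in 1:2) {
    p_hat <- clip01(y0 + fit$amplitude * exp(-fts$t / fit$tau))
    w <- fts$n / pmax(p_hat * (1 - p_hat), 5e-3)
    fit <- fit_exponential(fts$t, fts$f_rev, sem, y0 = y0,
                           n_boot = if (i == 2) n_boot else 0,
                           seed = derive_seed(config$seed, 20), weights = w)
  }
  list(fit = fit, timeseries = fts, protocol = protocol)
}

#' Re-sensitization recovery experiment family
#'
#' Simulates one pulse-train experiment per OFF duration (shared T_ON and
#' intensity, 100 larvae each by convention) and runs the recovery-ratio
#' analysis, fitting the re-sensitization time constant for each requested
#' pulse.
#'
#' @param config a \code{generator_config}; each condition derives its own
#'   seed from \code{config$seed}.
#' @param t_offs OFF durations in seconds
#'   (default c(0.5, 1, 2, 5, 10, 20, 40)).
#' @param t_on pulse duration (default 30 s, long enough for the
#'   population to habituate back to baseline within each pulse).
#' @param n_pulses pulses per experiment (default 5).
#' @param pulses pulse indices to fit (default 1, the first recovery).
#' @param frequency_hz,gamma stimulus intensity.
#' @param n_boot bootstrap resamples per fit.
#' @param method fit method, see [resensitization_ratios()].
#' @param tie_slow number of initial recovery curves sharing one time
#'   constant in the shared fit, see [resensitization_ratios()].
#' @return the [resensitization_ratios()] result (list with \code{ratios}
#'   and \code{fits}).
#' @export
resensitization_experiment <- function(config,
                                       t_offs = c(0.5, 1, 2, 5, 10, 20, 40),
                                       t_on = 30, n_pulses = 5, pulses = 1,
                                       frequency_hz = 500, gamma = 2,
                                       n_boot = 1000, method = "shared",
                                       tie_slow = 2) {
  record_sets <- lapply(seq_along(t_offs), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 30 + i)
    protocol <- stimulus_protocol(frequency_hz, gamma, t_on = t_on,
                                  t_off = t_offs[i], n_pulses = n_pulses)
    generate_response_records(cfg, protocol)
  })
  names(record_sets) <- paste0("t_off=", t_offs)
  resensitization_ratios(record_sets, t_offs, pulses = pulses,
                         n_boot = n_boot, seed = derive_seed(config$seed, 40),
                         method = method, tie_slow = tie_slow)
}
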