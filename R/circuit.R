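# Capacitor-switch circuit analog of habituation.
#
# A battery V charges a small capacitor C1 (Q1 = C1*V); every switch
# closing (period T) dumps Q1 onto a much larger capacitor C2, whose
# charge Q2 leaks through a resistor R with time constant R*C2:
#     Q2(t) = sum_n C1*V * theta(t - nT) * exp(-(t - nT)/(R*C2)),
# with C2 initially uncharged. Q2 is the accumulated "habituation"; the
# probability of the observed event (the reverse crawl) is P ~ exp(-Q2),
# so the event fraction is F(t) = F0 * exp(-Q2(t)).
#
# The C2 >> C1 idealization means the transferred packet is always the
# full Q1 regardless of C2's present charge; the summation above is
# implemented literally. By convention theta(0) = 1: querying t = nT gives
# the post-transfer value (pre-transfer values via the left-limit flag).

#' Circuit parameters for the habituation analog
#'
#' Units are arbitrary but mutually consistent.
#'
#' @param V battery voltage (default 1).
#' @param C1 small capacitor charged by the battery (default 1.2).
#' @param C2 large reservoir capacitor (default 160).
#' @param R leak resistance (default 1).
#' @param T_switch switch period T (default 30).
#' @param F0 event fraction at zero charge (default 0.55, the naive
#'   reversal fraction).
#' @return object of class \code{circuit_params}. Warns when C2/C1 < 10,
#'   since the full-packet transfer assumes C2 >> C1.
#' @export
circuit_params <- function(V = 1, C1 = 1.2, C2 = 160, R = 1, T_switch = 30,
                           F0 = 0.55) {
  if (any(c(V, C1, C2, R, T_switch) <= 0))
    stop_domain("all circuit parameters must be positive")
  if (F0 < 0 || F0 > 1) stop_domain("F0 must be in [0, 1]")
  if (C2 / C1 < 10)
    warning("C2/C1 < 10: the full-packet transfer assumption (C2 >> C1) is strained")
  structure(list(V = V, C1 = C1, C2 = C2, R = R, T_switch = T_switch,
                 F0 = F0),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("circuit_params: V = %g, C1 = %g, C2 = %g, R = %g, T = %g, F0 = %g\n",
              x$V, x$C1, x$C2, x$R, x$T_switch, x$F0))
  invisible(x)
}

#' Simulate the charge Q2 on the reservoir capacitor
#'
#' Term-by-term evaluation of the decaying-step summation.
#'
#' @param params a \code{circuit_params}.
#' @param t_grid increasing times >= 0.
#' @param left_limit if TRUE, evaluate t = nT just before the switch
#'   contribution at that instant (theta(0) treated as 0).
#' @return numeric Q2 series over \code{t_grid}.
#' @export
simulate_charge <- function(params, t_grid, left_limit = FALSE) {
  stopifnot(inherits(params, "circuit_params"))
  if (any(diff(t_grid) < 0)) stop_domain("t_grid must be increasing")
  q1 <- params$C1 * params$V
  tc <- params$R * params$C2
  period <- params$T_switch
  vapply(t_grid, function(t) {
    if (t < 0) return(0)
    n_max <- floor(t / period)
    ns <- 0:n_max
    dt <- t - ns * period
    keep <- if (left_limit) dt > 0 else dt >= 0
    sum(q1 * exp(-dt[keep] / tc))
  }, numeric(1))
}

#' Closed-form Q2 at switch instants
#'
#' Geometric-series value immediately after the (m+1)-th switch closing
#' (t = mT, post-transfer):
#' \eqn{Q_2(mT^+) = C_1 V (1 - x^{m+1}) / (1 - x)} with
#' \eqn{x = e^{-T/(R C_2)}}; saturates at \eqn{C_1 V / (1 - x)}.
#'
#' @param params a \code{circuit_params}.
#' @param m switch index (0-based), vectorized; \code{Inf} gives the
#'   saturation value.
#' @return Q2 at \code{t = mT} just after the transfer.
#' @export
charge_at_switch <- function(params, m) {
  stopifnot(inherits(params, "circuit_params"))
  x <- exp(-params$T_switch / (params$R * params$C2))
  q1 <- params$C1 * params$V
  ifelse(is.infinite(m), q1 / (1 - x), q1 * (1 - x^(m + 1)) / (1 - x))
}

#' Event fraction of the circuit model
#'
#' \eqn{F(t) = F_0 e^{-Q_2(t)}}.
#'
#' @param params a \code{circuit_params}.
#' @param t_grid increasing times >= 0.
#' @param left_limit passed to [simulate_charge()].
#' @return numeric event-fraction series.
#' @export
event_fraction <- function(params, t_grid, left_limit = FALSE) {
  params$F0 * exp(-simulate_charge(params, t_grid, left_limit))
}

#' Per-switch peak event fractions
#'
#' The event fraction evaluated at each switch-closing instant
#' \code{t = nT} (post-transfer) — the circuit analog of the per-pulse
#' peak reversal fractions. The series is monotone non-increasing and
#' converges to \code{F0 * exp(-Q2_sat)}.
#'
#' @param params a \code{circuit_params}.
#' @param n_switches number of switches (>= 1).
#' @return numeric vector of length \code{n_switches}.
#' @export
peak_series <- function(params, n_switches) {
  if (n_switches < 1) stop_domain("n_switches must be >= 1")
  ts <- (seq_len(n_switches) - 1) * params$T_switch
  event_fraction(params, ts)
}

#' Compare model peaks to empirical peaks with Fisher tests
#'
#' Converts both fraction series to counts at \code{n_per_peak} animals
#' and applies a two-sided Fisher's exact test per peak.
#'
#' @param model_peaks,empirical_peaks fraction series of equal length.
#' @param n_per_peak number of animals per peak (pooled N).
#' @return data.frame with \code{peak} (0-based), both fractions, and
#'   \code{p}.
#' @export
compare_peaks <- function(model_peaks, empirical_peaks, n_per_peak) {
  if (length(model_peaks) != length(empirical_peaks))
    stop_domain("peak series must have equal length")
  p <- mapply(function(a, b)
    fisher_compare(round(a * n_per_peak), n_per_peak,
                   round(b * n_per_peak), n_per_peak),
    model_peaks, empirical_peaks)
  data.frame(peak = seq_along(model_peaks) - 1L, model = model_peaks,
             empirical = empirical_peaks, p = p)
}

#' Run a circuit simulation from a JSON configuration
#'
#' Config keys: \code{V, C1, C2, R, T_switch, F0, n_switches, dt}. Writes
#' a tidy CSV \code{t_s, Q2, F} when \code{out} is given.
#'
#' @param config path to a JSON file or an equivalent named list.
#' @param out optional output CSV path.
#' @return data.frame with \code{t_s, Q2, F}, invisibly when writing.
#' @export
run_circuit <- function(config, out = NULL) {
  cfg <- if (is.character(config))
    jsonlite::read_json(config, simplifyVector = TRUE) else config
  par <- circuit_params(cfg$V, cfg$C1, cfg$C2, cfg$R, cfg$T_switch, cfg$F0)
  tmax <- cfg$n_switches * par$T_switch
  t <- seq(0, tmax, by = cfg$dt)
  q2 <- simulate_charge(par, t)
  df <- data.frame(t_s = t, Q2 = q2, F = par$F0 * exp(-q2))
  if (!is.null(out)) {
    utils::write.csv(df, out, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
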