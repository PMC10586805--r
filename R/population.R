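# Population-level response fractions and comparisons.
#
# F_ACTION = N_ACTION / N over the active larvae responding to a pulse;
# F_CONT + F_PAUSE + F_TURN + F_REV = 1 and F_STOP = F_PAUSE + F_TURN +
# F_REV by definition. Pairwise condition comparisons use two-sided
# Fisher's exact tests on the reversal counts.

#' Fractional behavioral response at one pulse
#'
#' Counts are taken over active larvae: records with NA or UNRESOLVED
#' labels at this pulse are excluded from N.
#'
#' @param records a \code{response_records} data.frame.
#' @param pulse_n pulse index (0-based).
#' @return object of class \code{population_fractions}: list with
#'   \code{pulse_n, n, counts} and fractions \code{f_cont, f_pause, f_turn,
#'   f_rev, f_stop}.
#' @export
response_fractions <- function(records, pulse_n) {
  rec <- records[records$pulse_n == pulse_n, ]
  lab <- as.character(rec$label)
  lab <- lab[!is.na(lab) & lab %in% behavior_levels()]
  n <- length(lab)
  if (n == 0) stop_domain("no active larvae at pulse ", pulse_n,
                          "; fractions undefined")
  counts <- vapply(behavior_levels(), function(l) sum(lab == l), integer(1))
  fr <- counts / n
  structure(
    list(pulse_n = pulse_n, n = n, counts = counts,
         f_cont = fr[["CONT"]], f_pause = fr[["PAUSE"]],
         f_turn = fr[["TURN"]], f_rev = fr[["REV"]],
         f_stop = fr[["PAUSE"]] + fr[["TURN"]] + fr[["REV"]]),
    class = "population_fractions"
  )
}

#' @export
print.population_fractions <- function(x, ...) {
  cat(sprintf(
    "pulse %d (N = %d): F_CONT = %.3f, F_PAUSE = %.3f, F_TURN = %.3f, F_REV = %.3f (F_STOP = %.3f)\n",
    x$pulse_n, x$n, x$f_cont, x$f_pause, x$f_turn, x$f_rev, x$f_stop))
  invisible(x)
}

#' Fractions for every pulse, as a tidy data.frame
#'
#' @param records a \code{response_records} data.frame.
#' @return data.frame with one row per pulse present in \code{records}:
#'   \code{pulse_n, n, f_cont, f_pause, f_turn, f_rev, f_stop}.
#' @export
fractions_by_pulse <- function(records) {
  pulses <- sort(unique(records$pulse_n))
  do.call(rbind, lapply(pulses, function(p) {
    f <- response_fractions(records, p)
    data.frame(pulse_n = p, n = f$n, f_cont = f$f_cont, f_pause = f$f_pause,
               f_turn = f$f_turn, f_rev = f$f_rev, f_stop = f$f_stop)
  }))
}

#' Binned fraction time series of instantaneous behavioral states
#'
#' @param states data.frame with one row per (larva, frame/bin):
#'   columns \code{larva_id}, \code{t} (s), logical \code{rev} and
#'   \code{stop} flags for the instantaneous state.
#' @param dt bin width in seconds (> 0).
#' @param t0 time of the first pulse onset; bins are aligned so that a bin
#'   edge falls at \code{t0} (default 0).
#' @return data.frame of class \code{fraction_timeseries} with columns
#'   \code{t} (bin centers), \code{n}, \code{f_rev}, \code{f_stop}.
#' @export
fraction_timeseries <- function(states, dt, t0 = 0) {
  if (dt <= 0) stop_domain("dt must be > 0")
  if (nrow(states) == 0) stop_domain("states must be non-empty")
  bin <- floor((states$t - t0) / dt)
  agg <- stats::aggregate(cbind(rev = states$rev, stop = states$stop,
                                one = rep(1L, nrow(states))),
                          by = list(bin = bin, larva_id = states$larva_id),
                          FUN = function(z) as.numeric(any(z > 0)))
  byb <- stats::aggregate(cbind(rev = agg$rev, stop = agg$stop,
                                n = rep(1L, nrow(agg))),
                          by = list(bin = agg$bin), FUN = sum)
  out <- data.frame(t = t0 + (byb$bin + 0.5) * dt, n = byb$n,
                    f_rev = byb$rev / byb$n, f_stop = byb$stop / byb$n)
  out <- out[order(out$t), ]
  rownames(out) <- NULL
  class(out) <- c("fraction_timeseries", "data.frame")
  attr(out, "dt") <- dt
  out
}

#' Convert a synthetic count time series to a fraction time series
#'
#' @param counts a \code{count_timeseries} from
#'   [generate_count_timeseries()].
#' @return a \code{fraction_timeseries} data.frame with columns \code{t, n,
#'   f_rev, f_stop} plus the zero-noise expectations.
#' @export
as_fraction_timeseries <- function(counts) {
  stopifnot(inherits(counts, "count_timeseries"))
  out <- data.frame(t = counts$t, n = counts$n_active,
                    f_rev = counts$n_rev / counts$n_active,
                    f_stop = counts$n_stop / counts$n_active,
                    p_rev = counts$p_rev, p_stop = counts$p_stop)
  class(out) <- c("fraction_timeseries", "data.frame")
  attr(out, "dt") <- attr(counts, "dt")
  out
}

#' Instantaneous behavioral state of each trajectory frame
#'
#' REV where the head-vector/velocity dot product is negative, STOP where
#' the frame lies inside a detected stop interval.
#'
#' @param traj a \code{trajectory}.
#' @param ... passed to [detect_stops()].
#' @return data.frame with columns \code{larva_id, t, rev, stop} suitable
#'   for [fraction_timeseries()].
#' @export
trajectory_states <- function(traj, ...) {
  kin <- trajectory_kinematics(traj)
  stops <- detect_stops(traj, ...)
  in_stop <- rep(FALSE, nrow(kin))
  for (i in seq_len(nrow(stops)))
    in_stop[kin$t >= stops$start_t[i] & kin$t <= stops$end_t[i]] <- TRUE
  rev <- kin$head_dot_vel < 0
  data.frame(larva_id = traj$larva_id[1], t = kin$t, rev = rev,
             stop = in_stop | rev)
}

#' Two-sided Fisher's exact test on two response counts
#'
#' Tests whether \code{k1/n1} and \code{k2/n2} (e.g. reversal counts out of
#' active larvae under two conditions) differ, from the 2x2 table
#' \code{[[k1, n1-k1], [k2, n2-k2]]}.
#'
#' @param k1,n1 successes and total for condition 1.
#' @param k2,n2 successes and total for condition 2.
#' @return the two-sided p-value.
#' @export
fisher_compare <- function(k1, n1, k2, n2) {
  if (any(c(k1, n1, k2, n2) < 0)) stop_domain("counts must be non-negative")
  if (k1 > n1 || k2 > n2) stop_domain("k must not exceed n")
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Summarize a grid of (f, Gamma) conditions with pairwise comparisons
#'
#' For each condition the initial reversal fraction and a Fisher test
#' against the no-stimulus baseline; for each pair of grid-adjacent
#' conditions (neighbors along the f or Gamma axis), a Fisher test between
#' their reversal counts. P-values are reported unadjusted at the 0.05
#' threshold.
#'
#' @param conditions data.frame with one row per condition: \code{f_hz},
#'   \code{gamma}, reversal count \code{k_rev} and active count \code{n}.
#' @param baseline list or row with \code{k_rev} and \code{n} for the
#'   no-stimulus control.
#' @param alpha significance threshold (default 0.05).
#' @return list with \code{conditions} (adds \code{f0_rev, p_vs_baseline,
#'   sig_vs_baseline}) and \code{edges} (one row per adjacent pair with
#'   \code{p} and \code{sig}).
#' @export
condition_grid <- function(conditions, baseline, alpha = 0.05) {
  if (nrow(conditions) < 2) stop_domain("need at least 2 conditions")
  cond <- conditions
  cond$f0_rev <- cond$k_rev / cond$n
  cond$p_vs_baseline <- mapply(function(k, n)
    fisher_compare(k, n, baseline$k_rev, baseline$n), cond$k_rev, cond$n)
  cond$sig_vs_baseline <- cond$p_vs_baseline < alpha
  fs <- sort(unique(cond$f_hz)); gs <- sort(unique(cond$gamma))
  edges <- list()
  for (i in seq_len(nrow(cond))) {
    for (j in seq_len(nrow(cond))) {
      if (j <= i) next
      fi <- match(cond$f_hz[i], fs); fj <- match(cond$f_hz[j], fs)
      gi <- match(cond$gamma[i], gs); gj <- match(cond$gamma[j], gs)
      adjacent <- (fi == fj && abs(gi - gj) == 1) ||
        (gi == gj && abs(fi - fj) == 1)
      if (!adjacent) next
      p <- fisher_compare(cond$k_rev[i], cond$n[i], cond$k_rev[j], cond$n[j])
      edges[[length(edges) + 1]] <- data.frame(
        i = i, j = j, f1 = cond$f_hz[i], gamma1 = cond$gamma[i],
        f2 = cond$f_hz[j], gamma2 = cond$gamma[j], p = p, sig = p < alpha)
    }
  }
  list(conditions = cond,
       edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(i = integer(0), j = integer(0), p = numeric(0),
                    sig = logical(0)))
}
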