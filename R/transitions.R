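# Individual-level behavioral transition matrices across pulses.
#
# For lag k, the entry (X, Y) is the percentage of larvae that responded
# with X at pulse n and with Y at pulse n + k, pooled over all starting
# pulses n and all larvae. Each defined row sums to 100. Habituation is
# one-way at the individual level: transitions from weaker behaviors into
# reverse crawling essentially never occur.

#' Behavioral transition matrix at a given lag
#'
#' @param records a \code{response_records} data.frame spanning at least
#'   \code{lag + 1} pulses per larva. Pairs containing NA or UNRESOLVED
#'   labels are dropped (no imputation).
#' @param lag pulse lag k >= 1 (default 1).
#' @param stratify_by_pulse if TRUE, additionally return per-starting-pulse
#'   count tables.
#' @return object of class \code{transition_matrix}: list with
#'   \code{percent} (4x4, rows summing to 100, NA rows where the from-label
#'   never occurs), \code{counts}, \code{n_transitions}, \code{lag}.
#' @export
transition_matrix <- function(records, lag = 1, stratify_by_pulse = FALSE) {
  if (lag < 1 || lag != round(lag)) stop_domain("lag must be a positive integer")
  lv <- behavior_levels()
  rec <- records[!is.na(records$label) &
                   as.character(records$label) %in% lv, ]
  counts <- matrix(0L, 4, 4, dimnames = list(from = lv, to = lv))
  strat <- list()
  by_larva <- split(rec, rec$larva_id)
  for (d in by_larva) {
    idx <- match(d$pulse_n + lag, d$pulse_n)
    ok <- !is.na(idx)
    if (!any(ok)) next
    from <- as.character(d$label[ok])
    to <- as.character(d$label[idx[ok]])
    for (i in seq_along(from))
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
    if (stratify_by_pulse) {
      for (i in seq_along(from)) {
        key <- as.character(d$pulse_n[ok][i])
        if (is.null(strat[[key]]))
          strat[[key]] <- matrix(0L, 4, 4, dimnames = list(from = lv, to = lv))
        strat[[key]][from[i], to[i]] <- strat[[key]][from[i], to[i]] + 1L
      }
    }
  }
  n_trans <- sum(counts)
  if (n_trans == 0) stop_domain("no valid transition pairs at lag ", lag)
  rs <- rowSums(counts)
  percent <- 100 * counts / ifelse(rs > 0, rs, NA)
  structure(
    list(percent = percent, counts = counts, n_transitions = n_trans,
         lag = lag,
         by_pulse = if (stratify_by_pulse) strat else NULL),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix (lag %d, %d transitions), row percentages:\n",
              x$lag, x$n_transitions))
  print(round(x$percent, 1))
  invisible(x)
}

#' Count violations of one-way habituation
#'
#' A violation is any observed transition from a non-REV behavior into REV.
#'
#' @param matrix a \code{transition_matrix}.
#' @return list with \code{n_violations} (total offending transition
#'   count) and \code{violations} (data.frame of offending entries with
#'   their counts and percentages).
#' @export
one_way_violations <- function(matrix) {
  stopifnot(inherits(matrix, "transition_matrix"))
  from <- c("CONT", "PAUSE", "TURN")
  counts <- matrix$counts[from, "REV"]
  off <- which(counts > 0)
  viol <- data.frame(from = from[off], to = rep("REV", length(off)),
                     count = as.integer(counts[off]),
                     percent = matrix$percent[from, "REV"][off])
  list(n_violations = sum(counts), violations = viol)
}

#' Write a transition matrix as labeled CSV
#'
#' 4x4 row-percentage table with labeled rows/columns, followed by an
#' \code{n_transitions} metadata row.
#'
#' @param matrix a \code{transition_matrix}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_transition_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "transition_matrix"))
  df <- as.data.frame(matrix$percent)
  df <- cbind(from = rownames(matrix$percent), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  cat(sprintf("n_transitions,%d,,,\n", matrix$n_transitions),
      file = path, append = TRUE)
  invisible(path)
}
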