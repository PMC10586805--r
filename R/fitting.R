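# Exponential fits with parametric-bootstrap uncertainties, and the
# re-sensitization ratio analysis.
#
# De-/re-sensitization time constants come from least-squares fits of
# y0 + A*exp(-t/tau) (y0 fixed at the baseline) or a*(1 - exp(-t/tau)).
# Fit uncertainty follows the parametric bootstrap: each data point is
# resampled from a Gaussian centered at its value with its SEM as width,
# the fit repeated (1000 times by default), and the standard deviation of
# the fitted constants reported as the uncertainty. Fits are compared with
# a statistic built on the bootstrap-set standard deviations (not SEMs),
# so the number of resamples does not affect significance.

#' Fit a fixed-offset exponential decay with bootstrap uncertainty
#'
#' Least-squares fit of \eqn{y_0 + A e^{-t/\tau}} with \eqn{y_0} fixed at
#' the supplied baseline. Uncertainty: \code{n_boot} Gaussian resamples of
#' each point (mean = value, sd = its SEM, negative resamples clipped to
#' 0) are refit independently; the sd of the resampled \eqn{\tau} values
#' is \code{sd_tau}.
#'
#' @param t times (s), >= 4 points.
#' @param f observed fractions at \code{t}.
#' @param sem per-point SEM (>= 0); scalar or vector. All-zero SEMs give
#'   \code{sd_tau = 0}.
#' @param y0 fixed offset (the baseline fraction).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed for the resampling.
#' @param tau_bounds,a_bounds box constraints for the optimizer.
#' @param weights optional least-squares weights for the point fit
#'   (default: unweighted; the SEMs enter through the bootstrap).
#' @return object of class \code{fit_result}: \code{tau}, \code{amplitude},
#'   \code{y0}, \code{sd_tau}, \code{n_boot}, \code{seed}, \code{boot_tau}
#'   (the bootstrap set), \code{converged}.
#' @export
fit_exponential <- function(t, f, sem = 0, y0, n_boot = 1000, seed = 1,
                            tau_bounds = c(0.1, 300), a_bounds = c(0, 1),
                            weights = NULL) {
  if (length(t) < 4) stop_domain("need at least 4 points")
  if (length(sem) == 1) sem <- rep(sem, length(t))
  if (any(sem < 0)) stop_domain("sem must be >= 0")
  model <- function(p, tt) y0 + p[2] * exp(-tt / p[1])
  fit <- fit_curve(t, f, model,
                   start = c(tau = 10,
                             A = min(max(f[which.min(t)] - y0, a_bounds[1] + 1e-3),
                                     a_bounds[2])),
                   lower = c(tau_bounds[1], a_bounds[1]),
                   upper = c(tau_bounds[2], a_bounds[2]),
                   weights = weights)
  boot <- bootstrap_taus(t, f, sem, model, fit, n_boot, seed,
                         lower = c(tau_bounds[1], a_bounds[1]),
                         upper = c(tau_bounds[2], a_bounds[2]),
                         weights = weights)
  structure(
    list(tau = fit$par[1], amplitude = fit$par[2], y0 = y0,
         sd_tau = stats::sd(boot), n_boot = n_boot, seed = seed,
         boot_tau = boot, converged = fit$converged),
    class = "fit_result"
  )
}

#' Fit a saturating-recovery curve with bootstrap uncertainty
#'
#' Least-squares fit of \eqn{a (1 - e^{-t/\tau})} to recovery-ratio data.
#' The free amplitude \eqn{a} absorbs the incomplete-recovery plateau, so
#' the normalized curve \code{ratio / a} asymptotes to 1.
#'
#' @param t_off OFF durations (s).
#' @param ratio observed recovery ratios.
#' @param sem per-point SEM (>= 0).
#' @param n_boot,seed,tau_bounds as in [fit_exponential()].
#' @param a_bounds box constraints for the plateau amplitude.
#' @return a \code{fit_result}; \code{amplitude} is the plateau \eqn{a}.
#' @export
fit_recovery <- function(t_off, ratio, sem = 0, n_boot = 1000, seed = 1,
                         tau_bounds = c(0.05, 300), a_bounds = c(0.05, 1.5)) {
  if (length(t_off) < 3) stop_domain("need at least 3 points")
  if (length(sem) == 1) sem <- rep(sem, length(t_off))
  if (any(sem < 0)) stop_domain("sem must be >= 0")
  model <- function(p, tt) p[2] * (1 - exp(-tt / p[1]))
  start_a <- min(max(max(ratio), a_bounds[1] + 1e-3), a_bounds[2])
  fit <- fit_curve(t_off, ratio, model,
                   start = c(tau = max(stats::median(t_off) / 2, 0.2),
                             a = start_a),
                   lower = c(tau_bounds[1], a_bounds[1]),
                   upper = c(tau_bounds[2], a_bounds[2]),
                   weights = if (all(sem > 0)) 1 / sem^2 else NULL)
  boot <- bootstrap_taus(t_off, ratio, sem, model, fit, n_boot, seed,
                         lower = c(tau_bounds[1], a_bounds[1]),
                         upper = c(tau_bounds[2], a_bounds[2]))
  structure(
    list(tau = fit$par[1], amplitude = fit$par[2], y0 = 0,
         sd_tau = stats::sd(boot), n_boot = n_boot, seed = seed,
         boot_tau = boot, converged = fit$converged),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: tau = %.3f +/- %.3f s (A = %.3f, y0 = %.3f, %d resamples)\n",
              x$tau, x$sd_tau, x$amplitude, x$y0, x$n_boot))
  invisible(x)
}

# Bounded least squares via minpack.lm (Levenberg-Marquardt).
#' @noRd
fit_curve <- function(t, y, model, start, lower, upper, weights = NULL) {
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  w[!is.finite(w)] <- max(w[is.finite(w)], 1)
  resid_fn <- function(p) sqrt(w) * (y - model(p, t))
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(out))
    stop_domain("exponential fit failed to converge (n = ", length(y),
                " points, start tau = ", start[1], ")")
  list(par = out$par, converged = out$info %in% 1:4)
}

# Parametric bootstrap of the fitted tau; refits reuse the point fit's
# least-squares weights so the resampled estimator matches the original.
#' @noRd
bootstrap_taus <- function(t, y, sem, model, fit, n_boot, seed, lower, upper,
                           weights = NULL) {
  if (all(sem == 0)) return(rep(fit$par[1], n_boot))
  set.seed(derive_seed(seed, 7))
  start <- fit$par
  sw <- if (is.null(weights)) rep(1, length(y)) else sqrt(weights)
  taus <- vapply(seq_len(n_boot), function(b) {
    yb <- pmax(stats::rnorm(length(y), y, sem), 0)   # clip negatives
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = start,
                           fn = function(p) sw * (yb - model(p, t)),
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$par[1]
  }, numeric(1))
  taus[is.finite(taus)]
}

#' Compare two bootstrap-backed fits
#'
#' Computes \eqn{z = (\bar\tau_A - \bar\tau_B) / \sqrt{sd_A^2 + sd_B^2}}
#' on the bootstrap sets — the standard two-sample t statistic rescaled by
#' \eqn{1/\sqrt{n_{boot}}} so the bootstrap-set standard deviations (not
#' their SEMs) set the scale. By construction the result does not depend
#' on the number of resamples. The p-value is the two-sided normal tail.
#'
#' @param fit_a,fit_b \code{fit_result} objects carrying bootstrap sets.
#' @return list with \code{statistic} (z) and \code{p_value}.
#' @export
compare_fits <- function(fit_a, fit_b) {
  if (is.null(fit_a$boot_tau) || is.null(fit_b$boot_tau))
    stop_domain("both fits must carry bootstrap sets")
  sa <- stats::sd(fit_a$boot_tau); sb <- stats::sd(fit_b$boot_tau)
  d <- mean(fit_a$boot_tau) - mean(fit_b$boot_tau)
  if (sa == 0 && sb == 0) {
    z <- if (d == 0) 0 else Inf * sign(d)
  } else {
    z <- d / sqrt(sa^2 + sb^2)
  }
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Re-sensitization ratios across a T_OFF protocol family
#'
#' For a family of experiments sharing (f, Gamma, T_ON) but varying
#' T_OFF, computes for each pulse n the recovery ratio
#' \eqn{F_{n,REV} / F_{n-1,REV}} as a function of T_OFF and fits
#' \eqn{a (1 - e^{-T_{OFF}/\tau})}; the fitted \eqn{\tau} is the
#' re-sensitization time constant \eqn{\tau_{res}(n-1)} and the free
#' plateau \eqn{a} normalizes for incomplete recovery (see the methods
#' vignette; a largest-tercile plateau estimator is available as an
#' alternative normalization).
#'
#' Because reversal at pulse n implies reversal at pulse n-1 under one-way
#' habituation, the ratio is estimated as the conditional binomial
#' proportion \code{k_n / k_{n-1}} with SEM
#' \code{sqrt(q (1-q) / k_{n-1})}.
#'
#' @param record_sets named list of \code{response_records}, one per T_OFF
#'   condition.
#' @param t_offs numeric vector of OFF durations (s), same order as
#'   \code{record_sets}.
#' @param pulses integer vector of pulse indices n >= 1 to report
#'   (default: every pulse available). The \code{"shared"} method always
#'   fits all available pulses jointly so the plateau is well constrained.
#' @param n_boot,seed bootstrap settings.
#' @param method normalization/fit method. \code{"shared"} (default): one
#'   joint fit of \eqn{a (1 - e^{-t/\tau_n})} over all pulse curves with a
#'   single shared plateau \eqn{a} and per-pulse \eqn{\tau_n}, using
#'   iteratively reweighted least squares with model-based binomial
#'   weights; late pulses, whose recovery saturates within the smallest
#'   T_OFF, pin the plateau. \code{"independent"}: a free plateau per
#'   pulse. \code{"tercile"}: plateau = mean ratio over the largest-T_OFF
#'   tercile, divided out before a fixed-amplitude fit.
#' @param tie_slow in the \code{"shared"} method, the number of initial
#'   recovery curves constrained to one common time constant (default 2):
#'   re-sensitization accelerates only after the second pulse, so the
#'   first two OFF gaps share the slow constant and pooling them sharpens
#'   its estimate. Set to 1 for fully per-pulse fits.
#' @return list with \code{ratios} (tidy data.frame: pulse_n, t_off_s,
#'   k_prev, k_cur, ratio, sem, normalized), \code{plateau}, and
#'   \code{fits} (named list of \code{fit_result} per reported pulse,
#'   names "n=1", ...).
#' @export
resensitization_ratios <- function(record_sets, t_offs, pulses = NULL,
                                   n_boot = 1000, seed = 1,
                                   method = c("shared", "independent",
                                              "tercile"), tie_slow = 2) {
  method <- match.arg(method)
  stopifnot(length(record_sets) == length(t_offs), length(t_offs) >= 3)
  max_pulse <- min(vapply(record_sets, function(r) max(r$pulse_n), numeric(1)))
  if (max_pulse < 1) stop_domain("record sets must span at least 2 pulses")
  if (is.null(pulses)) pulses <- seq_len(max_pulse)
  if (any(pulses < 1)) stop_domain("pulses must be >= 1")

  tab <- do.call(rbind, lapply(seq_along(record_sets), function(i) {
    rec <- record_sets[[i]]
    do.call(rbind, lapply(seq_len(max_pulse), function(n) {
      k_prev <- sum(rec$label[rec$pulse_n == n - 1] == "REV", na.rm = TRUE)
      k_cur <- sum(rec$label[rec$pulse_n == n] == "REV", na.rm = TRUE)
      if (k_prev == 0) return(NULL)               # ratio undefined, drop
      q <- k_cur / k_prev
      data.frame(pulse_n = n, t_off_s = t_offs[i], k_prev = k_prev,
                 k_cur = k_cur, ratio = q,
                 sem = sqrt(max(q * (1 - q), 1 / k_prev^2) / k_prev))
    }))
  }))
  if (is.null(tab) || nrow(tab) == 0)
    stop_domain("no pulse had enough defined ratios")

  if (method == "shared") {
    res <- fit_shared_recovery(tab, max_pulse, n_boot, seed, tie_slow)
    tab$normalized <- tab$ratio / res$plateau
    fits <- res$fits
  } else {
    fits <- list()
    for (n in sort(unique(tab$pulse_n))) {
      sub <- tab[tab$pulse_n == n, ]
      if (nrow(sub) < 3) next
      if (method == "independent") {
        ft <- fit_recovery(sub$t_off_s, sub$ratio, sub$sem,
                           n_boot = n_boot, seed = derive_seed(seed, n))
        tab$normalized[tab$pulse_n == n] <- sub$ratio / ft$amplitude
      } else {
        ord <- order(sub$t_off_s)
        top <- utils::tail(ord, ceiling(nrow(sub) / 3))
        plateau <- mean(sub$ratio[top])
        norm <- sub$ratio / plateau
        tab$normalized[tab$pulse_n == n] <- norm
        ft <- fit_recovery(sub$t_off_s, norm, sub$sem / plateau,
                           n_boot = n_boot, seed = derive_seed(seed, n),
                           a_bounds = c(1 - 1e-9, 1 + 1e-9))
      }
      fits[[paste0("n=", n)]] <- ft
    }
  }
  keep <- paste0("n=", intersect(pulses, sort(unique(tab$pulse_n))))
  fits <- fits[intersect(keep, names(fits))]
  if (length(fits) == 0) stop_domain("no requested pulse could be fitted")
  list(ratios = tab,
       plateau = if (method == "shared") res$plateau else NA_real_,
       fits = fits)
}

# Joint shared-plateau recovery fit: ratio ~ a * (1 - exp(-t / tau_n)).
# The first tie_slow curves share one (slow) time constant. Three IRLS
# passes with weights k_prev / (p (1 - p)) evaluated at the model;
# parametric bootstrap resamples the ratios (Gaussian, clipped at 0) and
# refits with the final weights frozen.
#' @noRd
fit_shared_recovery <- function(tab, max_pulse, n_boot, seed, tie_slow = 2) {
  npulse <- max_pulse
  tie_slow <- max(1L, min(as.integer(tie_slow), npulse))
  # parameter index per pulse: one slot for pulses 1..tie_slow, then one each
  pidx <- function(n) ifelse(n <= tie_slow, 2L, 2L + n - tie_slow)
  npar <- 1L + 1L + max(0L, npulse - tie_slow)
  start <- c(a = 0.9, rep(4, npar - 1))
  lower <- c(0.05, rep(0.05, npar - 1))
  upper <- c(1, rep(300, npar - 1))
  model <- function(p) p[1] * (1 - exp(-tab$t_off_s / p[pidx(tab$pulse_n)]))
  w <- rep(1, nrow(tab))
  par <- start
  for (it in 1:3) {
    out <- minpack.lm::nls.lm(
      par = par, fn = function(p) sqrt(w) * (tab$ratio - model(p)),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    par <- out$par
    pr <- pmin(pmax(model(par), 0.02), 0.98)
    w <- tab$k_prev / (pr * (1 - pr))
  }
  boot <- matrix(NA_real_, n_boot, npulse)
  if (n_boot > 0 && any(tab$sem > 0)) {
    set.seed(derive_seed(seed, 8))
    for (b in seq_len(n_boot)) {
      qb <- pmax(stats::rnorm(nrow(tab), tab$ratio, tab$sem), 0)
      res <- tryCatch(
        suppressWarnings(minpack.lm::nls.lm(
          par = par, fn = function(p)
            sqrt(w) * (qb - p[1] * (1 - exp(-tab$t_off_s / p[pidx(tab$pulse_n)]))),
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 100))),
        error = function(e) NULL)
      if (!is.null(res)) boot[b, ] <- res$par[pidx(seq_len(npulse))]
    }
  } else if (n_boot > 0) {
    boot <- matrix(rep(par[pidx(seq_len(npulse))], each = n_boot),
                   n_boot, npulse)
  }
  fits <- lapply(seq_len(npulse), function(n) {
    bt <- boot[, n]
    bt <- bt[is.finite(bt)]
    structure(
      list(tau = unname(par[pidx(n)]), amplitude = unname(par[1]), y0 = 0,
           sd_tau = if (length(bt) > 1) stats::sd(bt) else 0,
           n_boot = n_boot, seed = seed, boot_tau = bt,
           converged = TRUE),
      class = "fit_result")
  })
  names(fits) <- paste0("n=", seq_len(npulse))
  list(plateau = unname(par[1]), fits = fits)
}
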