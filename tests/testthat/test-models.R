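test_that("LTI convolution equals the brute-force double loop", {
  h <- impulse_response(c(0.5, 0.2, 0.1))
  expect_equal(lti_predict(h, 1), h$h)                       # unit impulse
  expect_equal(lti_predict(h, c(1, 0, 1)), c(0.5, 0.2, 0.6, 0.2, 0.1))
  expect_equal(lti_predict(h, rep(0, 10)), rep(0, 12))
  set.seed(5)
  for (i in 1:15) {
    s <- stats::runif(sample(1:100, 1))
    hh <- stats::rnorm(sample(1:100, 1))
    expect_equal(lti_predict(hh, s), conv_oracle(s, hh), tolerance = 1e-10)
  }
  expect_error(lti_predict(impulse_response(1:3, dt = 2), c(1, 0), dt = 1),
               "mismatch")
})

test_that("IRF extraction recovers a known impulse response", {
  # flat baseline input gives a null IRF
  flat <- data.frame(t = seq(0.5, 599.5, by = 1), n = 100,
                     f_rev = 0.03, f_stop = 0.24)
  class(flat) <- c("fraction_timeseries", "data.frame")
  attr(flat, "dt") <- 1
  prI <- stimulus_protocol(500, 2, t_on = 1, t_off = 299, n_pulses = 2)
  h0 <- extract_irf(flat, prI)
  expect_true(all(abs(h0$h) < 1e-12))
  # synthetic impulse data generated from known decay dynamics
  cfg <- generator_config(n_larvae = 4000, seed = 8)
  cts <- generate_count_timeseries(cfg, prI, 600)
  h <- extract_irf(as_fraction_timeseries(cts), prI)
  hp <- strain_preset("wildtype")
  truth <- (0.55 - 0.03) * exp(-(seq_along(h$h) - 0.5) / hp$tau_des)
  noise <- 3 * sqrt(0.55 * 0.45 / 4000) * sqrt(1 / 2)
  expect_lt(max(abs(h$h[1:10] - truth[1:10])), 5 * noise + 0.02)
  # averaging two identical impulses equals the mean of single extractions
  one <- stimulus_protocol(500, 2, t_on = 1, t_off = 299, n_pulses = 1)
  fts <- as_fraction_timeseries(cts)
  h1 <- extract_irf(fts[fts$t < 300, ], one, baseline = 0.03,
                    truncate = FALSE)
  fts2 <- fts[fts$t >= 300, ]; fts2$t <- fts2$t - 300
  attr(fts2, "dt") <- 1
  h2 <- extract_irf(fts2, one, baseline = 0.03, truncate = FALSE)
  h12 <- extract_irf(fts, prI, baseline = 0.03, truncate = FALSE)
  expect_equal(h12$h, (h1$h + h2$h) / 2, tolerance = 1e-10)
})

test_that("habituation model curves evaluate as closed forms", {
  hp <- habituation_params(f0_rev = 0.5, tau_des = 10)
  expect_equal(desensitization_curve(hp, 0), 0.5)
  expect_equal(desensitization_curve(hp, 10), 0.5 / exp(1), tolerance = 1e-4)
  expect_equal(desensitization_curve(hp, 1e6), 0)
  expect_equal(desensitization_curve(hp, 1e6, offset = TRUE), hp$baseline_rev)
  expect_equal(resensitization_curve(hp, 0, 1), 0)
  expect_equal(resensitization_curve(hp, hp$tau_res0, 1), 1 - exp(-1))
  expect_equal(resensitization_curve(hp, 1e6, 1), 1)
  # schedule: slow for the first two gaps, fast afterwards
  expect_equal(tau_res_at(hp, 0:4), c(5.3, 5.3, 0.8, 0.8, 0.8))
  expect_error(tau_res_at(hp, -1), "non-negative")
})

test_that("pulse-train prediction reduces to its limits", {
  hp <- strain_preset("wildtype")
  single <- stimulus_protocol(500, 2, t_on = 30, t_off = 0, n_pulses = 1)
  pt <- predict_pulse_train(hp, single, dt = 0.5)
  expect_equal(pt$f_rev, desensitization_curve(hp, pt$t), tolerance = 1e-12)
  # full recovery limit: constant tau_res, T_OFF >> tau_res
  hp2 <- habituation_params(tau_res0 = 2, tau_res_late = 2)
  long <- stimulus_protocol(500, 2, t_on = 5, t_off = 200, n_pulses = 4)
  pt2 <- predict_pulse_train(hp2, long, dt = 1)
  peaks <- sapply(pulse_onsets(long), function(o)
    max(pt2$f_rev[pt2$t >= o & pt2$t < o + 5]))
  expect_true(all(abs(peaks - peaks[1]) < 1e-10))
  # peak-1 / peak-0 ratio equals the first recovery factor
  p <- default_pulse_protocol(2)
  pt3 <- predict_pulse_train(hp, p, dt = 1)
  on0 <- pt3$f_rev[pt3$t > 0 & pt3$t < 10]
  on1 <- pt3$f_rev[pt3$t > 30 & pt3$t < 40]
  expect_equal(max(on1) / max(on0), 1 - exp(-20 / 5.3), tolerance = 1e-10)
  # stimulus-OFF windows predict zero event probability
  expect_true(all(pt3$f_rev[pt3$t > 10 & pt3$t < 30] == 0))
})

test_that("noiseless exponential fits recover tau with negligible bias", {
  t <- seq(0.5, 119.5, by = 1)
  for (tau in c(1, 5, 18.9, 25.6)) {
    f <- 0.03 + 0.5 * exp(-t / tau)
    fit <- fit_exponential(t, f, sem = 0, y0 = 0.03, n_boot = 10)
    expect_lt(abs(fit$tau - tau) / tau, 5e-4)
    expect_equal(fit$sd_tau, 0)
    expect_length(fit$boot_tau, 10)
  }
  expect_error(fit_exponential(1:3, c(1, 2, 3), 0, y0 = 0), "4 points")
})

test_that("bootstrap uncertainty is deterministic and scales with the SEM", {
  t <- seq(0.5, 59.5, by = 1)
  f <- 0.03 + 0.5 * exp(-t / 12)
  f1 <- fit_exponential(t, f, sem = 0.03, y0 = 0.03, n_boot = 300, seed = 2)
  f2 <- fit_exponential(t, f, sem = 0.03, y0 = 0.03, n_boot = 300, seed = 2)
  expect_identical(f1$boot_tau, f2$boot_tau)
  f3 <- fit_exponential(t, f, sem = 0.09, y0 = 0.03, n_boot = 300, seed = 2)
  expect_gt(f3$sd_tau, f1$sd_tau)
})

test_that("fit comparison uses the resample-count-invariant statistic", {
  t <- seq(0.5, 59.5, by = 1)
  f <- 0.03 + 0.5 * exp(-t / 12)
  fa <- fit_exponential(t, f, sem = 0.02, y0 = 0.03, n_boot = 400, seed = 3)
  expect_equal(compare_fits(fa, fa)$p_value, 1)
  # sets separated by ten pooled SDs
  fb <- fa
  fb$boot_tau <- fa$boot_tau + 10 * sqrt(2) * sd(fa$boot_tau)
  expect_lt(compare_fits(fa, fb)$p_value, 0.001)
  # doubling the resample count leaves the statistic essentially unchanged
  f500 <- fit_exponential(t, f, sem = 0.05, y0 = 0.03, n_boot = 500, seed = 4)
  f1000 <- fit_exponential(t, f, sem = 0.05, y0 = 0.03, n_boot = 1000, seed = 4)
  shifted <- function(ft, d) { ft$boot_tau <- ft$boot_tau + d; ft }
  z500 <- abs(compare_fits(f500, shifted(f500, 2))$statistic)
  z1000 <- abs(compare_fits(f1000, shifted(f1000, 2))$statistic)
  expect_equal(z500, z1000, tolerance = 0.1)
})

test_that("recovery ratios rise monotonically in expectation and fit tau_res", {
  hp <- strain_preset("wildtype")
  t_offs <- c(0.5, 1, 2, 5, 10, 20, 40)
  expected <- sapply(t_offs, function(to) resensitization_curve(hp, to, 1))
  expect_true(all(diff(expected) > 0))
  cfg <- generator_config(n_larvae = 100, seed = 51)
  rr <- resensitization_experiment(cfg, n_boot = 100)
  ft <- rr$fits[["n=1"]]
  expect_lt(abs(ft$tau - 5.3) / 5.3, 0.25)
  expect_gt(ft$sd_tau, 0)
  # large T_OFF ratios sit at the plateau, so normalized values approach 1
  top <- rr$ratios[rr$ratios$pulse_n == 1 & rr$ratios$t_off_s >= 20, ]
  expect_true(all(abs(top$normalized - 1) < 0.25))
})

test_that("model comparison prefers the pulse-indexed recovery schedule", {
  # synthetic pulsed data where late recoveries are fast; a model holding
  # tau_res constant misses the late-pulse peaks
  hp <- strain_preset("wildtype")
  p <- stimulus_protocol(500, 2, t_on = 10, t_off = 5, n_pulses = 8)
  cfg <- generator_config(n_larvae = 1000, seed = 61)
  cts <- generate_count_timeseries(cfg, p, protocol_span(p))
  fts <- as_fraction_timeseries(cts)
  onsets <- pulse_onsets(p)
  peak_of <- function(v) sapply(onsets, function(o)
    max(v[fts$t >= o & fts$t < o + p$t_on]))
  emp <- peak_of(fts$f_rev)
  rho <- 0.85
  full <- predict_pulse_train(hp, p, dt = 1, cumulative = TRUE,
                              persistence = rho)
  hp_const <- habituation_params(tau_res0 = hp$tau_res0,
                                 tau_res_late = hp$tau_res0)
  const <- predict_pulse_train(hp_const, p, dt = 1, cumulative = TRUE,
                               persistence = rho)
  mod_peak <- function(pt) sapply(onsets, function(o)
    max(pt$f_rev[pt$t >= o & pt$t < o + p$t_on]))
  err_full <- sum(abs(mod_peak(full) - emp))
  err_const <- sum(abs(mod_peak(const) - emp))
  expect_lt(err_full, err_const)
})

test_that("the LTI prediction fails under continuous stimulation", {
  cfg <- generator_config(n_larvae = 2000, seed = 71)
  prI <- stimulus_protocol(500, 2, t_on = 1, t_off = 299, n_pulses = 2)
  cts <- generate_count_timeseries(cfg, prI, 600)
  h <- extract_irf(as_fraction_timeseries(cts), prI)
  R <- lti_predict(h, rep(1, 120))[1:120]
  hp <- strain_preset("wildtype")
  eq3 <- desensitization_curve(hp, 0:119, offset = TRUE)
  divergence <- abs(R[21:120] - eq3[21:120])
  expect_gt(min(divergence), 0.5 * max(eq3))
})
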