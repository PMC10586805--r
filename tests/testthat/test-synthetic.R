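test_that("generator is deterministic under a fixed seed", {
  cfg <- generator_config(n_larvae = 50, seed = 11)
  p <- default_pulse_protocol(5)
  expect_identical(generate_response_records(cfg, p),
                   generate_response_records(cfg, p))
  expect_identical(generate_count_timeseries(cfg, p, 160),
                   generate_count_timeseries(cfg, p, 160))
  rec <- generate_response_records(cfg, p)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectories_csv(generate_trajectories(rec, p, seed = 4), f1)
  write_trajectories_csv(generate_trajectories(rec, p, seed = 4), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero larvae give an empty record table", {
  cfg <- generator_config(n_larvae = 0, seed = 1)
  rec <- generate_response_records(cfg, default_pulse_protocol(3))
  expect_s3_class(rec, "response_records")
  expect_equal(nrow(rec), 0)
})

test_that("below-threshold stimulation reproduces the configured baselines", {
  cfg <- generator_config(n_larvae = 10000, seed = 2)
  p <- stimulus_protocol(500, 0, t_on = 2, t_off = 0, n_pulses = 1)  # gamma 0
  rec <- generate_response_records(cfg, p)
  f <- response_fractions(rec, 0)
  sd_rev <- sqrt(0.03 * 0.97 / 10000)
  sd_stop <- sqrt(0.24 * 0.76 / 10000)
  expect_lt(abs(f$f_rev - 0.03), 3 * sd_rev)
  expect_lt(abs(f$f_stop - 0.24), 3 * sd_stop)
})

test_that("first-pulse label frequencies converge to configured probabilities", {
  cfg <- generator_config(n_larvae = 10000, seed = 6)
  rec <- generate_response_records(cfg, default_pulse_protocol(1))
  f <- response_fractions(rec, 0)
  # REV: F0 = 0.55; STOP: 0.90; pause/turn split 0.35/0.65 of non-REV stops
  expect_lt(abs(f$f_rev - 0.55), 3 * sqrt(0.55 * 0.45 / 10000))
  expect_lt(abs(f$f_stop - 0.90), 3 * sqrt(0.9 * 0.1 / 10000))
  nonrev_stop <- f$f_pause + f$f_turn
  expect_lt(abs(f$f_pause / nonrev_stop - 0.35), 0.02)
})

test_that("individual sequences are strictly one-way into REV", {
  for (s in 1:5) {
    cfg <- generator_config(n_larvae = 300, seed = s)
    rec <- generate_response_records(cfg, default_pulse_protocol(10))
    for (lag in c(1, 5)) {
      tm <- transition_matrix(rec, lag)
      expect_equal(one_way_violations(tm)$n_violations, 0)
    }
  }
})

test_that("full recovery with persistent reversals keeps pulse peaks at the naive level", {
  # isolate the recovery factor: repeat probability 1, long T_OFF relative
  # to tau_res(0), negligible late tau_res
  hp <- habituation_params(tau_res0 = 5.3, tau_res_late = 0.05)
  cfg <- generator_config(n_larvae = 8000, seed = 9, habituation = hp,
                          transition_kernel = default_transition_kernel(1))
  p <- stimulus_protocol(500, 2, t_on = 10, t_off = 60, n_pulses = 6)
  rec <- generate_response_records(cfg, p)
  f0 <- response_fractions(rec, 0)$f_rev
  f5 <- response_fractions(rec, 5)$f_rev
  expect_lt(abs(f5 - f0), 4 * sqrt(0.55 * 0.45 / 8000) * 2)
})

test_that("count-series expectation follows the decay law", {
  cfg <- generator_config(n_larvae = 100, seed = 3)
  cfg$dt <- 0.01
  p <- stimulus_protocol(500, 2, t_on = 60, t_off = 0, n_pulses = 1)
  cts <- generate_count_timeseries(cfg, p, 60)
  # at t -> 0+ the expectation equals F0_REV
  expect_equal(cts$p_rev[1], 0.55, tolerance = 1e-3)
  # one tau_des after onset: baseline + (F0 - baseline)/e
  i <- which.min(abs(cts$t - 18.9))
  expect_equal(cts$p_rev[i], 0.03 + (0.55 - 0.03) / exp(1), tolerance = 1e-3)
  # long after the pulse the expectation has relaxed to the baseline
  cfg2 <- generator_config(n_larvae = 100, seed = 3)
  p2 <- stimulus_protocol(500, 2, t_on = 1, t_off = 299, n_pulses = 1)
  cts2 <- generate_count_timeseries(cfg2, p2, 300)
  expect_equal(cts2$p_rev[cts2$t > 200], rep(0.03, sum(cts2$t > 200)),
               tolerance = 1e-4)
  expect_error(generate_count_timeseries(cfg, p, 10), "duration")
})

test_that("record CSV and config validation behave", {
  cfg <- generator_config(n_larvae = 20, seed = 5)
  rec <- generate_response_records(cfg, default_pulse_protocol(3))
  path <- tempfile(fileext = ".csv")
  write_records_csv(rec, path)
  back <- read_records_csv(path)
  expect_equal(as.character(back$label), as.character(rec$label))
  expect_error(generator_config(n_larvae = 10, seed = 1,
                                baseline_rev = 0.5, baseline_stop = 0.2),
               "baseline_rev")
  bad <- default_transition_kernel()
  bad["PAUSE", "REV"] <- 0.1; bad["PAUSE", "CONT"] <- 0.45
  expect_error(generator_config(n_larvae = 10, seed = 1,
                                transition_kernel = bad),
               "entries into REV")
})
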