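test_that("response fractions are exact count ratios that sum to one", {
  rec <- make_records(list(
    rep("CONT", 1), rep("CONT", 1), rep("CONT", 1), rep("CONT", 1),
    rep("CONT", 1), "PAUSE", "PAUSE", "TURN", "TURN", "REV"))
  f <- response_fractions(rec, 0)
  expect_equal(c(f$f_cont, f$f_pause, f$f_turn, f$f_rev),
               c(0.5, 0.2, 0.2, 0.1))
  expect_equal(f$f_stop, 0.5)
  all_cont <- make_records(list(rep("CONT", 2), rep("CONT", 2)))
  expect_equal(response_fractions(all_cont, 1)$f_stop, 0)
  # sum identity on random record sets
  set.seed(99)
  for (i in 1:20) {
    rec <- make_records(replicate(15, sample(c("CONT", "PAUSE", "TURN", "REV"),
                                             3, replace = TRUE),
                                  simplify = FALSE))
    f <- response_fractions(rec, sample(0:2, 1))
    expect_equal(f$f_cont + f$f_pause + f$f_turn + f$f_rev, 1)
  }
  expect_error(response_fractions(make_records(list("CONT")), 5), "no active")
})

test_that("fraction time series bins instantaneous states", {
  # one larva reversing for one full bin
  states <- data.frame(larva_id = 1,
                       t = seq(0.05, 3, by = 0.1),
                       rev = FALSE, stop = FALSE)
  states$rev[states$t > 1 & states$t < 2] <- TRUE
  states$stop <- states$rev
  fts <- fraction_timeseries(states, dt = 1)
  expect_equal(fts$f_rev[fts$t == 1.5], 1)
  expect_equal(fts$f_rev[fts$t == 2.5], 0)
  expect_true(all(fts$n == 1))
  expect_error(fraction_timeseries(states[0, ], 1), "non-empty")
  expect_error(fraction_timeseries(states, 0), "dt")
})

test_that("no-stimulus count series stays within binomial noise of baseline", {
  cfg <- generator_config(n_larvae = 400, seed = 14)
  p <- stimulus_protocol(500, 0, t_on = 60, t_off = 0, n_pulses = 1)
  cts <- generate_count_timeseries(cfg, p, 60)
  fts <- as_fraction_timeseries(cts)
  sd_rev <- sqrt(0.03 * 0.97 / 400)
  sd_stop <- sqrt(0.24 * 0.76 / 400)
  # per-bin 3-SD coverage holds for ~99.7% of bins; across 60 bins allow
  # the expected handful of exceedances but nothing beyond 4.5 SD
  expect_gte(mean(abs(fts$f_rev - 0.03) <= 3 * sd_rev), 0.95)
  expect_gte(mean(abs(fts$f_stop - 0.24) <= 3 * sd_stop), 0.95)
  expect_true(all(abs(fts$f_rev - 0.03) <= 4.5 * sd_rev))
  expect_true(all(abs(fts$f_stop - 0.24) <= 4.5 * sd_stop))
  expect_true(all(fts$n == 400))
})

test_that("fisher_compare matches the hypergeometric enumeration oracle", {
  expect_equal(fisher_compare(10, 100, 10, 100), 1)
  expect_lt(fisher_compare(50, 100, 10, 100), 0.001)
  expect_equal(fisher_compare(3, 20, 9, 25), fisher_compare(9, 25, 3, 20))
  set.seed(7)
  for (i in 1:200) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(fisher_compare(k1, n1, k2, n2),
                 fisher_oracle(k1, n1, k2, n2), tolerance = 1e-7)
  }
  expect_error(fisher_compare(-1, 10, 2, 10), "non-negative")
  expect_error(fisher_compare(11, 10, 2, 10), "exceed")
})

test_that("condition grids flag only genuinely different neighbors", {
  cond <- data.frame(f_hz = rep(c(100, 500), each = 2),
                     gamma = rep(c(1, 2), 2),
                     k_rev = c(10, 10, 10, 10), n = rep(100, 4))
  base <- list(k_rev = 10, n = 100)
  g <- condition_grid(cond, base)
  expect_false(any(g$edges$sig))
  expect_false(any(g$conditions$sig_vs_baseline))
  cond2 <- cond; cond2$k_rev <- c(5, 10, 15, 55)
  g2 <- condition_grid(cond2, base)
  big <- g2$edges[g2$edges$f2 == 500 & g2$edges$gamma2 == 2 &
                    g2$edges$gamma1 == 1, ]
  expect_true(all(big$sig))
  expect_error(condition_grid(cond[1, , drop = FALSE], base), "2 conditions")
})
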