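test_that("charge accumulates as decaying step functions", {
  cp <- circuit_params()                   # V=1, C1=1.2, C2=160, R=1, T=30
  expect_equal(simulate_charge(cp, 0), 1.2)            # first packet, C1*V
  expect_equal(simulate_charge(cp, -3), 0)             # initially uncharged
  expect_equal(simulate_charge(cp, 30, left_limit = TRUE),
               1.2 * exp(-30 / 160), tolerance = 1e-12)
  # decay between switches is exactly exp(-dt/(R C2))
  q <- simulate_charge(cp, c(5, 20))
  expect_equal(q[2] / q[1], exp(-15 / 160), tolerance = 1e-12)
  expect_true(all(simulate_charge(cp, seq(0, 500, by = 0.7)) >= 0))
  expect_error(simulate_charge(cp, c(3, 1)), "increasing")
})

test_that("iterative summation matches the geometric-series closed form", {
  cp <- circuit_params()
  m <- 0:1000
  expect_lt(max(abs(simulate_charge(cp, m * cp$T_switch) -
                      charge_at_switch(cp, m))), 1e-10)
  expect_equal(charge_at_switch(cp, Inf), 1.2 / (1 - exp(-30 / 160)),
               tolerance = 1e-12)
})

test_that("event fraction decreases monotonically in accumulated charge", {
  cp <- circuit_params(F0 = 0.5)
  expect_equal(event_fraction(cp, 0), 0.5 * exp(-1.2), tolerance = 1e-12)
  expect_equal(0.5 * exp(-1.2), 0.15059, tolerance = 1e-4)
  q <- simulate_charge(cp, 0:300)
  f <- event_fraction(cp, 0:300)
  expect_true(all(diff(f[order(q)]) <= 1e-12))
})

test_that("peak series is non-increasing and saturates", {
  cp <- circuit_params(F0 = 0.5)
  ps <- peak_series(cp, 50)
  expect_equal(ps[1], 0.5 * exp(-1.2))
  expect_true(all(diff(ps) <= 0))
  expect_equal(ps[50], cp$F0 * exp(-charge_at_switch(cp, Inf)),
               tolerance = 1e-2)
  expect_error(peak_series(cp, 0), "n_switches")
})

test_that("peak comparison applies Fisher tests per peak", {
  cp <- circuit_params(F0 = 0.55)
  ps <- peak_series(cp, 6)
  same <- compare_peaks(ps, ps, 100)
  expect_true(all(same$p == 1))
  expect_lt(compare_peaks(0.6, 0.1, 100)$p, 0.001)
  expect_error(compare_peaks(ps, ps[-1], 100), "equal length")
})

test_that("circuit configuration validates and runs from JSON", {
  expect_warning(circuit_params(C1 = 50, C2 = 100), "C2/C1")
  expect_error(circuit_params(V = -1), "positive")
  cfg <- list(V = 1, C1 = 1.2, C2 = 160, R = 1, T_switch = 30, F0 = 0.55,
              n_switches = 5, dt = 1)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  out <- tempfile(fileext = ".csv")
  run_circuit(path, out = out)
  df <- utils::read.csv(out)
  expect_equal(names(df), c("t_s", "Q2", "F"))
  expect_equal(df$Q2[1], 1.2)
  expect_equal(df$F, 0.55 * exp(-df$Q2), tolerance = 1e-12)
})
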