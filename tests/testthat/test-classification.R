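test_that("stop detection finds sustained low-speed intervals", {
  run <- make_run_trajectory()
  expect_equal(nrow(detect_stops(run)), 0)
  # 0.5 -> 0.02 -> 0.5 mm/s with a 2 s low phase
  tr <- make_stop_trajectory(stop_start = 8, stop_len = 2)
  st <- detect_stops(tr, abs_threshold = 0.1, min_duration = 0.5)
  expect_equal(nrow(st), 1)
  expect_equal(st$start_t, 8, tolerance = 0.3)
  expect_equal(st$end_t, 10, tolerance = 0.3)
  # interval scan oracle on the raw speed profile
  kin <- trajectory_kinematics(tr)
  oracle <- range(kin$t[kin$speed_smooth < 0.1])
  expect_equal(c(st$start_t, st$end_t), oracle, tolerance = 0.2)
  # entirely sub-threshold record: one stop spanning it
  slow <- make_stop_trajectory(stop_start = 0, stop_len = 30, duration = 30)
  st2 <- detect_stops(slow, abs_threshold = 0.1)
  expect_equal(nrow(st2), 1)
  expect_equal(st2$start_t, 0)
  expect_equal(st2$end_t, 30)
  expect_error(trajectory(1, c(0, 1), c(0, 0), c(0, 0), c(1, 1), c(0, 0)),
               "3 frames")
})

test_that("events resolve to PAUSE/TURN/REV by heading change and dot product", {
  tr10 <- make_stop_trajectory(dtheta = 10)
  st <- detect_stops(tr10)
  expect_equal(classify_event(tr10, st[1, ]), "PAUSE")
  tr45 <- make_stop_trajectory(dtheta = 45)
  expect_equal(classify_event(tr45, detect_stops(tr45)[1, ]), "TURN")
  # the boundary value counts as the stronger behavior
  tr30 <- make_stop_trajectory(dtheta = 30)
  expect_equal(classify_event(tr30, detect_stops(tr30)[1, ]), "TURN")
  rev <- make_rev_trajectory()
  expect_equal(classify_event(rev, detect_stops(rev)[1, ]), "REV")
  # stop at the record's end never resumes
  trunc <- make_stop_trajectory(stop_start = 8, stop_len = 12, duration = 20)
  st3 <- detect_stops(trunc)
  expect_equal(classify_event(trunc, st3[nrow(st3), ]), "UNRESOLVED")
})

test_that("pulse responses follow the mid-action rule", {
  p <- stimulus_protocol(500, 2, 10, 20, 1, t_start = 8)
  run <- make_run_trajectory(duration = 30)
  expect_equal(assign_pulse_response(run, p, 0)$label, "CONT")
  # larva mid-turn at onset (stop began at 7, onset 8), no further action
  turning <- make_stop_trajectory(stop_start = 7, stop_len = 2, dtheta = 60,
                                  duration = 30)
  expect_equal(assign_pulse_response(turning, p, 0)$label, "TURN")
  # running at onset, reversal starting 1.5 s into the window
  rev <- make_rev_trajectory(stop_start = 9.5, duration = 30)
  expect_equal(assign_pulse_response(rev, p, 0)$label, "REV")
  # trajectory that does not span the window is marked missing
  short <- make_run_trajectory(duration = 9)
  expect_true(is.na(assign_pulse_response(short, p, 0)$label))
})

test_that("classification is invariant under rotation and translation", {
  p <- default_pulse_protocol(3)
  rec <- generate_response_records(generator_config(n_larvae = 8, seed = 21), p)
  trajs <- generate_trajectories(rec, p, seed = 22)
  base <- classify_responses(trajs, p)
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- lapply(trajs, function(tr) {
    xy <- cbind(tr$x, tr$y) %*% R
    hv <- cbind(tr$head_dx, tr$head_dy) %*% R
    trajectory(tr$larva_id[1], tr$t, xy[, 1] + 37, xy[, 2] - 12,
               hv[, 1], hv[, 2])
  })
  expect_equal(as.character(classify_responses(moved, p)$label),
               as.character(base$label))
})

test_that("scripted behaviors round-trip through the classifier", {
  # the specific mixed script
  p4 <- default_pulse_protocol(4)
  rec <- make_records(list(c("REV", "TURN", "PAUSE", "CONT")))
  tr <- generate_trajectories(rec, p4, seed = 13)
  got <- classify_responses(tr, p4)
  expect_equal(as.character(got$label), c("REV", "TURN", "PAUSE", "CONT"))
  # population round trip at >= 99% agreement
  cfg <- generator_config(n_larvae = 40, seed = 31)
  p <- default_pulse_protocol(5)
  rec <- generate_response_records(cfg, p)
  trajs <- generate_trajectories(rec, p, seed = 32)
  cls <- classify_responses(trajs, p)
  m <- merge(as.data.frame(rec), as.data.frame(cls),
             by = c("larva_id", "pulse_n"))
  expect_gte(mean(as.character(m$label.x) == as.character(m$label.y)), 0.99)
})

test_that("widening the response window leaves aggregate fractions stable", {
  cfg <- generator_config(n_larvae = 30, seed = 41)
  p <- default_pulse_protocol(4)
  rec <- generate_response_records(cfg, p)
  trajs <- generate_trajectories(rec, p, seed = 42)
  f3 <- fractions_by_pulse(classify_responses(trajs, p, window = 3))
  f5 <- fractions_by_pulse(classify_responses(trajs, p, window = 5))
  for (col in c("f_cont", "f_pause", "f_turn", "f_rev"))
    expect_lt(max(abs(f3[[col]] - f5[[col]])), 0.05)
})
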