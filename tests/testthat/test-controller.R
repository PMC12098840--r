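test_that("the stimulate decision is the conjunction of the three gates", {
  expect_true(evaluate_gates(TRUE, TRUE, TRUE))
  expect_false(evaluate_gates(TRUE, FALSE, TRUE))
  expect_false(evaluate_gates(FALSE, TRUE, TRUE))
  expect_false(evaluate_gates(TRUE, TRUE, FALSE))
  expect_false(evaluate_gates(FALSE, FALSE, FALSE))
  expect_identical(evaluate_gates(c(TRUE, TRUE), c(TRUE, FALSE), TRUE),
                   c(TRUE, FALSE))
})

test_that("with clean streams the log follows the protocol exactly", {
  pr <- simple_protocol()
  log <- run_closed_loop(pr, flat_sensor_stream(60), always_in_target(60))
  expect_equal(nrow(log), 60 * 20)
  expect_equal(sum(log$stim_state == "on"), 30 * 20)
  expect_true(all(log$stim_state[log$time_s < 30] == "on"))
  expect_true(all(log$stim_state[log$time_s >= 30] == "off"))
  # gate soundness: on implies all three gates
  on <- log$stim_state == "on"
  expect_true(all(log$protocol_on[on] & log$sensors_ok[on] &
                  log$in_target[on]))
})

test_that("a threshold breach pauses stimulation within one poll interval", {
  pr <- simple_protocol()
  ss <- flat_sensor_stream(60)
  breach <- ss$kind == "temperature" & ss$time_s >= 5 & ss$time_s < 8
  ss$value[breach] <- ss$value[breach] + 100
  log <- run_closed_loop(pr, ss, always_in_target(60))
  expect_true(all(log$stim_state[log$time_s >= 5.05 & log$time_s < 8] ==
                  "off"))
  # pause semantics: stimulation resumes once readings recover
  expect_true(any(log$stim_state[log$time_s >= 8.1 & log$time_s < 30] ==
                  "on"))
  # abort semantics: the breach latches off for the rest of the run
  log2 <- run_closed_loop(pr, ss, always_in_target(60),
                          config = controller_config(breach_action = "abort"))
  expect_true(all(log2$stim_state[log2$time_s >= 5.05] == "off"))
})

test_that("a reading exactly at the limit counts as a breach", {
  pr <- simple_protocol()
  ss <- flat_sensor_stream(60, baselines = c(magnetic = 0, temperature = 40,
                                             sound = 45, vibration = 0.02))
  log <- run_closed_loop(pr, ss, always_in_target(60))
  expect_true(all(log$stim_state == "off"))
})

test_that("leaving the target area gates stimulation off with poll latency", {
  pr <- simple_protocol()
  t <- seq(0, 60, by = 0.05)
  pos <- data.frame(time_s = t, chamber = "dark",
                    in_target = !(t >= 10 & t < 15))
  log <- run_closed_loop(pr, flat_sensor_stream(60), pos)
  expect_true(all(log$stim_state[log$time_s >= 10.05 & log$time_s < 15] ==
                  "off"))
  expect_true(all(log$stim_state[log$time_s >= 15.05 & log$time_s < 30] ==
                  "on"))
})

test_that("stale sensors fail safe", {
  pr <- simple_protocol()
  ss <- flat_sensor_stream(60)
  # magnetic readings only once per second: stale at most polls
  keep <- ss$kind != "magnetic" | (round(ss$time_s * 20) %% 20 == 0)
  log <- run_closed_loop(pr, ss[keep, ], always_in_target(60))
  frac_on <- mean(log$stim_state[log$time_s < 30] == "on")
  expect_lt(frac_on, 0.2)
  # disabling the sparse sensor restores full stimulation
  thr <- sensor_thresholds(enabled = c(magnetic = FALSE))
  log2 <- run_closed_loop(pr, ss[keep, ], always_in_target(60), thr)
  expect_equal(sum(log2$stim_state == "on"), 600)
})

test_that("streams that end before the protocol are rejected by name", {
  pr <- simple_protocol()
  expect_error(run_closed_loop(pr, flat_sensor_stream(10),
                               always_in_target(60)), "sensor stream")
  expect_error(run_closed_loop(pr, flat_sensor_stream(60),
                               always_in_target(10)), "position stream")
})

test_that("threshold limits must respect the sensor detection ranges", {
  expect_error(sensor_thresholds(temperature = 200), "detection range")
  expect_error(sensor_thresholds(magnetic = c(-100, 50)), "detection range")
  expect_silent(sensor_thresholds(temperature = 39.5, sound = 80))
})

test_that("experiment logs round-trip through CSV and validate on read", {
  pr <- simple_protocol()
  log <- run_closed_loop(pr, flat_sensor_stream(60), always_in_target(60))
  path <- withr::local_tempfile(fileext = ".csv")
  write_log(log, path)
  back <- read_log(path)
  expect_equal(as.data.frame(back), as.data.frame(log))

  # a 5-minute log at 20 Hz parses with the monotone-time check
  pr5 <- simple_protocol(repeats = 5)
  log5 <- run_closed_loop(pr5, flat_sensor_stream(300),
                          always_in_target(300))
  expect_equal(nrow(log5), 6000)
  p5 <- withr::local_tempfile(fileext = ".csv")
  write_log(log5, p5)
  expect_silent(read_log(p5))

  # corrupt the time ordering: the parser reports the row
  lines <- readLines(p5)
  lines[c(10, 11)] <- lines[c(11, 10)]
  writeLines(lines, p5)
  expect_error(read_log(p5), "row")
})
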