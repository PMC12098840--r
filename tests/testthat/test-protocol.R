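test_that("bidirectional compilation alternates direction with dead gaps", {
  pr <- stimulation_protocol(protocol_phase(1, 0, frequency = 10,
                                            dead_time = 0.001))
  ev <- compile_waveform(pr)
  iv <- waveform_intervals(ev)
  expect_equal(nrow(iv), 20)                       # 20 half-periods
  expect_equal(iv$end_s - iv$start_s, rep(0.049, 20), tolerance = 1e-12)
  expect_identical(iv$direction, rep(c("forward", "reverse"), 10))
  # every hold is preceded by a dead gap of exactly dead_time
  gaps <- iv$start_s - c(0, iv$end_s[-20])
  expect_equal(gaps, rep(0.001, 20), tolerance = 1e-12)
  expect_equal(energized_time(ev), 1 - 20 * 0.001, tolerance = 1e-12)
})

test_that("zero stimulation compiles to an all-off waveform", {
  pr <- stimulation_protocol(protocol_phase(0, 10))
  ev <- compile_waveform(pr)
  expect_true(all(ev$pin_a == 0 & ev$pin_b == 0))
  expect_equal(energized_time(ev), 0)
})

test_that("the 30 s / 30 s x 5 session commands 150 s of stimulation", {
  pr <- simple_protocol(repeats = 5)
  tl <- protocol_timeline(pr)
  on <- tl[tl$stim_on, ]
  expect_equal(nrow(on), 5)
  expect_equal(on$start_s, c(0, 60, 120, 180, 240))
  expect_equal(sum(on$end_s - on$start_s), 150)
  # compiled events cover each ON interval and none of the rest periods
  ev <- compile_waveform(pr)
  iv <- waveform_intervals(ev)
  in_on <- vapply(seq_len(nrow(iv)), function(i)
    any(iv$start_s[i] >= on$start_s - 1e-9 & iv$end_s[i] <= on$end_s + 1e-9),
    logical(1))
  expect_true(all(in_on))
  expect_equal(energized_time(ev), 150 - 5 * 600 * 0.001, tolerance = 1e-9)
})

test_that("dead time at or beyond the half-period is rejected up front", {
  expect_error(protocol_phase(1, 0, frequency = 10, dead_time = 0.05),
               "half-period")
  expect_error(protocol_phase(1, 0, frequency = 10, dead_time = 0.06),
               "half-period")
  expect_silent(protocol_phase(1, 0, frequency = 10, dead_time = 0.049))
})

test_that("unidirectional mode is a 50% duty on/off square wave", {
  pr <- stimulation_protocol(protocol_phase(2, 1, frequency = 5,
                                            mode = "unidirectional"))
  ev <- compile_waveform(pr)
  expect_true(all(ev$pin_b == 0))                  # one direction only
  iv <- waveform_intervals(ev)
  expect_equal(nrow(iv), 10)                       # 10 cycles in 2 s at 5 Hz
  expect_equal(energized_time(ev), 1, tolerance = 1e-12)
})

test_that("randomized protocols never violate H-bridge safety", {
  set.seed(7)
  for (i in 1:200) {
    f <- stats::runif(1, 1, 150)
    dead <- stats::runif(1, 0, 0.9) / (2 * f)
    stim <- stats::runif(1, 0.1, 2)
    mode <- sample(c("bidirectional", "unidirectional"), 1)
    pr <- stimulation_protocol(protocol_phase(stim, stats::runif(1, 0, 0.5),
                                              f, dead, mode,
                                              sample(1:3, 1)))
    ev <- compile_waveform(pr)
    expect_false(any(ev$pin_a == 1 & ev$pin_b == 1))
    expect_true(all(diff(ev$time_s) > 0))
    iv <- waveform_intervals(ev)
    if (mode == "bidirectional" && nrow(iv) > 1) {
      flips <- which(iv$direction[-1] != iv$direction[-nrow(iv)])
      gap <- iv$start_s[flips + 1] - iv$end_s[flips]
      expect_true(all(gap >= dead - 1e-9))
    }
  }
})

test_that("timeline partitions the session without gap or overlap", {
  pr <- stimulation_protocol(list(
    protocol_phase(5, 2, frequency = 20, repeats = 2),
    protocol_phase(3, 1, frequency = 50, mode = "unidirectional")))
  tl <- protocol_timeline(pr)
  expect_equal(tl$start_s[-1], tl$end_s[-nrow(tl)])
  expect_equal(max(tl$end_s), protocol_duration(pr))
  expect_equal(sum((tl$end_s - tl$start_s)[tl$stim_on]), 2 * 5 + 3)
  empty <- stimulation_protocol(list())
  expect_equal(nrow(protocol_timeline(empty)), 0)
})

test_that("timing feasibility encodes the sensing/frequency trade-off", {
  p10 <- stimulation_protocol(protocol_phase(1, 0, frequency = 10))
  p250 <- stimulation_protocol(protocol_phase(1, 0, frequency = 250,
                                              dead_time = 1e-4))
  expect_true(validate_protocol(p10, sensing_enabled = TRUE)$feasible)
  r <- validate_protocol(p250, sensing_enabled = TRUE)
  expect_false(r$feasible)
  expect_match(r$note, "200 Hz")
  expect_true(validate_protocol(p250, sensing_enabled = FALSE)$feasible)
  # strict inequality at the boundary
  p200 <- stimulation_protocol(protocol_phase(1, 0, frequency = 200,
                                              dead_time = 1e-4))
  expect_false(validate_protocol(p200, sensing_enabled = TRUE)$feasible)
})

test_that("protocol tables round-trip through CSV", {
  pr <- stimulation_protocol(list(
    protocol_phase(30, 30, 10, 0.001, "bidirectional", 5),
    protocol_phase(2, 0.5, 40, 0.002, "unidirectional", 2)), 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_protocol(pr, path)
  back <- read_protocol(path, channel_count = 2)
  expect_equal(back, pr)
})
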