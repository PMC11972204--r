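test_that("cycle frequency reproduces the stimulus timing arithmetic", {
  expect_equal(cycle_frequency(stimulus_timing(60, 9, 4, 2)), 2.3)
  expect_equal(cycle_frequency(stimulus_timing(60, 30, 30, 1)), 1.0)
  # direct arithmetic oracle at a different refresh rate
  expect_equal(cycle_frequency(stimulus_timing(120, 9, 4, 2), digits = NULL),
               120 / (2 * 13))
  expect_error(stimulus_timing(60, 0, 4, 2), "invalid timing")
  expect_error(stimulus_timing(60, 9.5, 4, 2), "invalid timing")
})

test_that("physical schedule follows the block scheme", {
  sch <- build_physical_schedule()
  ev <- sch$events
  motion <- ev[ev$trial_type %in% c("horizontal", "vertical"), ]
  expect_equal(nrow(motion), 48)                # 6 reps x 4 alternations x 2
  expect_true(all(motion$duration == 10))
  # each super-block of four alternations spans 80 s
  first_flicker <- min(ev$onset[ev$trial_type == "flicker"])
  expect_equal(first_flicker - min(motion$onset), 80)
  expect_setequal(unique(ev$trial_type),
                  c("fixation", "horizontal", "vertical", "flicker"))
  # event durations tile the run exactly
  expect_equal(sum(ev$duration), sch$total_s)
  expect_equal(sch$n_volumes, floor(sch$total_s / sch$tr_s))
  # one repetition without fixation: 80 + 16 s
  sch1 <- build_physical_schedule(repetitions = 1, fixation_s = 0)
  expect_equal(sch1$total_s, 96)
  expect_error(build_physical_schedule(motion_block_s = -1),
               "invalid schedule")
})

test_that("percept streams respect bounds, alternate, and are reproducible", {
  proc <- percept_process()
  ev <- sample_percept_stream(proc, 80, seed = 11)
  expect_true(all(ev$duration <= 20 + 1e-9))
  # all dwells except the clipped final one respect the lower bound
  expect_true(all(ev$duration[-nrow(ev)] >= 3 - 1e-9))
  expect_true(all(ev$trial_type[-1] != ev$trial_type[-nrow(ev)]))
  expect_equal(sum(ev$duration), 80)
  expect_identical(ev, sample_percept_stream(proc, 80, seed = 11))
  expect_false(identical(ev, sample_percept_stream(proc, 80, seed = 12)))
  expect_error(percept_process(min_dwell_s = 5, max_dwell_s = 5),
               "invalid process")
})

test_that("dwell sampler matches the truncated-gamma mean", {
  proc <- percept_process()
  # independent oracle: numeric integration of the truncated density
  rate <- proc$shape / proc$mean_dwell_s
  dens <- function(x) stats::dgamma(x, proc$shape, rate)
  z <- stats::integrate(dens, 3, 20)$value
  mu <- stats::integrate(function(x) x * dens(x), 3, 20)$value / z
  expect_equal(truncated_dwell_mean(proc), mu, tolerance = 1e-6)
  set.seed(5)
  d <- sample_dwells(proc, 10000)
  expect_true(all(d >= 3 & d <= 20))
  expect_lt(abs(mean(d) - mu), 3 * stats::sd(d) / sqrt(length(d)))
})

test_that("switch-rate screening applies the inclusive 5-s rule", {
  mk <- function(durs) data.frame(onset = cumsum(c(0, durs[-length(durs)])),
                                  duration = durs,
                                  trial_type = rep(c("horizontal", "vertical"),
                                                   length.out = length(durs)),
                                  source = "percept")
  expect_true(screen_switch_rate(mk(rep(4, 10))))
  expect_false(screen_switch_rate(mk(c(4, 12, 4))))
  expect_true(screen_switch_rate(mk(rep(5, 10))))  # boundary inclusive
  expect_error(screen_switch_rate(mk(rep(4, 4))[0, ]), "no percept events")
})

test_that("ambiguous schedules carry stimulus and percept sources", {
  sch <- build_ambiguous_schedule(seed = 3, repetitions = 2)
  ev <- sch$events
  expect_setequal(unique(ev$source), c("stimulus", "percept"))
  amb <- ev[ev$trial_type == "ambiguous", ]
  per <- ev[ev$source == "percept", ]
  expect_equal(sum(per$duration), sum(amb$duration))
  # percepts stay within ambiguous blocks
  expect_true(all(per$onset >= min(amb$onset)))
  expect_identical(sch$events,
                   build_ambiguous_schedule(seed = 3, repetitions = 2)$events)
  # report latency shifts percept onsets only
  lag <- build_ambiguous_schedule(seed = 3, repetitions = 2, lag_s = 0.5)$events
  expect_equal(lag$onset[lag$source == "percept"][1], per$onset[1] + 0.5)
})
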