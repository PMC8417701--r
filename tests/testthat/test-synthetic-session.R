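# Synthetic generator: determinism, protocol structure, null construction,
# blink recoverability, event/behavior structure.

test_that("generation is deterministic for a fixed seed", {
  cfg <- effect_config(task_block_s = 60, rest_block_s = 20, seed = 7)
  a <- generate_session("P", cfg, "HLHL", streams = c("ecg", "et"))
  b <- generate_session("P", cfg, "HLHL", streams = c("ecg", "et"))
  expect_identical(a, b)
  cfg2 <- effect_config(task_block_s = 60, rest_block_s = 20, seed = 8)
  c2 <- generate_session("P", cfg2, "HLHL", streams = c("ecg", "et"))
  expect_false(identical(a$streams$ecg$samples, c2$streams$ecg$samples))
})

test_that("generated sessions satisfy the protocol invariants", {
  s <- short_session(11)
  expect_silent(validate_session(s))
  task <- s$blocks$kind[s$blocks$kind != "REST"]
  expect_equal(task, c("HIGH", "LOW", "HIGH", "LOW"))
  expect_equal(sum(s$blocks$kind == "REST"), 5)
  # rates carried through
  expect_equal(s$streams$ecg$nominal_rate, 256)
  expect_equal(s$streams$et$nominal_rate, 100)
})

test_that("cohort alternates block orders and honors stream selection", {
  spec <- cohort_spec(n_participants = 4,
                      effect = effect_config(task_block_s = 30,
                                             rest_block_s = 10),
                      streams = "ecg", drop_et_last = TRUE, seed = 3)
  coh <- generate_cohort(spec)
  expect_length(coh, 4)
  first_task <- vapply(coh, function(s)
    s$blocks$kind[s$blocks$kind != "REST"][1], character(1))
  expect_equal(unname(first_task), c("HIGH", "LOW", "HIGH", "LOW"))
  expect_true(all(vapply(coh, function(s) is.null(s$streams$et), logical(1))))
  # distinct participant baselines (independent draws)
  expect_error(cohort_spec(n_participants = 1), "n_participants")
})

test_that("invalid configurations are rejected", {
  expect_error(effect_config(eeg_beta_gamma_gain = -1), "gains")
  expect_error(effect_config(drift_magnitude = -0.1), "drift")
  expect_error(effect_config(et_rate = 0), "rates")
  expect_error(effect_config(task_block_s = -5), "durations")
})

test_that("blink gaps are the only missing ET samples and are exactly countable", {
  s <- short_session(13)
  et <- s$streams$et
  # every invalid sample has NA gaze; every valid sample is finite
  expect_true(all(is.na(et$samples[!et$valid, "gaze_x"])))
  expect_true(all(is.finite(et$samples[et$valid, "gaze_x"])))
  gaps <- detect_blinks(et$valid, et$nominal_rate)
  runs <- rle(!et$valid)
  n_runs <- sum(runs$values)
  # generator enforces separation, so every gap is one blink
  expect_equal(nrow(gaps), n_runs)
  expect_true(all(gaps$duration >= 0.07 & gaps$duration <= 0.5))
})

test_that("null configuration yields no separation between conditions", {
  ps <- vapply(1:5, function(seed) {
    cfg <- effect_config(hr_delta = 0, sdnn_delta = 0, pupil_delta = 0,
                         fixation_rate_gain = 1, fixation_duration_gain = 1,
                         aoi_dwell_shift = 0, drift_magnitude = 0,
                         task_block_s = 120, seed = seed)
    s <- generate_session("P", cfg, "HLHL", streams = "et")
    ep <- epoch_session(split_conditions(s))
    task <- Filter(function(e) e$block_kind != "REST", ep)
    pm <- vapply(task, function(e)
      mean(e$slices$et$samples[, "pupil_left"], na.rm = TRUE), numeric(1))
    cond <- vapply(task, function(e) e$block_kind, character(1))
    t.test(pm[cond == "HIGH"], pm[cond == "LOW"])$p.value
  }, numeric(1))
  # p-values behave like draws from a null distribution: none vanishingly
  # small, not all piled near zero
  expect_true(all(ps > 1e-3))
  expect_gt(max(ps), 0.1)
})

test_that("event and behavior streams have the protocol structure", {
  s <- short_session(11)
  ev <- s$events
  b <- s$blocks
  task_blocks <- b[b$kind != "REST", ]
  for (i in seq_len(nrow(task_blocks))) {
    inb <- ev$time >= task_blocks$start_time[i] &
      ev$time < task_blocks$end_time[i]
    # ATC spacing ~81 s; 2-min blocks hold 2 commands (first at +5 s)
    expect_equal(sum(ev$kind == "ATC" & inb), 2)
    expect_gte(sum(ev$kind == "POPUP" & inb), 4)
  }
  expect_equal(sum(ev$kind == "ISA"), 4)
  expect_true(all(ev$value[ev$kind == "ISA"] >= 0 &
                    ev$value[ev$kind == "ISA"] <= 100))
  # heading trace at 2 Hz, zone ticks at 20 Hz
  expect_equal(s$streams$heading$nominal_rate, 2)
  expect_equal(s$streams$zone$nominal_rate, 20)
  expect_true(all(s$streams$heading$samples[, 1] >= 0 &
                    s$streams$heading$samples[, 1] < 360))
})

test_that("behavioral effects follow the expected direction", {
  diffs <- vapply(1:3, function(seed) {
    s <- short_session(20 + seed, streams = character(0))
    es <- event_scores(s$events, s$blocks)
    es$popup_score[es$condition == "LOW"] -
      es$popup_score[es$condition == "HIGH"]
  }, numeric(1))
  expect_gt(mean(diffs), 0)    # more correct pop-up answers under LOW
})
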