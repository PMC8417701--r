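# Core data model: stream/session invariants, condition splitting,
# epoching and cross-stream alignment.

mk_stream <- function(name, fs, total, n_chan = 1) {
  n <- round(total * fs)
  stream_recording(name, fs, (0:(n - 1)) / fs,
                   matrix(rnorm(n * n_chan), n, n_chan))
}

mk_session <- function(task_s = 60, rest_s = 30, order = "LHLH",
                       fs_fast = 64, fs_slow = 10) {
  kinds <- if (order == "LHLH") c("LOW", "HIGH", "LOW", "HIGH")
           else c("HIGH", "LOW", "HIGH", "LOW")
  kind <- rep("REST", 9); dur <- rep(rest_s, 9)
  kind[seq(2, 8, 2)] <- kinds; dur[seq(2, 8, 2)] <- task_s
  end <- cumsum(dur)
  blocks <- data.frame(kind = kind, index = 1:9,
                       start_time = c(0, end[-9]), end_time = end)
  total <- max(end)
  session("X", blocks,
          list(fast = mk_stream("fast", fs_fast, total),
               slow = mk_stream("slow", fs_slow, total)))
}

test_that("stream invariants are enforced", {
  expect_error(stream_recording("s", 0, 1:3, matrix(0, 3, 1)),
               "nominal_rate")
  expect_error(stream_recording("s", 10, c(1, 1, 2), matrix(0, 3, 1)),
               "increasing")
  expect_error(stream_recording("s", 10, 1:3, matrix(0, 2, 1)),
               "row count")
})

test_that("session invariants catch malformed protocols", {
  s <- mk_session()
  expect_silent(validate_session(s))
  # drop one rest block
  b <- s$blocks[-1, ]
  expect_error(session("X", b, s$streams), "5 REST")
  # non-alternating task order
  b2 <- s$blocks
  b2$kind[c(2, 4, 6, 8)] <- c("LOW", "LOW", "HIGH", "HIGH")
  expect_error(session("X", b2, s$streams), "alternate")
  # overlap
  b3 <- s$blocks
  b3$end_time[1] <- b3$start_time[2] + 5
  expect_error(session("X", b3, s$streams), "overlap")
})

test_that("split_conditions yields the 9 protocol blocks with stream slices", {
  s <- mk_session(order = "LHLH")
  sp <- split_conditions(s)
  expect_length(sp$LOW, 2)
  expect_length(sp$HIGH, 2)
  expect_length(sp$REST, 5)
  # LHLH: LOW slices are the 1st and 3rd task blocks (indices 2 and 6)
  expect_equal(vapply(sp$LOW, function(b) b$index, numeric(1)), c(2, 6))
  # union of slices covers every sample of every stream exactly once
  n_fast <- sum(vapply(c(sp$LOW, sp$HIGH, sp$REST), function(b)
    length(b$streams$fast$timestamps), integer(1)))
  expect_equal(n_fast, length(s$streams$fast$timestamps))
})

test_that("epoch counts equal floor(block duration / epoch length)", {
  s <- mk_session(task_s = 480, rest_s = 60)
  ep <- epoch_session(split_conditions(s), epoch_len = 6)
  kinds <- vapply(ep, function(e) e$block_kind, character(1))
  expect_equal(sum(kinds != "REST"), 4 * 80)   # 480 s / 6 s per task block
  expect_equal(sum(kinds == "REST"), 5 * 10)   # 60 s / 6 s per rest block
  # trailing remainder discarded
  s2 <- mk_session(task_s = 63, rest_s = 31)
  ep2 <- epoch_session(split_conditions(s2), epoch_len = 6)
  kinds2 <- vapply(ep2, function(e) e$block_kind, character(1))
  expect_equal(sum(kinds2 != "REST"), 4 * 10)
  expect_equal(sum(kinds2 == "REST"), 5 * 5)
})

test_that("no sample appears in two epochs of the same block", {
  s <- mk_session()
  ep <- epoch_session(split_conditions(s), epoch_len = 6)
  by_block <- split(ep, vapply(ep, function(e) e$block_index, numeric(1)))
  for (blk in by_block) {
    for (nm in c("fast", "slow")) {
      ts <- unlist(lapply(blk, function(e) e$slices[[nm]]$timestamps))
      expect_false(any(duplicated(ts)))
    }
  }
})

test_that("secondary-stream boundaries align to the reference within one sample", {
  s <- mk_session(fs_fast = 64, fs_slow = 10)
  ep <- epoch_session(split_conditions(s), epoch_len = 6)
  for (e in ep) {
    fast <- e$slices$fast; slow <- e$slices$slow
    if (fast$empty || slow$empty) next
    expect_lt(abs(fast$timestamps[1] - slow$timestamps[1]), 1 / 10)
    expect_equal(length(fast$timestamps), 6 * 64, tolerance = 0.01)
  }
})

test_that("events out of range are rejected", {
  s <- mk_session()
  ev <- data.frame(kind = "POPUP", time = 10, correct = 2, rt = 1,
                   mu = NA, value = NA)
  expect_error(session("X", s$blocks, s$streams, ev), "correctness")
  ev2 <- data.frame(kind = "ISA", time = 10, correct = NA, rt = NA,
                    mu = NA, value = 150)
  expect_error(session("X", s$blocks, s$streams, ev2), "ISA")
})
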