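# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# short multimodal session (2-min task blocks) without EEG: cheap enough
# for most pipeline tests
short_session <- function(seed = 11, streams = c("ecg", "et"),
                          block_s = 120, ...) {
  key <- paste("sess", seed, paste(streams, collapse = ""), block_s, ...)
  cached(key, {
    cfg <- effect_config(task_block_s = block_s, seed = seed, ...)
    generate_session(sprintf("S%02d", seed), cfg,
                     order = if (seed %% 2) "HLHL" else "LHLH",
                     streams = streams)
  })
}

short_table <- function(seed = 11, streams = c("ecg", "et"), block_s = 120) {
  key <- paste("tbl", seed, paste(streams, collapse = ""), block_s)
  cached(key, extract_features(short_session(seed, streams, block_s),
                               sensors = streams,
                               eeg_method = "regression"))
}

# synthetic feature table built directly (no signal processing): epochs of
# 4 task blocks in the given condition order, each feature = condition
# effect + N(0,1) noise + optional linear time drift
toy_table <- function(n_per_block = 20, n_features = 3, effect = 1,
                      drift = 0, order = c("LOW", "HIGH", "LOW", "HIGH"),
                      participant = "T01", seed = 1, block_s = 480) {
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_along(order), function(b) {
      data.frame(participant = participant, condition = order[b],
                 block_index = b * 2L,
                 epoch_index = seq_len(n_per_block),
                 start_time = (b - 1) * (block_s + 60) + 60 +
                   (seq_len(n_per_block) - 1) * 6)
    }))
    total <- max(rows$start_time)
    for (f in seq_len(n_features)) {
      rows[[paste0("f", f)]] <- rnorm(nrow(rows)) +
        effect * (rows$condition == "HIGH") + drift * rows$start_time / total
    }
    rows
  })
}

# two-participant named list of toy tables
toy_cohort <- function(n_participants = 4, ...) {
  out <- lapply(seq_len(n_participants), function(i)
    toy_table(participant = sprintf("T%02d", i), seed = 100 + i,
              order = if (i %% 2) c("LOW", "HIGH", "LOW", "HIGH")
                      else c("HIGH", "LOW", "HIGH", "LOW"), ...))
  names(out) <- sprintf("T%02d", seq_len(n_participants))
  out
}

# synthetic ECG trace: gaussian R waves at the given beat times
qrs_train <- function(beat_times, fs = 256, total = NULL, amp = 1) {
  total <- total %||% (max(beat_times) + 1)
  n <- round(total * fs)
  x <- 0.02 * sin(2 * pi * 0.3 * (0:(n - 1)) / fs)
  half <- round(0.01 * fs)
  amp <- rep_len(amp, length(beat_times))
  for (i in seq_along(beat_times)) {
    c0 <- round(beat_times[i] * fs)
    sel <- max(1, c0 - half):min(n, c0 + half)
    x[sel] <- x[sel] + amp[i] * exp(-((sel - c0) / (0.4 * half))^2)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
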