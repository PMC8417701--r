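# EEG preprocessing and spectral features: filter response, ocular
# cleanup, multitaper band power, engagement index.

fs <- 256
n6 <- 6 * fs
tt <- (0:(n6 - 1)) / fs

test_that("band definitions are validated", {
  b <- eeg_bands()
  expect_equal(b$theta, c(4, 8))
  expect_equal(b$beta, c(12, 30))
  expect_error(eeg_bands(alpha = c(12, 8)), "band edges")
})

test_that("average re-reference zeroes the channel mean at every sample", {
  x <- matrix(rnorm(n6 * 4), n6, 4)
  eog <- matrix(rnorm(n6 * 2), n6, 2)
  out <- preprocess_eeg(x, eog, fs, method = "none")
  expect_lt(max(abs(rowMeans(out))), 1e-10)
})

test_that("a 60 Hz tone is attenuated by at least 20 dB", {
  x <- cbind(sin(2 * pi * 10 * tt) + sin(2 * pi * 60 * tt))
  out <- preprocess_eeg(cbind(x, -x), matrix(0, n6, 1), fs,
                        method = "none")
  amp_at <- function(sig, f) {
    ft <- abs(fft(sig)) / length(sig)
    2 * ft[round(f * length(sig) / fs) + 1]
  }
  atten_db <- 20 * log10(amp_at(x[, 1], 60) / amp_at(out[, 1], 60))
  expect_gte(atten_db, 20)
  # passband (10 Hz) essentially untouched
  expect_equal(amp_at(out[, 1], 10), 1, tolerance = 0.05)
})

test_that("ocular components are removed against a known mixing", {
  withr::with_seed(42, {
    clean <- sapply(1:4, function(i) {
      sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)) + 0.3 * rnorm(n6)
    })
    src <- rep(0, n6)
    for (b0 in c(1, 2.8, 4.5)) {
      sel <- which(tt >= b0 & tt < b0 + 0.3)
      src[sel] <- 8 * (1 - cos(2 * pi * seq_along(sel) / length(sel)))
    }
    topo <- c(1, 0.6, 0.2, 0)
    x <- clean + outer(src, topo)
    eog <- cbind(src + 0.2 * rnorm(n6))
    for (method in c("ica", "regression")) {
      out <- preprocess_eeg(x, eog, fs, method = method)
      expect_lt(abs(cor(out[, 1], src)), abs(cor(x[, 1], src)))
      expect_lt(abs(cor(out[, 1], src)), 0.35)
    }
  })
})

test_that("high-rate epochs are decimated to 512 Hz without amplitude loss", {
  fs_hi <- 2048
  th <- (0:(6 * fs_hi - 1)) / fs_hi
  x <- sin(2 * pi * 10 * th)
  out <- preprocess_eeg(cbind(x, -x), matrix(0, length(x), 1), fs_hi,
                        method = "none")
  expect_equal(nrow(out), 6 * 512)
  expect_equal(attr(out, "fs"), 512)
  bp <- band_power(out)
  # unit sinusoid power 1/2 survives filtering + decimation
  expect_equal(unname(bp["alpha", 1]), 0.5, tolerance = 0.05)
  expect_error(preprocess_eeg(cbind(x, -x), matrix(0, length(x), 1),
                              fs = 1000, resample_to = 512),
               "integer multiple")
})

test_that("epochs shorter than the filter warm-up are rejected", {
  expect_error(preprocess_eeg(matrix(rnorm(64), 64, 1),
                              matrix(0, 64, 1), fs), "too short")
})

test_that("a pure 10 Hz tone concentrates its power in the alpha band", {
  x <- cbind(sin(2 * pi * 10 * tt))
  bp <- band_power(x, fs = fs)
  expect_gt(bp["alpha", 1] / max(bp["theta", 1], bp["beta", 1],
                                 bp["gamma", 1]), 100)
  # absolute power of a unit sinusoid is its variance, 1/2
  expect_equal(unname(bp["alpha", 1]), 0.5, tolerance = 0.05)
})

test_that("white-noise band powers are proportional to bandwidth", {
  withr::with_seed(1, {
    x <- matrix(rnorm(20 * fs * 3), ncol = 3)   # 20 s, 3 channels
    bp <- band_power(x, fs = fs)
    widths <- c(theta = 4, alpha = 4, beta = 18, gamma = 15)
    dens <- rowMeans(bp) / widths
    expect_lt(max(dens) / min(dens), 1.12)
    # density of N(0,1) noise is 2/fs per Hz (one-sided)
    expect_equal(unname(dens["beta"]), 2 / fs, tolerance = 0.05)
  })
})

test_that("zero signal has zero power and undefined engagement index", {
  bp <- band_power(matrix(0, n6, 2), fs = fs)
  expect_true(all(bp == 0))
  expect_true(all(is.na(engagement_index(bp))))
})

test_that("doubling amplitude quadruples power and leaves EI unchanged", {
  withr::with_seed(2, x <- matrix(rnorm(n6 * 2), n6, 2))
  bp1 <- band_power(x, fs = fs)
  bp2 <- band_power(2 * x, fs = fs)
  expect_equal(bp2, 4 * bp1, tolerance = 1e-10)
  expect_equal(engagement_index(bp1), engagement_index(bp2),
               tolerance = 1e-10)
})

test_that("engagement index follows its defining ratio", {
  p <- matrix(c(1, 3, 4, 0,    2, 1, 6, 0,    1, 1, 0, 0),
              nrow = 4, dimnames = list(c("theta", "alpha", "beta", "gamma"),
                                        c("e1", "e2", "e3")))
  ei <- engagement_index(p)
  expect_equal(unname(ei["e1"]), 1.0)   # 4 / (3 + 1)
  expect_equal(unname(ei["e2"]), 2.0)   # 6 / (1 + 2)
  expect_equal(unname(ei["e3"]), 0.0)   # beta = 0
  p0 <- p; p0[c("theta", "alpha"), 1] <- 0
  expect_true(is.na(engagement_index(p0)["e1"]))
})

test_that("multitaper psd integrates to the signal variance", {
  withr::with_seed(3, x <- rnorm(n6))
  spec <- multitaper_psd(x, fs)
  df <- spec$freq[2] - spec$freq[1]
  expect_equal(sum(spec$psd) * df, var(x) * (n6 - 1) / n6,
               tolerance = 0.02)
})

test_that("dpss tapers are orthonormal", {
  tp <- dpss_tapers(512, nw = 4, k = 7)
  g <- crossprod(tp)
  expect_equal(g, diag(7), tolerance = 1e-8)
})

test_that("synthetic high-load epochs carry more beta power at effect sites", {
  s <- short_session(31, streams = "eeg", block_s = 60)
  ep <- epoch_session(split_conditions(s))
  task <- Filter(function(e) e$block_kind != "REST", ep)
  pw <- vapply(task, function(e) {
    sl <- e$slices$eeg
    x <- preprocess_eeg(sl$samples[, eeg_electrodes()],
                        sl$samples[, c("VEOG", "HEOG")],
                        sl$nominal_rate, method = "regression")
    bp <- band_power(x)
    c(mean(bp["beta", eeg_effect_sites()]),
      mean(bp["gamma", eeg_effect_sites()]))
  }, numeric(2))
  cond <- vapply(task, function(e) e$block_kind, character(1))
  expect_gt(mean(pw[1, cond == "HIGH"]), mean(pw[1, cond == "LOW"]))
  expect_gt(mean(pw[2, cond == "HIGH"]), mean(pw[2, cond == "LOW"]))
})
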