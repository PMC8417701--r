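#' Extract RR intervals from an ECG epoch
#'
#' High-pass filters the trace (> 1 Hz), detects R peaks with a
#' derivative-energy detector and an adaptive amplitude threshold (a
#' fraction of the median candidate peak height, Pan-Tompkins style), and
#' returns successive peak differences.
#'
#' @param x single-channel ECG, numeric vector.
#' @param fs sampling rate, Hz.
#' @param threshold_frac peak acceptance threshold as a fraction of the
#'   median candidate peak amplitude (default 0.5).
#' @param refractory minimum peak separation, seconds (default 0.25).
#' @return List of class `rr_series`: `intervals` (ms), `times` (anchor
#'   time of each interval's end peak, seconds, relative to epoch start),
#'   `peaks` (peak sample indices), `empty` flag.
#' @export
extract_rr <- function(x, fs, threshold_frac = 0.5, refractory = 0.25) {
  x <- as.numeric(x)
  n <- length(x)
  empty <- function() structure(list(intervals = numeric(),
                                     times = numeric(), peaks = integer(),
                                     empty = TRUE), class = "rr_series")
  if (n < fs) return(empty())
  hp <- signal::butter(2, 1 / (fs / 2), type = "high")
  xf <- signal::filtfilt(hp, x)
  # derivative energy emphasizes the sharp QRS upstroke
  en <- c(0, diff(xf))^2
  w <- max(3L, round(0.06 * fs))
  en <- as.numeric(stats::filter(en, rep(1 / w, w), sides = 2))
  en[is.na(en)] <- 0
  if (max(en) <= 0 || sd(xf) < 1e-12) return(empty())
  # candidate local maxima of the energy envelope, refractory-separated
  cand <- which(diff(sign(diff(en))) < 0) + 1L
  if (!length(cand)) return(empty())
  # two-stage adaptive threshold on the amplitude scale (energy is
  # quadratic in peak height): provisional R peaks above half the maximum
  # set the typical R amplitude; acceptance is threshold_frac of its
  # median, so isolated low-amplitude beats survive while noise maxima
  # between beats stay below threshold
  amp <- sqrt(en[cand])
  provisional <- amp >= 0.5 * max(amp)
  thr <- threshold_frac * median(amp[provisional])
  cand <- cand[amp >= thr]
  cand <- cand[order(cand)]
  peaks <- integer()
  for (p in cand) {
    if (!length(peaks) || (p - peaks[length(peaks)]) > refractory * fs)
      peaks <- c(peaks, p)
    else if (en[p] > en[peaks[length(peaks)]])
      peaks[length(peaks)] <- p
  }
  # refine each peak to the local maximum of the filtered trace
  half <- round(0.04 * fs)
  peaks <- vapply(peaks, function(p) {
    sel <- max(1, p - half):min(n, p + half)
    sel[which.max(xf[sel])]
  }, integer(1))
  peaks <- unique(peaks)
  if (length(peaks) < 2) return(empty())
  structure(list(intervals = diff(peaks) / fs * 1000,
                 times = peaks[-1] / fs, peaks = peaks, empty = FALSE),
            class = "rr_series")
}

#' Malik-rule RR artifact cleaning
#'
#' Removes an interval when it deviates from the previous retained
#' interval by more than 20% of that interval. The first interval is
#' always kept. Idempotent: cleaning its own output changes nothing.
#'
#' @param rr an `rr_series` (or numeric vector of intervals in ms).
#' @param tolerance relative deviation threshold (default 0.2).
#' @return Cleaned `rr_series` (or numeric vector, matching the input).
#' @export
clean_rr_malik <- function(rr, tolerance = 0.2) {
  iv <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  if (length(iv) <= 1) return(rr)
  keep <- logical(length(iv))
  keep[1] <- TRUE
  prev <- iv[1]
  for (i in 2:length(iv)) {
    if (abs(iv[i] - prev) <= tolerance * prev) {
      keep[i] <- TRUE
      prev <- iv[i]
    }
  }
  if (inherits(rr, "rr_series")) {
    structure(list(intervals = iv[keep], times = rr$times[keep],
                   peaks = rr$peaks, empty = !any(keep)),
              class = "rr_series")
  } else iv[keep]
}

#' Heart rate and SDNN from an RR series
#'
#' `hr = 60000 / mean(RR)` (beats/min); `hrv_sdnn` is the sample standard
#' deviation of the intervals (ms). SDNN needs at least two intervals, HR
#' at least one; otherwise the value is `NA`.
#'
#' @param rr an `rr_series` or numeric vector of intervals in ms.
#' @return Named numeric vector `c(hr = , hrv_sdnn = )`.
#' @export
rr_features <- function(rr) {
  iv <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  hr <- if (length(iv) >= 1) 60000 / mean(iv) else NA_real_
  sdnn <- if (length(iv) >= 2) sd(iv) else NA_real_
  c(hr = hr, hrv_sdnn = sdnn)
}

#' Rest-baseline normalization
#'
#' Subtracts the mean of the feature over the immediately preceding rest
#' block from a task-epoch feature value.
#'
#' @param value feature value(s) for task epochs.
#' @param rest_mean mean of the same feature over the preceding rest
#'   block's epochs.
#' @return `value - rest_mean`.
#' @export
rest_normalize <- function(value, rest_mean) {
  if (length(rest_mean) != 1 || is.na(rest_mean))
    stop("missing rest baseline for normalization")
  value - rest_mean
}
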