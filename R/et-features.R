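#' Detect blinks from missing eye-tracking samples
#'
#' Blinks are inferred from gaps in the gaze stream: maximal runs of
#' invalid samples whose duration falls within `[min_blink, max_blink]`.
#' Shorter runs are treated as tracker dropout, longer ones as signal
#' loss; neither counts as a blink.
#'
#' @param valid logical vector of per-sample validity flags.
#' @param fs sampling rate, Hz.
#' @param min_blink,max_blink blink duration window, seconds (defaults
#'   0.07-0.5).
#' @return Data frame with `start`, `end`, `duration` (seconds, relative
#'   to slice start); zero rows when no blink is found.
#' @export
detect_blinks <- function(valid, fs, min_blink = 0.07, max_blink = 0.5) {
  empty <- data.frame(start = numeric(), end = numeric(), duration = numeric())
  if (!length(valid) || all(valid)) return(empty)
  r <- rle(!valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gap <- which(r$values)
  dur <- r$lengths[gap] / fs
  keep <- dur >= min_blink & dur <= max_blink
  data.frame(start = (starts[gap[keep]] - 1) / fs,
             end = ends[gap[keep]] / fs, duration = dur[keep])
}

#' Dispersion-threshold fixation detection (I-DT)
#'
#' Grows windows while the spatial dispersion (x range + y range) stays
#' within `dispersion` and emits a fixation when the window lasts at least
#' `min_duration`. Invalid (blink) samples break the window. Each fixation
#' is labeled with the modal AOI of its samples.
#'
#' @param gx,gy gaze coordinates (same units as `dispersion`).
#' @param times sample times, seconds.
#' @param aoi optional per-sample AOI labels.
#' @param valid optional validity flags.
#' @param dispersion dispersion threshold (default 1.5).
#' @param min_duration minimum fixation duration, seconds (default 0.1).
#' @return Data frame of fixations: `start`, `end`, `duration`,
#'   `centroid_x`, `centroid_y`, `aoi`.
#' @export
detect_fixations <- function(gx, gy, times, aoi = NULL, valid = NULL,
                             dispersion = 1.5, min_duration = 0.1) {
  n <- length(gx)
  if (is.null(valid)) valid <- !(is.na(gx) | is.na(gy))
  valid <- valid & !(is.na(gx) | is.na(gy))
  empty <- data.frame(start = numeric(), end = numeric(),
                      duration = numeric(), centroid_x = numeric(),
                      centroid_y = numeric(), aoi = character())
  if (!n || !any(valid)) return(empty)
  i0s <- integer(); i1s <- integer()
  i <- 1L
  while (i <= n) {
    if (!valid[i]) { i <- i + 1L; next }
    j <- i
    xmin <- gx[i]; xmax <- gx[i]; ymin <- gy[i]; ymax <- gy[i]
    while (j < n && valid[j + 1L]) {
      nxmin <- min(xmin, gx[j + 1L]); nxmax <- max(xmax, gx[j + 1L])
      nymin <- min(ymin, gy[j + 1L]); nymax <- max(ymax, gy[j + 1L])
      if ((nxmax - nxmin) + (nymax - nymin) > dispersion) break
      xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      j <- j + 1L
    }
    if (j > i && times[j] - times[i] >= min_duration) {
      i0s <- c(i0s, i); i1s <- c(i1s, j)
    }
    i <- j + 1L
  }
  if (!length(i0s)) return(empty)
  data.frame(
    start = times[i0s], end = times[i1s], duration = times[i1s] - times[i0s],
    centroid_x = vapply(seq_along(i0s),
                        function(k) mean(gx[i0s[k]:i1s[k]]), numeric(1)),
    centroid_y = vapply(seq_along(i0s),
                        function(k) mean(gy[i0s[k]:i1s[k]]), numeric(1)),
    aoi = if (is.null(aoi)) NA_character_ else
      vapply(seq_along(i0s), function(k)
        names(which.max(table(aoi[i0s[k]:i1s[k]]))), character(1)))
}

#' Summarize eye-tracking features for one epoch
#'
#' Counts and durations of fixations (overall and per analyzed AOI),
#' blink count and mean inter-blink latency, and mean pupil dilation of
#' both eyes. AOIs outside [analyzed_aois()] are pooled as off-screen and
#' excluded from the per-AOI columns.
#'
#' @param blinks data frame from [detect_blinks()].
#' @param fixations data frame from [detect_fixations()].
#' @param pupil numeric matrix or vector of pupil samples (both eyes).
#' @param epoch_len epoch duration, seconds.
#' @return Named numeric vector: `n_fixations`, `mean_fixation_duration`,
#'   `blink_count`, `blink_latency`, `pupil_dilation`, and per-AOI
#'   `aoi<k>_nfix` / `aoi<k>_dur`.
#' @export
summarize_et <- function(blinks, fixations, pupil, epoch_len = 6) {
  nfix <- nrow(fixations)
  out <- c(
    n_fixations = nfix,
    mean_fixation_duration = if (nfix) mean(fixations$duration) else NA_real_,
    blink_count = nrow(blinks),
    blink_latency = if (nrow(blinks) >= 2) mean(diff(blinks$start)) else NA_real_,
    pupil_dilation = if (length(pupil)) mean(pupil, na.rm = TRUE) else NA_real_)
  for (a in analyzed_aois()) {
    sel <- !is.na(fixations$aoi) & fixations$aoi == a
    tag <- gsub("\\.", "_", tolower(a))
    out[paste0(tag, "_nfix")] <- sum(sel)
    out[paste0(tag, "_dur")] <- if (any(sel)) sum(fixations$duration[sel]) else 0
  }
  out
}
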