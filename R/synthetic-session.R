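#' Retained EEG electrode montage
#'
#' The 20 scalp sites retained for classification, and the 10 sites at
#' which beta/gamma power increases under high workload.
#' @format Character vectors.
#' @name montage
NULL

#' @rdname montage
#' @export
eeg_electrodes <- function() {
  c("Fp1", "AF3", "F7", "F3", "FC5", "T7", "CP5", "P7", "PO3", "O1",
    "Oz", "O2", "PO4", "P8", "T8", "FC6", "F4", "F8", "AF4", "Fp2")
}

#' @rdname montage
#' @export
eeg_effect_sites <- function() {
  c("Fp2", "FC5", "FC6", "T7", "T8", "CP5", "P8", "O1", "Oz", "O2")
}

# parieto-occipital sites carrying the (slight) alpha decrease
eeg_parietal_sites <- function() c("P7", "PO3", "PO4", "P8")

#' Analyzed areas of interest
#'
#' The five screen regions entering the per-AOI features: the three flight
#' simulator screens (AOI1-AOI3) and the two most-used sub-areas of the UAV
#' interaction application (AOI4.1 path display, AOI4.2 request panel).
#' @return Character vector of AOI labels.
#' @export
analyzed_aois <- function() c("AOI1", "AOI2", "AOI3", "AOI4.1", "AOI4.2")

#' Workload effect configuration for the synthetic generator
#'
#' Magnitudes of the condition effects and nuisance structure the generator
#' injects. Defaults are calibrated to the direction pattern reported for
#' this protocol (higher beta/gamma power, heart rate, pupil dilation and
#' fixation count under high load; slightly lower parietal alpha, SDNN and
#' fixation duration) at magnitudes that place the synthetic benchmark in a
#' non-saturated 55-75% accuracy regime.
#'
#' @param eeg_beta_gamma_gain multiplicative beta/gamma *power* gain under
#'   HIGH at the 10 effect sites.
#' @param alpha_parietal_gain multiplicative alpha power gain (< 1) under
#'   HIGH at parieto-occipital sites.
#' @param hr_delta heart-rate increase under HIGH, beats/min.
#' @param sdnn_delta SDNN decrease under HIGH, ms.
#' @param pupil_delta pupil-dilation increase under HIGH, a.u.
#' @param fixation_rate_gain multiplicative increase of fixation rate under
#'   HIGH (shorter inter-fixation gaps).
#' @param fixation_duration_gain multiplicative change (< 1) of mean
#'   fixation duration under HIGH.
#' @param aoi_dwell_shift extra dwell probability moved onto AOI2 and
#'   AOI4.1 under HIGH.
#' @param drift_magnitude fractional peak-to-peak slow change of band
#'   amplitudes, RR baseline and pupil baseline across the session
#'   (time-on-task non-stationarity); 0 disables drift.
#' @param eeg_background relative amplitude of the broadband 1/f background
#'   (per-band oscillations have unit base amplitude).
#' @param eeg_amp_var log-SD of the slow multiplicative amplitude
#'   modulation of each band oscillation (EEG bursting; mean-one, ~5 s
#'   time constant), the main source of epoch-to-epoch band-power
#'   variability.
#' @param hr_slow_sd SD of the slow heart-rate baseline wander
#'   (Mayer-wave / respiratory-scale fluctuations), beats/min.
#' @param pupil_noise SD of slow pupil-diameter fluctuations, a.u.
#' @param resting_hr resting heart rate, beats/min.
#' @param sdnn_base resting RR variability (SDNN), ms.
#' @param alpha_amp participant alpha amplitude multiplier.
#' @param pupil_base baseline pupil size, a.u.
#' @param blink_rate blinks per minute (no condition effect is injected).
#' @param popup_correct,memory_correct named probabilities of a correct
#'   response per condition.
#' @param popup_rt_mean named mean response times per condition, s.
#' @param heading_sd named heading-deviation SD per condition, degrees.
#' @param zone_prob named per-second probability of entering a restricted
#'   zone per condition.
#' @param eeg_rate,ecg_rate,et_rate sampling rates, Hz.
#' @param task_block_s,rest_block_s block durations, seconds (protocol:
#'   480 s task, 60 s rest).
#' @param n_popup,n_atc events per task block.
#' @param seed integer seed making generation reproducible.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(eeg_beta_gamma_gain = 1.5,
                          alpha_parietal_gain = 0.9,
                          hr_delta = 5,
                          sdnn_delta = 10,
                          pupil_delta = 0.12,
                          fixation_rate_gain = 1.2,
                          fixation_duration_gain = 0.85,
                          aoi_dwell_shift = 0.10,
                          drift_magnitude = 0.2,
                          eeg_background = 0.25,
                          eeg_amp_var = 0.6,
                          hr_slow_sd = 4.5,
                          pupil_noise = 0.12,
                          resting_hr = 70,
                          sdnn_base = 50,
                          alpha_amp = 1,
                          pupil_base = 3,
                          blink_rate = 12,
                          popup_correct = c(LOW = 0.95, HIGH = 0.80),
                          popup_rt_mean = c(LOW = 1.2, HIGH = 1.8),
                          memory_correct = c(LOW = 0.90, HIGH = 0.70),
                          heading_sd = c(LOW = 10, HIGH = 18),
                          zone_prob = c(LOW = 0.005, HIGH = 0.05),
                          eeg_rate = 256, ecg_rate = 256, et_rate = 100,
                          task_block_s = 480, rest_block_s = 60,
                          n_popup = 15, n_atc = 6,
                          seed = 1L) {
  cfg <- as.list(environment())
  gains <- c(cfg$eeg_beta_gamma_gain, cfg$alpha_parietal_gain,
             cfg$fixation_rate_gain, cfg$fixation_duration_gain)
  if (any(gains <= 0)) stop("all gains must be > 0")
  if (cfg$drift_magnitude < 0) stop("drift_magnitude must be >= 0")
  if (any(c(cfg$eeg_rate, cfg$ecg_rate, cfg$et_rate) <= 0))
    stop("sampling rates must be > 0")
  if (any(c(cfg$task_block_s, cfg$rest_block_s) <= 0))
    stop("block durations must be > 0")
  class(cfg) <- "effect_config"
  cfg
}

#' Cohort specification for the synthetic generator
#'
#' @param n_participants number of participants (>= 2); task-block order
#'   alternates H-L-H-L / L-H-L-H across participants.
#' @param resting_hr_range,alpha_amp_range,pupil_base_range per-participant
#'   baseline randomization ranges.
#' @param effect an [effect_config()] shared by the cohort.
#' @param drop_et_last if `TRUE`, the last participant's eye-tracking
#'   stream is omitted (mirrors a cohort in which one fewer participant has
#'   usable gaze data).
#' @param streams physiological streams to generate for every participant
#'   (subset of `c("eeg", "ecg", "et")`).
#' @param seed master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 14,
                        resting_hr_range = c(60, 80),
                        alpha_amp_range = c(0.8, 1.2),
                        pupil_base_range = c(2.5, 3.5),
                        effect = effect_config(),
                        drop_et_last = FALSE,
                        streams = c("eeg", "ecg", "et"),
                        seed = 1L) {
  if (n_participants < 2) stop("n_participants must be >= 2")
  structure(as.list(environment()), class = "cohort_spec")
}

# ---- signal synthesis helpers ------------------------------------------

# folded two-sided frequency axis, cached per (n, fs)
folded_freq <- function(n, fs) {
  key <- sprintf("ff_%d_%g", n, fs)
  hit <- .mwbench_cache[[key]]
  if (!is.null(hit)) return(hit)
  freq <- (0:(n - 1)) * fs / n
  freq <- pmin(freq, fs - freq)
  .mwbench_cache[[key]] <- freq
  freq
}

# Spectrally-synthesized 1/f (pink) noise, unit variance. Drawing an
# independent complex Gaussian spectrum and keeping the real part of its
# inverse transform yields real Gaussian noise with the shaped spectrum.
pink_noise <- function(n) {
  f <- c(1, seq_len(n - 1))
  f <- sqrt(pmin(f, n - f + 1))
  z <- complex(real = rnorm(n), imaginary = rnorm(n)) / f
  x <- Re(fft(z, inverse = TRUE))
  x / sd(x)
}

# Band-limited Gaussian noise within [lo, hi] Hz (raised-cosine edges),
# unit variance; only in-band spectral bins are drawn.
band_noise <- function(n, fs, lo, hi, edge = 1) {
  key <- sprintf("bm_%d_%g_%g_%g", n, fs, lo, hi)
  cached <- .mwbench_cache[[key]]
  if (is.null(cached)) {
    freq <- folded_freq(n, fs)
    sel <- which(freq >= lo - edge & freq <= hi + edge)
    fr <- freq[sel]
    w <- rep(1, length(sel))
    w[fr < lo] <- 0.5 * (1 + cos(pi * (lo - fr[fr < lo]) / edge))
    w[fr > hi] <- 0.5 * (1 + cos(pi * (fr[fr > hi] - hi) / edge))
    cached <- list(sel = sel, w = w)
    .mwbench_cache[[key]] <- cached
  }
  m <- length(cached$sel)
  z <- complex(length.out = n)
  z[cached$sel] <- cached$w * complex(real = rnorm(m), imaginary = rnorm(m))
  x <- Re(fft(z, inverse = TRUE))
  s <- sd(x)
  if (s == 0) x else x / s
}

# smooth bump used as the ocular (blink) artifact waveform
blink_bump <- function(n_samp) {
  0.5 * (1 - cos(2 * pi * seq_len(n_samp) / (n_samp + 1)))
}

# per-sample condition indicator from the block table
condition_indicator <- function(times, blocks, kind) {
  ind <- rep(FALSE, length(times))
  for (i in which(blocks$kind == kind))
    ind <- ind | (times >= blocks$start_time[i] & times < blocks$end_time[i])
  ind
}

# multiplicative slow drift profile, zero-mean across the session
drift_profile <- function(times, total, magnitude) {
  1 + magnitude * (times / total - 0.5)
}

# slow AR(1) process sampled at 1 Hz and linearly interpolated onto a
# target time grid; stationary SD `sd_target`, time constant `tau` seconds
slow_ar <- function(times, total, sd_target, tau) {
  n1 <- max(2L, ceiling(total) + 1L)
  rho <- exp(-1 / tau)
  e <- rnorm(n1, 0, sd_target * sqrt(1 - rho^2))
  z <- numeric(n1)
  z[1] <- rnorm(1, 0, sd_target)
  for (k in 2:n1) z[k] <- rho * z[k - 1] + e[k]
  approx(seq(0, by = 1, length.out = n1), z, xout = times, rule = 2)$y
}

session_blocks <- function(order, task_s, rest_s) {
  kinds <- if (order == "HLHL") c("HIGH", "LOW", "HIGH", "LOW")
           else c("LOW", "HIGH", "LOW", "HIGH")
  kind <- character(9); dur <- numeric(9)
  kind[seq(1, 9, 2)] <- "REST"; dur[seq(1, 9, 2)] <- rest_s
  kind[seq(2, 8, 2)] <- kinds;  dur[seq(2, 8, 2)] <- task_s
  end <- cumsum(dur)
  data.frame(kind = kind, index = seq_len(9),
             start_time = c(0, end[-9]), end_time = end)
}

# ---- per-stream generators ---------------------------------------------

gen_eeg_stream <- function(cfg, blocks, total, blink_events) {
  fs <- cfg$eeg_rate
  n <- round(total * fs)
  t <- (0:(n - 1)) / fs
  high <- condition_indicator(t, blocks, "HIGH")
  drift <- drift_profile(t, total, cfg$drift_magnitude)
  chans <- eeg_electrodes()
  bands <- list(theta = c(4, 8), alpha = c(8, 12),
                beta = c(12, 30), gamma = c(30, 45))
  base_amp <- c(theta = 1, alpha = 1.5 * cfg$alpha_amp,
                beta = 0.8, gamma = 0.5)
  # blink artifact source with frontal topography
  src <- rep(0, n)
  for (bt in blink_events) {
    i0 <- round(bt * fs); len <- round(0.3 * fs)
    sel <- (i0 + 1):min(i0 + len, n)
    if (length(sel) > 1) src[sel] <- src[sel] + 40 * blink_bump(length(sel))
  }
  topo <- setNames(rep(0, length(chans)), chans)
  topo[c("Fp1", "Fp2")] <- 1
  topo[c("AF3", "AF4")] <- 0.6
  topo[c("F7", "F8", "F3", "F4")] <- 0.3
  # amplitude profiles: amplitude = sqrt(power gain) * drift; precomputed
  # once per (band, site-class) and shared across channels
  amp_profile <- function(power_gain) {
    gain <- rep(1, n)
    gain[high] <- power_gain
    sqrt(gain) * drift
  }
  profiles <- list(
    flat = amp_profile(1),
    bg = amp_profile(cfg$eeg_beta_gamma_gain),
    ap = amp_profile(cfg$alpha_parietal_gain))
  # mean-one lognormal slow amplitude modulation (bursting), independent
  # per channel and band; E[amp^2] = 1 so configured power gains survive
  burst <- function() {
    if (cfg$eeg_amp_var <= 0) return(1)
    g <- slow_ar(t, total, cfg$eeg_amp_var, tau = 5)
    exp(g - cfg$eeg_amp_var^2)
  }
  X <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  for (ci in seq_along(chans)) {
    ch <- chans[ci]
    x <- cfg$eeg_background * pink_noise(n)
    for (bn in names(bands)) {
      prof <- profiles$flat
      if (bn %in% c("beta", "gamma") && ch %in% eeg_effect_sites())
        prof <- profiles$bg
      if (bn == "alpha" && ch %in% eeg_parietal_sites())
        prof <- profiles$ap
      # synthesis support sits 0.5-1 Hz inside the nominal band edges so
      # neither the ramps nor multitaper smoothing (~0.7 Hz bandwidth at
      # 6-s epochs) pushes one band's power into a neighboring analysis band
      x <- x + (base_amp[[bn]] * prof * burst()) *
        band_noise(n, fs, bands[[bn]][1] + 1, bands[[bn]][2] - 1,
                   edge = 0.5)
    }
    X[, ci] <- x + topo[[ch]] * src
  }
  eog <- cbind(VEOG = src + 0.5 * rnorm(n), HEOG = 0.5 * rnorm(n))
  stream_recording("eeg", fs, t, cbind(X, eog))
}

gen_ecg_stream <- function(cfg, blocks, total) {
  fs <- cfg$ecg_rate
  # sequential RR generation following the instantaneous condition state
  beats <- numeric(ceiling(total / 0.3))
  # slow HR baseline wander (Mayer-wave scale), evaluated per beat
  wander_t <- seq(0, ceiling(total), by = 1)
  wander <- slow_ar(wander_t, total, cfg$hr_slow_sd, tau = 20)
  tcur <- 0.2; k <- 0
  while (tcur < total) {
    high <- any(blocks$kind == "HIGH" & tcur >= blocks$start_time &
                  tcur < blocks$end_time)
    hr <- cfg$resting_hr + (if (high) cfg$hr_delta else 0) +
      wander[min(length(wander), floor(tcur) + 1)]
    hr <- max(hr, 30)
    sdnn <- cfg$sdnn_base - if (high) cfg$sdnn_delta else 0
    rr_ms <- 60000 / hr * drift_profile(tcur, total, cfg$drift_magnitude)
    rr <- rnorm(1, rr_ms, max(sdnn, 1)) / 1000
    rr <- max(rr, 0.3)
    k <- k + 1; beats[k] <- tcur
    tcur <- tcur + rr
  }
  beats <- beats[seq_len(k)]
  n <- round(total * fs)
  t <- (0:(n - 1)) / fs
  x <- 0.03 * rnorm(n)
  qrs_half <- round(0.006 * fs)                 # ~12 ms wide R wave
  for (bt in beats) {
    i0 <- round(bt * fs)
    sel <- max(1, i0 - qrs_half):min(n, i0 + qrs_half)
    x[sel] <- x[sel] + exp(-((sel - i0) / (0.4 * qrs_half + 1e-9))^2)
  }
  st <- stream_recording("ecg", fs, t, matrix(x, ncol = 1,
                                              dimnames = list(NULL, "ECG")))
  attr(st, "beat_times") <- beats
  st
}

gen_et_stream <- function(cfg, blocks, total, blink_events) {
  fs <- cfg$et_rate
  n <- round(total * fs)
  t <- (0:(n - 1)) / fs
  aoi_centers <- list(
    "AOI1" = c(-30, 0), "AOI2" = c(-10, 0), "AOI3" = c(10, 0),
    "AOI4.1" = c(30, 5), "AOI4.2" = c(30, -5), "AOI4.3" = c(30, -15),
    "NO_SCREEN" = c(0, -30))
  base_probs <- c("AOI1" = 0.18, "AOI2" = 0.27, "AOI3" = 0.14,
                  "AOI4.1" = 0.14, "AOI4.2" = 0.21, "AOI4.3" = 0.02,
                  "NO_SCREEN" = 0.04)
  high_probs <- base_probs
  high_probs[c("AOI2", "AOI4.1")] <-
    high_probs[c("AOI2", "AOI4.1")] + cfg$aoi_dwell_shift / 2
  high_probs <- high_probs / sum(high_probs)
  gx <- numeric(n); gy <- numeric(n); aoi <- character(n)
  base_fix <- 0.30; base_gap <- 0.06
  tcur <- 0
  while (tcur < total) {
    high <- any(blocks$kind == "HIGH" & tcur >= blocks$start_time &
                  tcur < blocks$end_time)
    pr <- if (high) high_probs else base_probs
    # broad lognormal durations: fixation times are highly variable, which
    # keeps per-epoch summaries from being trivially separable
    dur <- rlnorm(1, log(base_fix *
                           if (high) cfg$fixation_duration_gain else 1), 0.6)
    dur <- min(max(dur, 0.1), 2.5)
    gap <- base_gap / if (high) cfg$fixation_rate_gain else 1
    lab <- sample(names(pr), 1, prob = pr)
    ctr <- aoi_centers[[lab]] + rnorm(2, 0, 0.3)
    # uniform grid: index arithmetic instead of timestamp scans
    grid_idx <- function(a, b)
      seq.int(max(1L, floor(a * fs) + 1L), min(n, ceiling(b * fs)))
    sel <- grid_idx(tcur, min(tcur + dur, total))
    gx[sel] <- ctr[1] + rnorm(length(sel), 0, 0.12)
    gy[sel] <- ctr[2] + rnorm(length(sel), 0, 0.12)
    aoi[sel] <- lab
    if (tcur + dur < total) {
      gsel <- grid_idx(tcur + dur, min(tcur + dur + gap, total))
      gx[gsel] <- ctr[1]; gy[gsel] <- ctr[2]  # transition samples
      aoi[gsel] <- "NO_SCREEN"
    }
    tcur <- tcur + dur + gap
  }
  aoi[aoi == ""] <- "NO_SCREEN"
  # pupil: baseline + condition effect + drift + slow fluctuation
  high_i <- condition_indicator(t, blocks, "HIGH")
  pupil <- cfg$pupil_base *
    drift_profile(t, total, cfg$drift_magnitude) +
    cfg$pupil_delta * high_i + slow_ar(t, total, cfg$pupil_noise, tau = 4)
  pl <- pupil + 0.02 * rnorm(n)
  prr <- pupil + 0.02 * rnorm(n)
  valid <- rep(TRUE, n)
  for (bt in blink_events) {
    dur <- runif(1, 0.1, 0.4)
    valid[t >= bt & t < bt + dur] <- FALSE
  }
  samp <- cbind(gaze_x = gx, gaze_y = gy, pupil_left = pl, pupil_right = prr)
  samp[!valid, ] <- NA
  stream_recording("et", fs, t, samp, valid = valid, aoi = aoi)
}

gen_events_and_behavior <- function(cfg, blocks, total) {
  ev <- list()
  heading_mu <- runif(1, 0, 360)
  # ATC + POPUP events per task block
  for (i in which(blocks$kind != "REST")) {
    cond <- blocks$kind[i]; t0 <- blocks$start_time[i]
    pop_t <- t0 + cumsum(runif(cfg$n_popup, 21, 24))
    pop_t <- pop_t[pop_t < blocks$end_time[i]]
    ev[[length(ev) + 1]] <- data.frame(
      kind = "POPUP", time = pop_t,
      correct = rbinom(length(pop_t), 1, cfg$popup_correct[[cond]]),
      rt = rlnorm(length(pop_t), log(cfg$popup_rt_mean[[cond]]), 0.25),
      mu = NA_real_, value = NA_real_)
    atc_t <- t0 + c(5, 5 + cumsum(runif(cfg$n_atc - 1, 80, 82)))
    atc_t <- atc_t[atc_t < blocks$end_time[i]]
    ev[[length(ev) + 1]] <- data.frame(
      kind = "ATC", time = atc_t,
      correct = rbinom(length(atc_t), 1, cfg$memory_correct[[cond]]),
      rt = rlnorm(length(atc_t), log(2.5), 0.25),
      mu = runif(length(atc_t), 0, 360), value = NA_real_)
  }
  # ISA probe at the start of each rest block after a task block
  for (i in which(blocks$kind == "REST" & blocks$index > 1)) {
    prev <- blocks$kind[i - 1]
    score <- min(100, max(0, rnorm(1, if (prev == "HIGH") 65 else 35, 8)))
    ev[[length(ev) + 1]] <- data.frame(
      kind = "ISA", time = blocks$start_time[i], correct = NA_real_,
      rt = NA_real_, mu = NA_real_, value = score)
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$time), ]
  rownames(events) <- NULL
  # heading trace at 2 Hz: relaxes toward the active commanded heading
  th <- seq(0, total - 0.5, by = 0.5)
  atc <- events[events$kind == "ATC", ]
  heading <- numeric(length(th))
  cur <- heading_mu; dev <- 0
  for (k in seq_along(th)) {
    newer <- atc$mu[atc$time <= th[k]]
    if (length(newer)) cur <- newer[length(newer)]
    cond_high <- any(blocks$kind == "HIGH" & th[k] >= blocks$start_time &
                       th[k] < blocks$end_time)
    sdv <- if (cond_high) cfg$heading_sd[["HIGH"]] else cfg$heading_sd[["LOW"]]
    dev <- 0.8 * dev + rnorm(1, 0, sdv * sqrt(1 - 0.8^2))
    heading[k] <- (cur + dev) %% 360
  }
  # restricted-zone occupancy ticks at 20 Hz within task blocks
  tz <- seq(0, total - 0.05, by = 0.05)
  occ <- rep(FALSE, length(tz))
  for (i in which(blocks$kind != "REST")) {
    cond <- blocks$kind[i]
    sel <- which(tz >= blocks$start_time[i] & tz < blocks$end_time[i])
    entries <- sel[runif(length(sel)) < cfg$zone_prob[[cond]] * 0.05]
    for (e0 in entries) {
      len <- round(runif(1, 0.5, 3) / 0.05)
      occ[e0:min(e0 + len, length(tz))] <- TRUE
    }
  }
  list(events = events,
       heading = stream_recording("heading", 2, th,
                                  matrix(heading, ncol = 1,
                                         dimnames = list(NULL, "heading"))),
       zone = stream_recording("zone", 20, tz,
                               matrix(as.numeric(occ), ncol = 1,
                                      dimnames = list(NULL, "occupied"))))
}

#' Generate one synthetic multimodal session
#'
#' Builds a full protocol session (4 task blocks alternating low/high
#' workload, 5 interleaved rest blocks) with EEG+EOG, ECG, eye-tracking,
#' heading and restricted-zone streams plus pop-up/ATC/ISA events, under
#' the effect structure of `config`. Output is byte-identical for a fixed
#' `config$seed`.
#'
#' @param participant_id identifier stored in the session.
#' @param config an [effect_config()].
#' @param order task-block condition order, `"HLHL"` or `"LHLH"`.
#' @param streams which physiological streams to generate (subset of
#'   `c("eeg", "ecg", "et")`); behavioral streams are always generated.
#' @return A validated [session()]. The true R-peak times of the ECG are
#'   attached to the ECG stream as attribute `beat_times`.
#' @export
generate_session <- function(participant_id, config = effect_config(),
                             order = c("HLHL", "LHLH"),
                             streams = c("eeg", "ecg", "et")) {
  order <- match.arg(order)
  cfg <- config
  blocks <- session_blocks(order, cfg$task_block_s, cfg$rest_block_s)
  total <- max(blocks$end_time)
  with_seed(cfg$seed, {
    blink_events <- sort(runif(round(cfg$blink_rate * total / 60), 0,
                               total - 0.5))
    # enforce >= 1 s separation so gaps never merge: blink count stays
    # exactly recoverable from the missing-sample runs
    if (length(blink_events) > 1)
      blink_events <- blink_events[c(TRUE, diff(blink_events) > 1)]
    st <- list()
    if ("eeg" %in% streams) st$eeg <- gen_eeg_stream(cfg, blocks, total,
                                                     blink_events)
    if ("ecg" %in% streams) st$ecg <- gen_ecg_stream(cfg, blocks, total)
    if ("et" %in% streams) st$et <- gen_et_stream(cfg, blocks, total,
                                                  blink_events)
    beh <- gen_events_and_behavior(cfg, blocks, total)
    st$heading <- beh$heading
    st$zone <- beh$zone
    session(participant_id, blocks, st, beh$events)
  })
}

#' Generate a synthetic cohort
#'
#' Participant baselines (resting heart rate, alpha amplitude, pupil
#' baseline) are drawn independently from the spec ranges; the task-block
#' order alternates H-L-H-L / L-H-L-H across participants.
#'
#' @param spec a [cohort_spec()].
#' @return List of [session()] objects, one per participant.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  n <- spec$n_participants
  draws <- with_seed(spec$seed, data.frame(
    hr = runif(n, spec$resting_hr_range[1], spec$resting_hr_range[2]),
    alpha = runif(n, spec$alpha_amp_range[1], spec$alpha_amp_range[2]),
    pupil = runif(n, spec$pupil_base_range[1], spec$pupil_base_range[2])))
  lapply(seq_len(n), function(i) {
    cfg <- spec$effect
    cfg$resting_hr <- draws$hr[i]
    cfg$alpha_amp <- draws$alpha[i]
    cfg$pupil_base <- draws$pupil[i]
    cfg$seed <- child_seed(spec$seed, "participant", i)
    streams <- spec$streams
    if (isTRUE(spec$drop_et_last) && i == n) streams <- setdiff(streams, "et")
    generate_session(sprintf("P%02d", i), cfg,
                     order = if (i %% 2 == 1) "HLHL" else "LHLH",
                     streams = streams)
  })
}
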