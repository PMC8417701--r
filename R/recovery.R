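#' Recover configured workload effects from a synthetic cohort
#'
#' Generator validation: runs the feature extractors over a cohort and
#' estimates the condition effects that [effect_config()] injected, so
#' parameter-recovery tests can compare estimate against configuration.
#' Estimators are chosen to be unbiased for what they recover:
#'
#' * `hr_delta`: mean rest-normalized heart rate HIGH minus LOW over
#'   6-s epochs (the [extract_features()] ECG pipeline), averaged over
#'   participants.
#' * `sdnn_delta`: LOW minus HIGH mean of per-epoch SDNN, without Malik
#'   cleaning: on artifact-free beats the 20% rule truncates the RR
#'   distribution tails and shrinks the SD it should estimate. The
#'   epoch (6-s) scale matches where the configured SDNN lives; slower
#'   heart-rate wander is nearly constant within an epoch and so stays
#'   out of the estimate.
#' * `pupil_delta`: condition coefficient of a per-participant linear
#'   model of raw epoch-mean pupil size on condition plus a linear time
#'   term, so the slow session drift is estimated jointly instead of
#'   leaking into the contrast.
#' * `beta_gain` / `gamma_gain`: HIGH/LOW ratio of oscillatory band power
#'   at the 10 effect sites, geometric-averaged over participants (the
#'   alternating block orders make slow drift cancel geometrically).
#'   Epochs are band-pass filtered and EOG-regression cleaned but not
#'   average re-referenced, and the aperiodic background - estimated per
#'   channel by least-squares fitting `a/f + w` to the multitaper density
#'   over 50-90 Hz, where the generator places no oscillation - is
#'   subtracted before forming the ratio, since channel mixing, 1/f
#'   background and broadband cleaning residue would otherwise dilute a
#'   pure oscillatory gain.
#'
#' @param sessions list of [session()] objects (a [generate_cohort()]
#'   output); order-balanced cohorts give unbiased estimates under drift.
#' @param epoch_len epoch length, seconds.
#' @param sensors which effect families to recover (any of `"ecg"`,
#'   `"et"`, `"eeg"`).
#' @return Named numeric vector with elements among `hr_delta`,
#'   `sdnn_delta`, `pupil_delta`, `beta_gain`, `gamma_gain`.
#' @export
recover_effects <- function(sessions, epoch_len = 6,
                            sensors = c("ecg", "et", "eeg")) {
  out <- c()
  have <- function(sens) {
    vapply(sessions, function(s) sens %in% names(s$streams), logical(1))
  }
  if ("ecg" %in% sensors && any(have("ecg"))) {
    per <- vapply(sessions[have("ecg")], function(s) {
      tb <- extract_features(s, epoch_len, sensors = "ecg")
      hrd <- mean(tb$ecg_hr[tb$condition == "HIGH"], na.rm = TRUE) -
        mean(tb$ecg_hr[tb$condition == "LOW"], na.rm = TRUE)
      ep <- epoch_session(split_conditions(s), epoch_len)
      task <- Filter(function(e) e$block_kind != "REST", ep)
      sdnn <- vapply(task, function(e) {
        sl <- e$slices$ecg
        rr <- extract_rr(sl$samples[, 1], sl$nominal_rate)
        rr_features(rr)[["hrv_sdnn"]]
      }, numeric(1))
      cond <- vapply(task, function(e) e$block_kind, character(1))
      sdd <- mean(sdnn[cond == "LOW"], na.rm = TRUE) -
        mean(sdnn[cond == "HIGH"], na.rm = TRUE)
      c(hrd, sdd)
    }, numeric(2))
    out <- c(out, hr_delta = mean(per[1, ]), sdnn_delta = mean(per[2, ]))
  }
  if ("et" %in% sensors && any(have("et"))) {
    per <- vapply(sessions[have("et")], function(s) {
      ep <- epoch_session(split_conditions(s), epoch_len)
      task <- Filter(function(e) e$block_kind != "REST", ep)
      pm <- vapply(task, function(e) {
        sl <- e$slices$et
        if (is.null(sl) || sl$empty) return(NA_real_)
        mean(sl$samples[, c("pupil_left", "pupil_right")], na.rm = TRUE)
      }, numeric(1))
      cond <- vapply(task, function(e) e$block_kind, character(1))
      tm <- vapply(task, function(e) e$start_time, numeric(1))
      fit <- lm(pm ~ I(cond == "HIGH") + tm)
      unname(coef(fit)[2])
    }, numeric(1))
    out <- c(out, pupil_delta = mean(per))
  }
  if ("eeg" %in% sensors && any(have("eeg"))) {
    bands <- eeg_bands()
    per <- vapply(sessions[have("eeg")], function(s) {
      ep <- epoch_session(split_conditions(s), epoch_len)
      task <- Filter(function(e) e$block_kind != "REST" &&
                       !is.null(e$slices$eeg) && !e$slices$eeg$empty, ep)
      cond <- vapply(task, function(e) e$block_kind, character(1))
      acc <- list(LOW = c(beta = 0, gamma = 0, bg = 0),
                  HIGH = c(beta = 0, gamma = 0, bg = 0))
      for (e in task) {
        sl <- e$slices$eeg
        x <- preprocess_eeg(sl$samples[, eeg_effect_sites(), drop = FALSE],
                            sl$samples[, c("VEOG", "HEOG"), drop = FALSE],
                            fs = sl$nominal_rate, high = 120,
                            method = "regression", reref = FALSE)
        spec <- multitaper_psd(x, attr(x, "fs"))
        fsel <- spec$freq >= 50 & spec$freq <= 90
        # per-channel background psd ~ a/f + w (pink + flat residue)
        basis <- cbind(1 / spec$freq[fsel], 1)
        coefs <- qr.solve(basis, spec$psd[fsel, , drop = FALSE])
        df <- spec$freq[2] - spec$freq[1]
        pw <- vapply(c("beta", "gamma"), function(bn) {
          b <- bands[[bn]]
          sel <- spec$freq >= b[1] & spec$freq < b[2]
          bg <- coefs[1, ] * log(b[2] / b[1]) + coefs[2, ] * (b[2] - b[1])
          mean(colSums(spec$psd[sel, , drop = FALSE]) * df - bg)
        }, numeric(1))
        acc[[e$block_kind]] <- acc[[e$block_kind]] + c(pw, bg = 0)
      }
      nl <- sum(cond == "LOW"); nh <- sum(cond == "HIGH")
      c(beta = (acc$HIGH[["beta"]] / nh) / (acc$LOW[["beta"]] / nl),
        gamma = (acc$HIGH[["gamma"]] / nh) / (acc$LOW[["gamma"]] / nl))
    }, numeric(2))
    out <- c(out, beta_gain = exp(mean(log(per[1, ]))),
             gamma_gain = exp(mean(log(per[2, ]))))
  }
  out
}
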