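#' EEG frequency band definitions
#'
#' Default bands: theta 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz, gamma
#' 30-45 Hz. Band membership is half-open (`low <= f < high`) so adjacent
#' bands do not share bins.
#'
#' @param theta,alpha,beta,gamma numeric length-2 vectors `c(low, high)`.
#' @return Named list of band edges.
#' @export
eeg_bands <- function(theta = c(4, 8), alpha = c(8, 12),
                      beta = c(12, 30), gamma = c(30, 45)) {
  bands <- list(theta = theta, alpha = alpha, beta = beta, gamma = gamma)
  for (b in bands) if (!(b[1] > 0 && b[2] > b[1]))
    stop("band edges must satisfy 0 < low < high")
  bands
}

# Zero-phase band-pass applied in the frequency domain: the squared
# magnitude of an order-2 Butterworth high-pass cascaded with an order-6
# low-pass (the response a forward-backward IIR pass would have), exact in
# phase and numerically stable at low corner frequencies. Operates on all
# channels of the epoch at once.
bandpass_zerophase <- function(x, fs, low, high) {
  x <- as.matrix(x)
  n <- nrow(x)
  freq <- folded_freq(n, fs)
  g <- rep(1, n)
  nz <- freq > 0
  g[nz] <- 1 / (1 + (low / freq[nz])^4)      # |H_hp|^2, order 2
  g[!nz] <- 0
  g <- g / (1 + (freq / high)^12)            # |H_lp|^2, order 6
  ctr <- colMeans(x)
  f <- mvfft(sweep(x, 2, ctr)) * g
  out <- Re(mvfft(f, inverse = TRUE)) / n
  colnames(out) <- colnames(x)
  out
}

#' Preprocess one EEG epoch
#'
#' Zero-phase band-pass filtering (default 1-45 Hz; a strict 1-40 Hz mode
#' is available through `high`), resampling down to `resample_to` Hz when
#' the input rate exceeds it, ocular artifact removal against the EOG
#' reference channels, and average re-referencing.
#'
#' Ocular removal methods: `"ica"` decomposes the EEG with [fast_ica()]
#' and zeroes components whose absolute correlation with any EOG channel
#' exceeds `eog_threshold` (falling back to regression with a warning if
#' the decomposition fails to converge); `"regression"` subtracts the
#' least-squares projection onto the EOG channels; `"none"` skips removal.
#'
#' @param epoch_eeg numeric matrix, samples x EEG channels.
#' @param eog_channels numeric matrix, samples x EOG channels.
#' @param fs input sampling rate, Hz.
#' @param low,high filter corners, Hz.
#' @param resample_to target rate ceiling, Hz (default 512; a no-op when
#'   `fs <= resample_to`).
#' @param method ocular removal method.
#' @param eog_threshold absolute correlation above which a component is
#'   considered ocular.
#' @param reref apply average re-referencing (default `TRUE`; parameter
#'   recovery diagnostics disable it because the channel-mean subtraction
#'   mixes sites and biases site-level power contrasts).
#' @return Cleaned matrix with attribute `fs` (possibly reduced rate).
#' @export
preprocess_eeg <- function(epoch_eeg, eog_channels, fs,
                           low = 1, high = 45, resample_to = 512,
                           method = c("ica", "regression", "none"),
                           eog_threshold = 0.8, reref = TRUE) {
  method <- match.arg(method)
  x <- as.matrix(epoch_eeg)
  if (nrow(x) < 4 * ceiling(fs / low))
    stop("epoch too short for the filter warm-up; use longer epochs")
  eog <- as.matrix(eog_channels)
  x <- bandpass_zerophase(x, fs, low, high)
  eog <- bandpass_zerophase(eog, fs, low, high)
  if (fs > resample_to) {
    if (fs %% resample_to != 0)
      stop("input rate must be an integer multiple of resample_to")
    q <- fs %/% resample_to
    x <- apply(x, 2, signal::decimate, q = q)
    eog <- apply(eog, 2, signal::decimate, q = q)
    fs <- resample_to
  }
  if (method == "ica") {
    dec <- fast_ica(x)
    if (!dec$converged) {
      warning("ICA did not converge; falling back to EOG regression")
      method <- "regression"
    } else {
      cors <- abs(stats::cor(dec$S, eog))
      ocular <- apply(cors, 1, max) > eog_threshold
      if (any(ocular)) {
        S <- dec$S
        S[, ocular] <- 0
        x <- S %*% t(dec$A)
        x <- sweep(x, 2, -dec$center)
      }
    }
  }
  if (method == "regression") {
    beta <- qr.solve(cbind(1, eog), x)
    x <- x - cbind(1, eog) %*% beta
  }
  if (reref) x <- x - rowMeans(x)            # average re-reference
  colnames(x) <- colnames(epoch_eeg)
  attr(x, "fs") <- fs
  x
}

#' Absolute band power per electrode
#'
#' Integrates the multitaper power spectral density over each band
#' (half-open in frequency). Deterministic given its input.
#'
#' @param cleaned numeric matrix, samples x channels (see
#'   [preprocess_eeg()]), with attribute `fs` or an explicit `fs`.
#' @param bands band definitions from [eeg_bands()].
#' @param fs sampling rate, Hz.
#' @param nw multitaper time-bandwidth product.
#' @return Matrix bands x channels of absolute power (signal units^2).
#' @export
band_power <- function(cleaned, bands = eeg_bands(),
                       fs = attr(cleaned, "fs"), nw = 4) {
  x <- as.matrix(cleaned)
  if (is.null(fs)) stop("sampling rate not supplied")
  spec <- multitaper_psd(x, fs, nw = nw)
  df <- spec$freq[2] - spec$freq[1]
  out <- matrix(0, length(bands), ncol(x),
                dimnames = list(names(bands), colnames(x)))
  nyq <- fs / 2
  for (bn in names(bands)) {
    b <- bands[[bn]]
    if (b[2] > nyq)
      warning("band ", bn, " extends beyond the Nyquist frequency")
    sel <- spec$freq >= b[1] & spec$freq < b[2]
    out[bn, ] <- colSums(spec$psd[sel, , drop = FALSE]) * df
  }
  out
}

#' Engagement index
#'
#' The spectral ratio beta / (alpha + theta) per electrode; a workload /
#' engagement marker that rises with task demand. Electrodes with zero
#' alpha + theta power yield `NA` rather than infinity.
#'
#' @param powers bands x channels matrix from [band_power()] (rows must
#'   include `theta`, `alpha`, `beta`).
#' @return Named numeric vector, one engagement index per electrode.
#' @export
engagement_index <- function(powers) {
  stopifnot(all(c("theta", "alpha", "beta") %in% rownames(powers)))
  denom <- powers["alpha", ] + powers["theta", ]
  ei <- ifelse(denom > 0, powers["beta", ] / denom, NA_real_)
  names(ei) <- colnames(powers)
  ei
}
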