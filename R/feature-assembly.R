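#' Extract the per-epoch multimodal feature table for one session
#'
#' Runs the full extraction pipeline: 6-s epoching of every stream, EEG
#' preprocessing and spectral features (band powers and engagement index
#' per retained electrode), ECG RR extraction with Malik cleaning and
#' rest-baseline-normalized HR/SDNN, and eye-tracking blink / fixation /
#' AOI / pupil features (pupil epoch means are z-scored per participant
#' across the session). Rest epochs feed the ECG baseline and are not
#' returned as rows.
#'
#' @param s a [session()].
#' @param epoch_len epoch length, seconds.
#' @param eeg_method ocular-removal method passed to [preprocess_eeg()].
#' @param eeg_high upper filter corner, Hz (45 widens the filter to cover
#'   the gamma band; set 40 for a strict low-pass at 40 Hz).
#' @param sensors which feature families to extract (subset of
#'   `c("eeg", "ecg", "et")`); families whose stream is absent are skipped.
#' @return Data frame with metadata columns (`participant`, `condition`,
#'   `block_index`, `epoch_index`, `start_time`) and feature columns
#'   prefixed `eeg_` / `ecg_` / `et_`.
#' @export
extract_features <- function(s, epoch_len = 6,
                             eeg_method = c("ica", "regression", "none"),
                             eeg_high = 45,
                             sensors = c("eeg", "ecg", "et")) {
  eeg_method <- match.arg(eeg_method)
  sensors <- intersect(sensors, names(s$streams))
  split <- split_conditions(s)
  epochs <- epoch_session(split, epoch_len)
  is_task <- vapply(epochs, function(e) e$block_kind != "REST", logical(1))

  ecg_of <- function(e) {
    sl <- e$slices$ecg
    if (is.null(sl) || sl$empty) return(c(hr = NA_real_, hrv_sdnn = NA_real_))
    rr <- extract_rr(sl$samples[, 1], sl$nominal_rate)
    if (rr$empty) return(c(hr = NA_real_, hrv_sdnn = NA_real_))
    rr_features(clean_rr_malik(rr))
  }

  rows <- list()
  # ECG rest baselines: mean feature per rest block
  rest_base <- NULL
  if ("ecg" %in% sensors) {
    rest_eps <- epochs[!is_task]
    if (length(rest_eps)) {
      vals <- t(vapply(rest_eps, ecg_of, numeric(2)))
      bidx <- vapply(rest_eps, function(e) e$block_index, numeric(1))
      rest_base <- aggregate(vals, list(block = bidx), mean, na.rm = TRUE)
    }
  }
  blocks <- s$blocks[order(s$blocks$start_time), ]
  preceding_rest <- function(block_index) {
    i <- which(blocks$index == block_index)
    cand <- blocks$index[seq_len(i - 1)][blocks$kind[seq_len(i - 1)] == "REST"]
    if (!length(cand)) stop("no rest block precedes block ", block_index)
    cand[length(cand)]
  }

  for (e in epochs[is_task]) {
    row <- list(participant = s$participant_id, condition = e$block_kind,
                block_index = e$block_index, epoch_index = e$epoch_index,
                start_time = e$start_time)
    if ("eeg" %in% sensors && !is.null(e$slices$eeg) && !e$slices$eeg$empty) {
      sl <- e$slices$eeg
      eeg_cols <- intersect(eeg_electrodes(), colnames(sl$samples))
      eog_cols <- intersect(c("VEOG", "HEOG"), colnames(sl$samples))
      cleaned <- preprocess_eeg(sl$samples[, eeg_cols, drop = FALSE],
                                sl$samples[, eog_cols, drop = FALSE],
                                fs = sl$nominal_rate, high = eeg_high,
                                method = eeg_method)
      bp <- band_power(cleaned)
      ei <- engagement_index(bp)
      for (bn in rownames(bp))
        row[paste0("eeg_", bn, "_", colnames(bp))] <- bp[bn, ]
      row[paste0("eeg_ei_", names(ei))] <- ei
    }
    if ("ecg" %in% sensors) {
      feats <- ecg_of(e)
      base <- rest_base[rest_base$block == preceding_rest(e$block_index), ]
      row$ecg_hr <- feats[["hr"]] - base$hr
      row$ecg_hrv <- feats[["hrv_sdnn"]] - base$hrv_sdnn
      row$ecg_hr_raw <- feats[["hr"]]
      row$ecg_hrv_raw <- feats[["hrv_sdnn"]]
    }
    if ("et" %in% sensors && !is.null(e$slices$et) && !e$slices$et$empty) {
      sl <- e$slices$et
      tt <- sl$timestamps
      blinks <- detect_blinks(sl$valid, sl$nominal_rate)
      fixes <- detect_fixations(sl$samples[, "gaze_x"], sl$samples[, "gaze_y"],
                                tt, aoi = sl$aoi, valid = sl$valid)
      et <- summarize_et(blinks, fixes,
                         sl$samples[, c("pupil_left", "pupil_right")],
                         epoch_len = e$duration)
      nm <- names(et)
      nm[nm == "n_fixations"] <- "nfix"
      nm[nm == "mean_fixation_duration"] <- "fixdur"
      nm[nm == "blink_count"] <- "nblink"
      nm[nm == "blink_latency"] <- "blinklat"
      nm[nm == "pupil_dilation"] <- "pupil"
      row[paste0("et_", nm)] <- unname(et)
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row, check.names = FALSE)
  }
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  if ("et_pupil" %in% names(tbl)) {
    mu <- mean(tbl$et_pupil, na.rm = TRUE)
    sg <- sd(tbl$et_pupil, na.rm = TRUE)
    tbl$et_pupil_raw <- tbl$et_pupil
    tbl$et_pupil <- if (is.finite(sg) && sg > 0) (tbl$et_pupil - mu) / sg
                    else tbl$et_pupil - mu
  }
  tbl
}

#' Extract feature tables for a whole cohort
#'
#' @param sessions list of [session()] objects (see [generate_cohort()]).
#' @param ... passed to [extract_features()].
#' @return Named list of per-participant feature tables.
#' @export
assemble_cohort <- function(sessions, ...) {
  out <- lapply(sessions, extract_features, ...)
  names(out) <- vapply(sessions, function(s) s$participant_id, character(1))
  out
}

#' The seven sensor-combination feature sets
#'
#' Pinned column compositions: EEG = beta power, gamma power and
#' engagement index at each of the 20 retained electrodes (60 columns);
#' ECG = rest-normalized heart rate and SDNN (2 columns); ET = fixation
#' count, mean fixation duration, pupil dilation and per-AOI fixation
#' count/total duration for the 5 analyzed AOIs (13 columns; blink
#' features are excluded, mirroring the load-significance selection rule).
#'
#' @return Named list of 7 character vectors of column names, keyed
#'   `EEG`, `ECG`, `ET`, `EEG+ECG`, `EEG+ET`, `ECG+ET`, `EEG+ECG+ET`.
#' @export
feature_sets <- function() {
  el <- eeg_electrodes()
  eeg <- c(paste0("eeg_beta_", el), paste0("eeg_gamma_", el),
           paste0("eeg_ei_", el))
  ecg <- c("ecg_hr", "ecg_hrv")
  tags <- gsub("\\.", "_", tolower(analyzed_aois()))
  et <- c("et_nfix", "et_fixdur", "et_pupil",
          paste0("et_", tags, "_nfix"), paste0("et_", tags, "_dur"))
  list("EEG" = eeg, "ECG" = ecg, "ET" = et,
       "EEG+ECG" = c(eeg, ecg), "EEG+ET" = c(eeg, et),
       "ECG+ET" = c(ecg, et), "EEG+ECG+ET" = c(eeg, ecg, et))
}

#' Significance-based feature selection
#'
#' For each feature, condition means are computed per participant and a
#' paired two-sided location test across participants compares LOW vs.
#' HIGH: a paired t-test when the differences pass a Shapiro-Wilk
#' normality check, a Wilcoxon signed-rank test otherwise. Features with
#' p below `alpha` are retained. Respecting the repeated-measures
#' structure, the test operates on per-participant condition means, not
#' pooled epochs.
#'
#' @param tables named list of per-participant feature tables (or one
#'   combined table with a `participant` column).
#' @param alpha significance level (default 0.05, uncorrected per-feature
#'   tests).
#' @param features candidate columns (default: all feature columns).
#' @return Character vector of retained column names, with a `stats`
#'   attribute (data frame of per-feature p-values and test used).
#' @export
select_features <- function(tables, alpha = 0.05, features = NULL) {
  tbl <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  meta <- c("participant", "condition", "block_index", "epoch_index",
            "start_time")
  if (is.null(features))
    features <- setdiff(names(tbl), c(meta, grep("_raw$", names(tbl),
                                                 value = TRUE)))
  stats_rows <- list()
  for (f in features) {
    agg <- aggregate(tbl[[f]],
                     list(participant = tbl$participant,
                          condition = tbl$condition), mean, na.rm = TRUE)
    wide <- merge(agg[agg$condition == "LOW", c("participant", "x")],
                  agg[agg$condition == "HIGH", c("participant", "x")],
                  by = "participant", suffixes = c("_low", "_high"))
    d <- wide$x_high - wide$x_low
    d <- d[is.finite(d)]
    if (length(d) < 2 || all(d == 0) || sd(d) == 0) {
      if (all(d == 0)) warning("feature '", f, "' is constant across ",
                               "conditions; dropped")
      stats_rows[[f]] <- data.frame(feature = f, p = NA_real_,
                                    test = "none", keep = FALSE)
      next
    }
    normal <- length(d) >= 3 && shapiro.test(d)$p.value > 0.05
    p <- if (normal) t.test(d)$p.value
         else suppressWarnings(wilcox.test(d, exact = FALSE)$p.value)
    stats_rows[[f]] <- data.frame(feature = f, p = p,
                                  test = if (normal) "t" else "wilcoxon",
                                  keep = p < alpha)
  }
  st <- do.call(rbind, stats_rows)
  rownames(st) <- NULL
  kept <- st$feature[st$keep]
  attr(kept, "stats") <- st
  kept
}
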