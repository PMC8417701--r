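#' Multichannel timestamped stream
#'
#' Container for one recorded stream (EEG+EOG+ECG, eye-tracking, heading,
#' restricted-zone occupancy). Eye-tracking streams additionally carry a
#' per-sample validity flag and an area-of-interest (AOI) label.
#'
#' @param name stream identifier, e.g. `"eeg"`, `"et"`.
#' @param nominal_rate nominal sampling rate in Hz (> 0).
#' @param timestamps numeric vector of sample times in seconds from session
#'   start, strictly increasing.
#' @param samples numeric matrix, one row per timestamp, one column per
#'   channel.
#' @param channel_labels character vector of column names.
#' @param valid optional logical vector (eye-tracking validity per sample).
#' @param aoi optional character vector of per-sample AOI labels.
#' @return An object of class `stream_recording`.
#' @export
stream_recording <- function(name, nominal_rate, timestamps, samples,
                             channel_labels = colnames(samples),
                             valid = NULL, aoi = NULL) {
  samples <- as.matrix(samples)
  if (nominal_rate <= 0) stop("nominal_rate must be > 0")
  if (nrow(samples) != length(timestamps))
    stop("samples row count must equal timestamp count")
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (!is.null(valid) && length(valid) != length(timestamps))
    stop("valid must have one flag per sample")
  if (!is.null(aoi) && length(aoi) != length(timestamps))
    stop("aoi must have one label per sample")
  if (!is.null(channel_labels)) colnames(samples) <- channel_labels
  structure(
    list(name = name, nominal_rate = nominal_rate,
         timestamps = as.numeric(timestamps), samples = samples,
         channel_labels = colnames(samples), valid = valid, aoi = aoi),
    class = "stream_recording")
}

#' @export
print.stream_recording <- function(x, ...) {
  cat(sprintf("<stream_recording '%s'> %d samples x %d channels @ %g Hz\n",
              x$name, nrow(x$samples), ncol(x$samples), x$nominal_rate))
  invisible(x)
}

#' A participant's full session recording
#'
#' A session holds the block layout (four 8-min task blocks alternating low
#' and high workload, interleaved with five 1-min rest blocks), the
#' recorded streams, and the event stream (pop-up probes, ATC commands, ISA
#' ratings).
#'
#' @param participant_id participant identifier.
#' @param blocks data frame with columns `kind` (`"LOW"`, `"HIGH"`,
#'   `"REST"`), `index`, `start_time`, `end_time` (seconds).
#' @param streams named list of [stream_recording()] objects.
#' @param events data frame with columns `kind` (`"POPUP"`, `"ATC"`,
#'   `"ISA"`), `time`, `correct` (0/1), `rt` (s), `mu` (commanded heading,
#'   degrees), `value` (ISA score or channel payload).
#' @param validate check session invariants (default `TRUE`).
#' @return An object of class `session`.
#' @export
session <- function(participant_id, blocks, streams, events = NULL,
                    validate = TRUE) {
  if (is.null(events))
    events <- data.frame(kind = character(), time = numeric(),
                         correct = numeric(), rt = numeric(),
                         mu = numeric(), value = numeric())
  s <- structure(
    list(participant_id = participant_id, blocks = blocks,
         streams = streams, events = events),
    class = "session")
  if (validate) validate_session(s)
  s
}

#' Validate session invariants
#'
#' Checks the protocol structure: exactly 4 task blocks (2 LOW, 2 HIGH) and
#' 5 rest blocks, alternating task order (H-L-H-L or L-H-L-H),
#' non-overlapping time-ordered blocks, and well-formed events.
#'
#' @param s a [session()].
#' @return `s`, invisibly; errors describe the violated invariant.
#' @export
validate_session <- function(s) {
  b <- s$blocks
  stopifnot(is.data.frame(b),
            all(c("kind", "index", "start_time", "end_time") %in% names(b)))
  if (any(b$end_time <= b$start_time)) stop("block end_time must exceed start_time")
  b <- b[order(b$start_time), ]
  if (any(b$start_time[-1] < b$end_time[-nrow(b)]))
    stop("blocks overlap in time")
  n_low <- sum(b$kind == "LOW"); n_high <- sum(b$kind == "HIGH")
  n_rest <- sum(b$kind == "REST")
  if (n_low != 2L) stop("session must contain exactly 2 LOW blocks (found ", n_low, ")")
  if (n_high != 2L) stop("session must contain exactly 2 HIGH blocks (found ", n_high, ")")
  if (n_rest != 5L) stop("session must contain exactly 5 REST blocks (found ", n_rest, ")")
  task <- b$kind[b$kind != "REST"]
  if (!identical(task, c("HIGH", "LOW", "HIGH", "LOW")) &&
      !identical(task, c("LOW", "HIGH", "LOW", "HIGH")))
    stop("task-block order must alternate H-L-H-L or L-H-L-H")
  ev <- s$events
  if (nrow(ev)) {
    pop <- ev[ev$kind == "POPUP", ]
    if (any(!pop$correct %in% c(0, 1))) stop("POPUP correctness must be 0/1")
    if (any(pop$rt < 0, na.rm = TRUE)) stop("response times must be >= 0")
    isa <- ev[ev$kind == "ISA", ]
    if (any(isa$value < 0 | isa$value > 100, na.rm = TRUE))
      stop("ISA scores must lie in [0, 100]")
  }
  invisible(s)
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session '%s'> %d blocks, streams: %s, %d events\n",
              x$participant_id, nrow(x$blocks),
              paste(names(x$streams), collapse = ", "), nrow(x$events)))
  invisible(x)
}

slice_stream <- function(st, t0, t1) {
  keep <- st$timestamps >= t0 & st$timestamps < t1
  stream_recording(st$name, st$nominal_rate,
                   st$timestamps[keep], st$samples[keep, , drop = FALSE],
                   valid = st$valid[keep], aoi = st$aoi[keep])
}

#' Split a session into per-condition block slices
#'
#' Separates a participant's recording into its 9 protocol blocks (2 LOW,
#' 2 HIGH, 5 REST), each slice carrying its own cut of every stream.
#'
#' @param s a [session()].
#' @return A list with elements `LOW`, `HIGH`, `REST`; each a list of block
#'   slices (`kind`, `index`, `start_time`, `end_time`, `participant_id`,
#'   `streams`).
#' @export
split_conditions <- function(s) {
  validate_session(s)
  b <- s$blocks[order(s$blocks$start_time), ]
  out <- list(LOW = list(), HIGH = list(), REST = list())
  for (i in seq_len(nrow(b))) {
    sl <- list(kind = b$kind[i], index = b$index[i],
               start_time = b$start_time[i], end_time = b$end_time[i],
               participant_id = s$participant_id,
               streams = lapply(s$streams, slice_stream,
                                t0 = b$start_time[i], t1 = b$end_time[i]))
    out[[b$kind[i]]] <- c(out[[b$kind[i]]], list(sl))
  }
  out
}

#' Cut block slices into aligned fixed-length epochs
#'
#' Epochs are anchored at the block start on a fixed grid; the trailing
#' remainder shorter than `epoch_len` is discarded. Epoch boundaries are
#' taken on the highest-rate stream present (the reference); every other
#' stream is cut at its own timestamp nearest each reference boundary, so
#' cross-stream alignment error is at most half a sample period of the
#' slower stream.
#'
#' @param block_slices output of [split_conditions()], or a plain list of
#'   block slices.
#' @param epoch_len epoch length in seconds (default 6).
#' @return List of epochs; each has `participant_id`, `block_kind`,
#'   `block_index`, `epoch_index`, `start_time`, `duration` and `slices`
#'   (per-stream `timestamps`/`samples`/`valid`/`aoi`, possibly empty and
#'   flagged with `empty = TRUE`).
#' @export
epoch_session <- function(block_slices, epoch_len = 6) {
  stopifnot(epoch_len > 0)
  if (!is.null(block_slices$streams)) block_slices <- list(block_slices)
  if (all(c("LOW", "HIGH", "REST") %in% names(block_slices)))
    block_slices <- c(block_slices$LOW, block_slices$HIGH, block_slices$REST)
  epochs <- list()
  for (bl in block_slices) {
    n_ep <- floor((bl$end_time - bl$start_time) / epoch_len)
    if (n_ep < 1) next
    rates <- vapply(bl$streams, function(s) s$nominal_rate, numeric(1))
    nonempty <- vapply(bl$streams, function(s) length(s$timestamps) > 0, logical(1))
    ref_name <- names(which.max(rates[nonempty]))
    bounds <- bl$start_time + epoch_len * (0:n_ep)
    if (length(ref_name)) {
      ref_ts <- bl$streams[[ref_name]]$timestamps
      bound_ts <- ref_ts[nearest_index(bounds, ref_ts)]
    } else bound_ts <- bounds
    # per-stream boundary indices against the reference boundary timestamps
    cuts <- lapply(bl$streams, function(st) {
      if (!length(st$timestamps)) return(NULL)
      idx <- nearest_index(bound_ts, st$timestamps)
      # boundary index marks the first sample of the epoch; enforce monotone
      cummax(idx)
    })
    for (k in seq_len(n_ep)) {
      slices <- list()
      for (nm in names(bl$streams)) {
        st <- bl$streams[[nm]]
        ix <- cuts[[nm]]
        if (is.null(ix) || ix[k + 1] <= ix[k]) {
          slices[[nm]] <- list(timestamps = numeric(), samples =
                                 st$samples[0, , drop = FALSE],
                               valid = logical(), aoi = character(),
                               nominal_rate = st$nominal_rate, empty = TRUE)
        } else {
          sel <- ix[k]:(ix[k + 1] - 1L)
          slices[[nm]] <- list(timestamps = st$timestamps[sel],
                               samples = st$samples[sel, , drop = FALSE],
                               valid = st$valid[sel], aoi = st$aoi[sel],
                               nominal_rate = st$nominal_rate, empty = FALSE)
        }
      }
      epochs[[length(epochs) + 1L]] <- list(
        participant_id = bl$participant_id, block_kind = bl$kind,
        block_index = bl$index, epoch_index = k,
        start_time = bl$start_time + (k - 1) * epoch_len,
        duration = epoch_len, slices = slices)
    }
  }
  epochs
}
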