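#' Minimal wrapped angular difference
#'
#' Maps heading differences to (-180, 180] degrees so the 359/1 degree
#' discontinuity does not inflate deviations.
#'
#' @param a,b headings in degrees.
#' @return Signed minimal difference `a - b` in degrees.
#' @export
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Heading trace for one ATC segment
#'
#' @param times heading sample times (nominally every 500 ms), seconds.
#' @param headings observed headings, degrees.
#' @param mu commanded heading, degrees.
#' @param sigma Gaussian kernel width, degrees (default 20).
#' @param zone_ticks number of 50-ms ticks spent inside a restricted zone
#'   (or a logical vector of per-tick occupancy).
#' @return List of class `heading_trace`.
#' @export
heading_trace <- function(times, headings, mu, sigma = 20, zone_ticks = 0) {
  stopifnot(sigma > 0)
  if (is.logical(zone_ticks)) zone_ticks <- sum(zone_ticks)
  structure(list(times = times, headings = headings %% 360, mu = mu %% 360,
                 sigma = sigma, zone_ticks = zone_ticks),
            class = "heading_trace")
}

#' Gaussian heading-compliance score for one ATC segment
#'
#' Sums a Gaussian kernel of the wrapped deviation between each observed
#' heading and the commanded heading, and subtracts 0.5 per 50-ms
#' restricted-zone tick:
#' `score = sum_n (1 / (sigma * sqrt(2*pi))) * exp(-d_n^2 / (2 sigma^2))
#'  - 0.5 * zone_ticks`, with `d_n` the minimal angular difference.
#'
#' The score is maximal when every sample sits on the commanded heading
#' and decreases strictly as any deviation grows.
#'
#' @param trace a [heading_trace()].
#' @return Numeric score; an empty trace scores 0 with a warning.
#' @export
flying_score <- function(trace) {
  stopifnot(inherits(trace, "heading_trace"))
  if (!length(trace$headings)) {
    warning("empty heading trace; score 0")
    return(0)
  }
  d <- angle_diff(trace$headings, trace$mu)
  gauss <- sum(exp(-d^2 / (2 * trace$sigma^2))) / (trace$sigma * sqrt(2 * pi))
  gauss - 0.5 * trace$zone_ticks
}

#' Per-condition flying scores of a session
#'
#' Splits the heading stream at ATC command times, scores each segment
#' with [flying_score()] against the heading commanded at its start, and
#' averages segment scores per workload condition. Restricted-zone ticks
#' are read from the 20 Hz zone stream.
#'
#' @param s a [session()] with `heading` and `zone` streams and ATC events.
#' @return Named numeric vector `c(LOW = , HIGH = )` of mean segment scores.
#' @export
session_flying_scores <- function(s) {
  atc <- s$events[s$events$kind == "ATC", ]
  hd <- s$streams$heading; zn <- s$streams$zone
  scores <- data.frame(cond = character(), score = numeric())
  b <- s$blocks
  for (i in seq_len(nrow(atc))) {
    t0 <- atc$time[i]
    blk <- which(b$start_time <= t0 & b$end_time > t0)
    t1 <- min(c(atc$time[atc$time > t0], b$end_time[blk]))
    sel <- hd$timestamps >= t0 & hd$timestamps < t1
    zsel <- zn$timestamps >= t0 & zn$timestamps < t1
    tr <- heading_trace(hd$timestamps[sel], hd$samples[sel, 1],
                        mu = atc$mu[i],
                        zone_ticks = sum(zn$samples[zsel, 1] > 0))
    scores <- rbind(scores, data.frame(cond = b$kind[blk],
                                       score = flying_score(tr)))
  }
  c(LOW = mean(scores$score[scores$cond == "LOW"]),
    HIGH = mean(scores$score[scores$cond == "HIGH"]))
}

#' Per-condition behavioral event scores
#'
#' Mean pop-up detection correctness and response time, and mean working
#' memory (ATC channel recall) correctness and response time, per
#' workload condition across all blocks of that condition.
#'
#' @param events session event data frame (see [session()]).
#' @param blocks session block table (supplies the condition of each
#'   event's block).
#' @return Data frame with one row per condition: `popup_score`,
#'   `popup_rt`, `memory_score`, `memory_rt` (NA when a condition has no
#'   events of that kind).
#' @export
event_scores <- function(events, blocks) {
  cond_of <- function(tt) {
    i <- which(blocks$start_time <= tt & blocks$end_time > tt)
    if (length(i)) blocks$kind[i] else NA_character_
  }
  events$cond <- vapply(events$time, cond_of, character(1))
  out <- data.frame(condition = c("LOW", "HIGH"), popup_score = NA_real_,
                    popup_rt = NA_real_, memory_score = NA_real_,
                    memory_rt = NA_real_)
  for (r in seq_len(2)) {
    cc <- out$condition[r]
    pop <- events[events$kind == "POPUP" & events$cond %in% cc, ]
    atc <- events[events$kind == "ATC" & events$cond %in% cc, ]
    if (nrow(pop)) {
      out$popup_score[r] <- mean(pop$correct)
      out$popup_rt[r] <- mean(pop$rt)
    }
    if (nrow(atc)) {
      out$memory_score[r] <- mean(atc$correct)
      out$memory_rt[r] <- mean(atc$rt)
    }
  }
  out
}
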