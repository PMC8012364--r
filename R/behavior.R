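.summaryFromCounts <- function(ev) {
  C <- sum(ev$outcome == "correct")
  I <- sum(ev$outcome == "incorrect")
  O <- sum(ev$outcome == "omission")
  P <- sum(ev$outcome == "premature")
  N <- nrow(ev)
  respLat <- ev$response_time_s - ev$cue_onset_s
  respLat <- respLat[ev$outcome %in% c("correct", "incorrect")]
  data.frame(
    n_started = N, n_correct = C, n_incorrect = I, n_omission = O,
    n_premature = P,
    accuracy_pct = if (C + I > 0) 100 * C / (C + I) else NA_real_,
    premature_pct = if (N > 0) 100 * P / N else NA_real_,
    omission_pct = if (N > 0) 100 * O / N else NA_real_,
    response_latency_s = if (length(respLat)) mean(respLat) else NA_real_,
    magazine_latency_s = if (any(!is.na(ev$magazine_latency_s)))
      mean(ev$magazine_latency_s, na.rm = TRUE) else NA_real_)
}

#' Summarize a 5-CSRTT session
#'
#' Applies the magazine-latency exclusion first — trials with magazine
#' latency above \code{magazineMaxS} (default 10 s) are dropped from every
#' tally — then computes accuracy = 100 C/(C+I), premature and omission
#' percentages of started trials, and mean latencies, overall and broken down
#' by delay and by cue duration. With \code{excludeFrom = "latency"} the long
#' magazine latencies are dropped only from the latency statistics, keeping
#' the trials in the outcome tallies.
#'
#' @param events a \linkS4class{SessionEvents}
#' @param magazineMaxS magazine-latency exclusion threshold (s)
#' @param excludeFrom "all" (drop the trial entirely) or "latency"
#' @return list: \code{overall} (one-row data.frame), \code{byDelay},
#'   \code{byCueDuration}, and \code{nExcluded}.
#' @export
summarizeSession <- function(events, magazineMaxS = 10,
                             excludeFrom = c("all", "latency")) {
  stopifnot(is(events, "SessionEvents"))
  excludeFrom <- match.arg(excludeFrom)
  ev <- eventTable(events)
  tooSlow <- !is.na(ev$magazine_latency_s) &
    ev$magazine_latency_s > magazineMaxS
  nExcluded <- sum(tooSlow)
  if (excludeFrom == "all") {
    ev <- ev[!tooSlow, , drop = FALSE]
  } else {
    ev$magazine_latency_s[tooSlow] <- NA_real_
  }
  if (!nrow(ev)) {
    empty <- .summaryFromCounts(ev)
    return(list(overall = empty, byDelay = NULL, byCueDuration = NULL,
                nExcluded = nExcluded))
  }
  byDelay <- do.call(rbind, lapply(sort(unique(ev$delay_s)), function(d)
    cbind(delay_s = d, .summaryFromCounts(ev[ev$delay_s == d, ]))))
  byCue <- do.call(rbind, lapply(sort(unique(ev$cue_duration_s)), function(cd)
    cbind(cue_duration_s = cd,
          .summaryFromCounts(ev[ev$cue_duration_s == cd, ]))))
  list(overall = .summaryFromCounts(ev), byDelay = byDelay,
       byCueDuration = byCue, nExcluded = nExcluded)
}

#' Per-block session summaries
#'
#' Splits the session (default: five 30-min blocks of a 2.5 h window) by
#' trial start time — blocks are half-open, so a trial at exactly 30:00 falls
#' in block 2 — and summarizes each block. Blocks beyond the data are
#' reported empty.
#'
#' @param events a \linkS4class{SessionEvents}
#' @param blockMinutes block length (min)
#' @param nBlocks number of blocks
#' @param ... passed to \code{\link{summarizeSession}}
#' @return data.frame: one row per block with block index and summary fields.
#' @export
splitBlocks <- function(events, blockMinutes = 30, nBlocks = 5, ...) {
  stopifnot(is(events, "SessionEvents"))
  if (blockMinutes <= 0 || nBlocks < 1) stop("non-positive block size")
  ev <- eventTable(events)
  blockS <- blockMinutes * 60
  idx <- floor(ev$trial_start_s / blockS) + 1L
  do.call(rbind, lapply(seq_len(nBlocks), function(b) {
    sub <- SessionEvents(ev[idx == b, , drop = FALSE])
    cbind(block = b, summarizeSession(sub, ...)$overall)
  }))
}

#' Distribution of premature-response latencies
#'
#' Latency is response time minus trial start for premature trials (so it
#' lies in [0, delay)); returns a histogram on a fixed bin grid plus the
#' empirical CDF, after optional delay filtering.
#'
#' @param events a \linkS4class{SessionEvents}
#' @param delay keep only these delays (s), or NULL for all
#' @param binWidthS histogram bin width (s)
#' @return list: \code{latencies}, \code{breaks}, \code{counts},
#'   \code{ecdf} (a function); empty (with a warning) if no premature trial
#'   survives the filter.
#' @export
prematureLatencyDistribution <- function(events, delay = NULL,
                                         binWidthS = 0.5) {
  stopifnot(is(events, "SessionEvents"))
  ev <- eventTable(events)
  ev <- ev[ev$outcome == "premature", , drop = FALSE]
  if (!is.null(delay)) ev <- ev[ev$delay_s %in% delay, , drop = FALSE]
  if (!nrow(ev)) {
    warning("no premature trials after filtering")
    return(list(latencies = numeric(0), breaks = numeric(0),
                counts = integer(0), ecdf = NULL))
  }
  lat <- ev$response_time_s - ev$trial_start_s
  breaks <- seq(0, ceiling(max(lat) / binWidthS) * binWidthS,
                by = binWidthS)
  h <- hist(lat, breaks = breaks, plot = FALSE)
  list(latencies = lat, breaks = h$breaks, counts = h$counts,
       ecdf = stats::ecdf(lat))
}

#' Double-label percentage for cell-count quantification
#'
#' 100 * nDouble / nTotal, rounded half-to-even to two decimals — the
#' convention used when reporting the share of neurons positive for both
#' retrograde labels.
#'
#' @param nDouble double-labeled cell count
#' @param nTotal total labeled cell count (> 0)
#' @return percentage (2 decimal places).
#' @export
doubleLabelPercentage <- function(nDouble, nTotal) {
  if (length(nTotal) != 1L || nTotal <= 0) stop("nTotal must be positive")
  if (nDouble < 0 || nDouble > nTotal)
    stop("nDouble must lie in [0, nTotal]")
  round(100 * nDouble / nTotal, 2L)
}
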