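#' Cut a processed trace into event-aligned trial epochs
#'
#' One row per trial whose full window — including the pre-trial baseline —
#' lies inside the recording; trials truncated by the recording edges are
#' dropped and counted in the tensor metadata. The alignment frame is the
#' first frame at or after the event time (no interpolation); frame times are
#' the nominal grid \code{k / fs} for frame offsets \code{k} covering the
#' half-open window \code{[window[1], window[2])}.
#'
#' Whatever the alignment event, the per-trial baseline statistics (mean and
#' SD of delta-F/F over \code{baselineWindowS} relative to *trial start*) are
#' computed here from the trace and stored in \code{rowData}, so z-scoring to
#' the pre-trial baseline works identically for response-aligned epochs.
#'
#' @param trace a \linkS4class{ProcessedTrace} (final delta-F/F)
#' @param events a \linkS4class{SessionEvents}
#' @param alignEvent "trial_start", "cue_onset" or "response"
#' @param windowS numeric(2), half-open window around the event (s)
#' @param baselineWindowS numeric(2), baseline window relative to trial start
#'   (s); the standard setting is -5 to -1 s, inside the enforced quiet
#'   inter-trial interval
#' @return An \linkS4class{EpochedTensor} (not yet z-scored). Metadata field
#'   \code{droppedTrials} counts edge-dropped trials.
#' @export
epochTrials <- function(trace, events, alignEvent = "trial_start",
                        windowS = c(-5, 15), baselineWindowS = c(-5, -1)) {
  stopifnot(is(trace, "ProcessedTrace"), is(events, "SessionEvents"))
  ev <- eventTable(events)
  fs <- trace@fsHz
  x <- trace@dff
  n <- length(x)
  alignTimes <- switch(alignEvent,
    trial_start = ev$trial_start_s,
    cue_onset = ev$cue_onset_s,
    response = ev$response_time_s,
    stop("unknown alignEvent: ", alignEvent))
  ks <- seq.int(ceiling(windowS[1] * fs - 1e-9),
                ceiling(windowS[2] * fs - 1e-9) - 1L)
  frameTimesS <- ks / fs
  kbase <- seq.int(ceiling(baselineWindowS[1] * fs - 1e-9),
                   ceiling(baselineWindowS[2] * fs - 1e-9) - 1L)
  rows <- list(); meta <- list(); dropped <- 0L
  for (i in seq_len(nrow(ev))) {
    tA <- alignTimes[i]
    if (is.na(tA)) { dropped <- dropped + 1L; next }
    i0 <- ceiling((tA - trace@t0S) * fs - 1e-9) + 1L  # first frame time >= tA
    iB <- ceiling((ev$trial_start_s[i] - trace@t0S) * fs - 1e-9) + 1L
    idx <- i0 + ks
    idxB <- iB + kbase
    if (min(idx, idxB) < 1L || max(idx, idxB) > n) { dropped <- dropped + 1L; next }
    xb <- x[idxB]
    rows[[length(rows) + 1L]] <- x[idx]
    meta[[length(meta) + 1L]] <- data.frame(
      trial_index = ev$trial_index[i], outcome = ev$outcome[i],
      delay_s = ev$delay_s[i], session_id = ev$session_id[i],
      baseline_mean = mean(xb), baseline_sd = stats::sd(xb),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no trial window fits inside the recording")
  EpochedTensor(do.call(rbind, rows), frameTimesS, do.call(rbind, meta),
                alignEvent, fs, baselineWindowS = baselineWindowS,
                zscored = FALSE,
                extraMeta = list(droppedTrials = dropped,
                                 nBaselineFrames = length(kbase)))
}

#' Z-score each trial epoch to its pre-trial baseline
#'
#' Per trial, \code{z = (x - mu_baseline) / sd_baseline} using the baseline
#' statistics stored by \code{\link{epochTrials}}. Sample SD (denominator
#' n-1) is the default, sensible for the ~60 baseline frames a 4 s window
#' holds at ~16 Hz. Trials with zero baseline SD are excluded (not silently
#' zeroed) and counted in metadata.
#'
#' @param epochs an \linkS4class{EpochedTensor}
#' @return An \linkS4class{EpochedTensor} in z units
#'   (\code{isZscored() == TRUE}).
#' @export
zscoreEpochs <- function(epochs) {
  stopifnot(is(epochs, "EpochedTensor"))
  md <- S4Vectors::metadata(epochs)
  if (isTRUE(md$zscored)) return(epochs)
  if (md$nBaselineFrames < 2L) stop("baseline window must contain >= 2 frames")
  tm <- trialMeta(epochs)
  bad <- !is.finite(tm$baseline_sd) | tm$baseline_sd <= 0
  if (any(bad))
    warning(sum(bad), " trial(s) excluded: zero or undefined baseline SD")
  vals <- epochValues(epochs)[!bad, , drop = FALSE]
  tm2 <- tm[!bad, , drop = FALSE]
  if (!nrow(vals)) stop("no trial has a usable baseline")
  z <- (vals - tm2$baseline_mean) / tm2$baseline_sd
  EpochedTensor(z, frameTimes(epochs), tm2, md$alignEvent, md$fsHz,
                baselineWindowS = md$baselineWindowS, zscored = TRUE,
                extraMeta = list(droppedTrials = md$droppedTrials,
                                 nBaselineFrames = md$nBaselineFrames,
                                 excludedZeroSd = sum(bad)))
}

#' Subset trials by outcome and/or delay
#'
#' Row subset with metadata preserved; chained filters commute. An empty
#' selection returns an explicit empty tensor with a warning.
#'
#' @param epochs an \linkS4class{EpochedTensor}
#' @param outcome character vector of outcomes to keep, or NULL
#' @param delay numeric vector of delays (s) to keep, or NULL
#' @return An \linkS4class{EpochedTensor} with the selected rows.
#' @export
selectTrials <- function(epochs, outcome = NULL, delay = NULL) {
  stopifnot(is(epochs, "EpochedTensor"))
  tm <- trialMeta(epochs)
  keep <- rep(TRUE, nrow(tm))
  if (!is.null(outcome)) {
    if (!all(outcome %in% .OUTCOMES)) stop("unknown outcome in filter")
    keep <- keep & tm$outcome %in% outcome
  }
  if (!is.null(delay)) keep <- keep & tm$delay_s %in% delay
  if (!any(keep)) warning("selection is empty")
  epochs[keep, ]
}

#' Collapse an epoch tensor to one mean trace per subject/session
#'
#' Builds the \linkS4class{GroupTraces} substrate for the resampling stage:
#' for each level of \code{by} (usually the session/animal id), the mean
#' across that subject's trials at every frame.
#'
#' @param epochs a z-scored \linkS4class{EpochedTensor}
#' @param by rowData column naming the subject (default "session_id")
#' @param label group label
#' @return A \linkS4class{GroupTraces}.
#' @export
subjectMeanTraces <- function(epochs, by = "session_id", label = "") {
  stopifnot(is(epochs, "EpochedTensor"))
  tm <- trialMeta(epochs)
  if (!by %in% names(tm)) stop("no rowData column named ", by)
  vals <- epochValues(epochs)
  ids <- unique(tm[[by]])
  traces <- t(vapply(ids, function(id)
    colMeans(vals[tm[[by]] == id, , drop = FALSE]),
    numeric(ncol(vals))))
  rownames(traces) <- ids
  GroupTraces(traces, frameTimes(epochs), label)
}
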