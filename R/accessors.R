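#' Construct a SessionEvents object
#'
#' @param events data.frame following the event-log schema (see
#'   \linkS4class{SessionEvents}).
#' @return A \linkS4class{SessionEvents} object.
#' @export
SessionEvents <- function(events) {
  events <- as.data.frame(events)
  for (col in setdiff(.EVENT_COLUMNS, names(events))) events[[col]] <- NA_real_
  events <- events[, .EVENT_COLUMNS]
  new("SessionEvents", events = events)
}

#' @rdname SessionEvents
#' @param object,x a SessionEvents object
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))

#' @rdname SessionEvents
#' @export
setMethod("eventTable", "SessionEvents", function(object) object@events)

#' @rdname SessionEvents
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname SessionEvents
#' @export
setMethod("nTrials", "SessionEvents", function(object) nrow(object@events))

setMethod("show", "SessionEvents", function(object) {
  ev <- object@events
  cat("SessionEvents:", nrow(ev), "trials\n")
  if (nrow(ev)) {
    cat("  outcomes:", paste(sprintf("%s=%d", names(table(ev$outcome)),
                                     as.integer(table(ev$outcome))),
                             collapse = ", "), "\n")
    cat("  delays (s):", paste(sort(unique(ev$delay_s)), collapse = ", "), "\n")
    cat(sprintf("  span: %.1f-%.1f s\n", min(ev$trial_start_s),
                max(ev$trial_start_s)))
  }
})

#' Construct a RawPhotometryRecording
#'
#' @param sig470,sig405 sampled fluorescence traces (a.u.), equal length
#' @param fsHz sampling rate (Hz)
#' @param t0S time of the first sample (s from session start)
#' @return A \linkS4class{RawPhotometryRecording}.
#' @export
RawPhotometryRecording <- function(sig470, sig405, fsHz, t0S = 0) {
  new("RawPhotometryRecording", sig470 = as.numeric(sig470),
      sig405 = as.numeric(sig405), fsHz = fsHz, t0S = t0S)
}

#' Sampling rate accessor
#' @param object a recording, trace, epoch tensor or protocol
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "RawPhotometryRecording", function(object) object@fsHz)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "ProcessedTrace", function(object) object@fsHz)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EphysProtocol", function(object) object@fsHz)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochedTensor", function(object)
  S4Vectors::metadata(object)$fsHz)

setMethod("show", "RawPhotometryRecording", function(object) {
  cat(sprintf("RawPhotometryRecording: %d samples @ %.2f Hz (%.1f s)\n",
              length(object@sig470), object@fsHz,
              length(object@sig470) / object@fsHz))
})

#' Construct a ProcessedTrace
#'
#' @param dff numeric trace
#' @param fsHz sampling rate (Hz)
#' @param t0S time of the first sample (s)
#' @param provenance list of processing parameters
#' @return A \linkS4class{ProcessedTrace}.
#' @export
ProcessedTrace <- function(dff, fsHz, t0S = 0, provenance = list()) {
  new("ProcessedTrace", dff = as.numeric(dff), fsHz = fsHz, t0S = t0S,
      provenance = provenance)
}

#' @rdname ProcessedTrace
#' @param object a ProcessedTrace
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))

#' @rdname ProcessedTrace
#' @export
setMethod("traceValues", "ProcessedTrace", function(object) object@dff)

#' Sample times of a trace (seconds from session start)
#' @param object a ProcessedTrace
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))

#' @rdname traceTimes
#' @export
setMethod("traceTimes", "ProcessedTrace", function(object)
  object@t0S + (seq_along(object@dff) - 1L) / object@fsHz)

setMethod("show", "ProcessedTrace", function(object) {
  cat(sprintf("ProcessedTrace: %d frames @ %.2f Hz", length(object@dff),
              object@fsHz))
  steps <- names(object@provenance)
  if (length(steps)) cat(" [", paste(steps, collapse = " > "), "]", sep = "")
  cat("\n")
})

#' Construct an EpochedTensor
#'
#' Usually produced by \code{\link{epochTrials}} rather than called directly.
#'
#' @param values trials x frames matrix
#' @param frameTimesS frame times relative to the alignment event (s)
#' @param trialMeta data.frame of per-trial metadata (one row per trial)
#' @param alignEvent one of "trial_start", "cue_onset", "response"
#' @param fsHz frame rate (Hz)
#' @param baselineWindowS baseline window, s relative to trial start
#' @param zscored logical: rows already z-scored to their baseline?
#' @param extraMeta additional metadata fields (list)
#' @return An \linkS4class{EpochedTensor}.
#' @export
EpochedTensor <- function(values, frameTimesS, trialMeta, alignEvent, fsHz,
                          baselineWindowS = c(-5, -1), zscored = FALSE,
                          extraMeta = list()) {
  values <- as.matrix(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    rowData = S4Vectors::DataFrame(trialMeta),
    colData = S4Vectors::DataFrame(frame_time_s = frameTimesS),
    metadata = c(list(alignEvent = alignEvent, fsHz = fsHz,
                      baselineWindowS = baselineWindowS, zscored = zscored),
                 extraMeta)
  )
  new("EpochedTensor", se)
}

#' @rdname EpochedTensor
#' @param object an EpochedTensor
#' @export
setGeneric("epochValues", function(object) standardGeneric("epochValues"))

#' @rdname EpochedTensor
#' @export
setMethod("epochValues", "EpochedTensor", function(object)
  SummarizedExperiment::assay(object, "values"))

#' @rdname EpochedTensor
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname EpochedTensor
#' @export
setMethod("frameTimes", "EpochedTensor", function(object) object$frame_time_s)

#' @rdname EpochedTensor
#' @export
setMethod("frameTimes", "GroupTraces", function(object) object@frameTimesS)

#' @rdname EpochedTensor
#' @export
setGeneric("trialMeta", function(object) standardGeneric("trialMeta"))

#' @rdname EpochedTensor
#' @export
setMethod("trialMeta", "EpochedTensor", function(object)
  as.data.frame(SummarizedExperiment::rowData(object)))

#' @rdname EpochedTensor
#' @export
setGeneric("isZscored", function(object) standardGeneric("isZscored"))

#' @rdname EpochedTensor
#' @export
setMethod("isZscored", "EpochedTensor", function(object)
  isTRUE(S4Vectors::metadata(object)$zscored))

setMethod("show", "EpochedTensor", function(object) {
  md <- S4Vectors::metadata(object)
  ft <- frameTimes(object)
  cat(sprintf(
    "EpochedTensor: %d trials x %d frames, aligned on %s, %s\n",
    nrow(object), ncol(object), md$alignEvent,
    if (isTRUE(md$zscored)) "z-scored" else "raw dF/F"))
  if (length(ft))
    cat(sprintf("  window %.2f..%.2f s @ %.2f Hz\n", ft[1], ft[length(ft)],
                md$fsHz))
})

#' Construct a GroupTraces object
#'
#' @param traces subjects x frames matrix of per-subject mean traces (z units)
#' @param frameTimesS frame times (s)
#' @param label free-text label
#' @return A \linkS4class{GroupTraces}.
#' @export
GroupTraces <- function(traces, frameTimesS, label = "") {
  new("GroupTraces", traces = as.matrix(traces),
      frameTimesS = as.numeric(frameTimesS), label = label)
}

#' @rdname GroupTraces
#' @param object a GroupTraces object
#' @export
setGeneric("groupTraces", function(object) standardGeneric("groupTraces"))

#' @rdname GroupTraces
#' @export
setMethod("groupTraces", "GroupTraces", function(object) object@traces)

#' @rdname GroupTraces
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))

#' @rdname GroupTraces
#' @export
setMethod("nSubjects", "GroupTraces", function(object) nrow(object@traces))

setMethod("show", "GroupTraces", function(object) {
  cat(sprintf("GroupTraces '%s': %d subjects x %d frames\n", object@label,
              nrow(object@traces), ncol(object@traces)))
})

#' @rdname SignificanceMask-accessors
#' @param object a SignificanceMask or BootstrapResult
#' @export
setGeneric("significantFrames", function(object)
  standardGeneric("significantFrames"))

#' Accessors for SignificanceMask
#'
#' \code{significantFrames} returns the post-filter per-frame logical;
#' \code{significanceWindows} the contiguous half-open windows (seconds).
#'
#' @name SignificanceMask-accessors
#' @export
setMethod("significantFrames", "SignificanceMask", function(object)
  object@significant)

#' @rdname SignificanceMask-accessors
#' @export
setGeneric("significanceWindows", function(object)
  standardGeneric("significanceWindows"))

#' @rdname SignificanceMask-accessors
#' @export
setMethod("significanceWindows", "SignificanceMask", function(object)
  object@windows)

setMethod("show", "SignificanceMask", function(object) {
  cat(sprintf("SignificanceMask: %d/%d frames significant, %d window(s)\n",
              sum(object@significant), length(object@significant),
              nrow(object@windows)))
  if (nrow(object@windows))
    for (i in seq_len(nrow(object@windows)))
      cat(sprintf("  [%.3f, %.3f) s\n", object@windows$start_s[i],
                  object@windows$end_s[i]))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf(
    "BootstrapResult: %d frames, %d iterations, two-sided alpha %.4g\n",
    length(object@lower), as.integer(object@nIter), object@alpha))
})

#' Construct an EphysProtocol
#'
#' @param sweeps sweeps x samples matrix
#' @param fsHz sampling rate (Hz)
#' @param mode "current_clamp" or "voltage_clamp"
#' @param stim stimulus metadata list
#' @param truth simulation ground truth list (empty for real data)
#' @return An \linkS4class{EphysProtocol}.
#' @export
EphysProtocol <- function(sweeps, fsHz, mode, stim = list(), truth = list()) {
  new("EphysProtocol", sweeps = as.matrix(sweeps), fsHz = fsHz, mode = mode,
      stim = stim, truth = truth)
}

#' @rdname EphysProtocol
#' @param object an EphysProtocol
#' @export
setGeneric("sweepMatrix", function(object) standardGeneric("sweepMatrix"))

#' @rdname EphysProtocol
#' @export
setMethod("sweepMatrix", "EphysProtocol", function(object) object@sweeps)

#' @rdname EphysProtocol
#' @export
setGeneric("stimMeta", function(object) standardGeneric("stimMeta"))

#' @rdname EphysProtocol
#' @export
setMethod("stimMeta", "EphysProtocol", function(object) object@stim)

#' @rdname EphysProtocol
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname EphysProtocol
#' @export
setMethod("groundTruth", "EphysProtocol", function(object) object@truth)

setMethod("show", "EphysProtocol", function(object) {
  cat(sprintf("EphysProtocol (%s): %d sweeps x %d samples @ %.0f Hz\n",
              object@mode, nrow(object@sweeps), ncol(object@sweeps),
              object@fsHz))
})
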