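#' @import methods
#' @importFrom stats coef lm mad median quantile residuals rnorm runif sd
#'   setNames var
#' @importFrom graphics hist
#' @importFrom utils head read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors metadata DataFrame
NULL

.OUTCOMES <- c("correct", "incorrect", "omission", "premature")

.EVENT_COLUMNS <- c(
  "session_id", "trial_index", "trial_start_s", "delay_s", "cue_onset_s",
  "cue_duration_s", "response_time_s", "outcome", "reward_collect_s",
  "magazine_latency_s"
)

#' SessionEvents: an ordered 5-CSRTT trial log
#'
#' One row per started trial. Times are seconds from session start; missing
#' values mean "not applicable" (e.g. no response on an omission). The
#' invariants encode the task contingencies: the cue comes on exactly
#' \code{delay_s} after the trial start, premature responses precede the cue,
#' and omissions carry no response time.
#'
#' @slot events data.frame with columns \code{session_id}, \code{trial_index},
#'   \code{trial_start_s}, \code{delay_s}, \code{cue_onset_s},
#'   \code{cue_duration_s}, \code{response_time_s}, \code{outcome},
#'   \code{reward_collect_s}, \code{magazine_latency_s}.
#' @exportClass SessionEvents
setClass("SessionEvents", representation(events = "data.frame"))

setValidity("SessionEvents", function(object) {
  ev <- object@events
  missing_cols <- setdiff(.EVENT_COLUMNS, names(ev))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(ev) == 0L) return(TRUE)
  if (!all(ev$outcome %in% .OUTCOMES))
    return("outcome must be one of correct/incorrect/omission/premature")
  if (is.unsorted(ev$trial_start_s, strictly = TRUE))
    return("trial_start_s must be strictly increasing")
  if (any(abs(ev$cue_onset_s - ev$trial_start_s - ev$delay_s) > 1e-9))
    return("cue_onset_s must equal trial_start_s + delay_s")
  prem <- ev$outcome == "premature"
  if (any(prem & !(ev$response_time_s < ev$cue_onset_s), na.rm = FALSE))
    return("premature trials must respond before cue onset")
  if (any(ev$outcome == "omission" & !is.na(ev$response_time_s)))
    return("omission trials must have no response time")
  TRUE
})

#' RawPhotometryRecording: paired 470/405 nm traces
#'
#' The raw substrate for motion correction: a calcium-dependent 470 nm channel
#' and the calcium-independent isosbestic 405 nm channel, sampled on a common
#' clock.
#'
#' @slot sig470 numeric, 470 nm fluorescence (a.u.)
#' @slot sig405 numeric, 405 nm isosbestic fluorescence (a.u.), same length
#' @slot fsHz sampling rate in Hz
#' @slot t0S time of the first sample, seconds from session start
#' @exportClass RawPhotometryRecording
setClass("RawPhotometryRecording", representation(
  sig470 = "numeric", sig405 = "numeric", fsHz = "numeric", t0S = "numeric"
))

setValidity("RawPhotometryRecording", function(object) {
  if (length(object@sig470) != length(object@sig405))
    return("sig470 and sig405 must have equal length")
  if (length(object@fsHz) != 1L || !is.finite(object@fsHz) || object@fsHz <= 0)
    return("fsHz must be a single positive number")
  if (!all(is.finite(object@sig470)) || !all(is.finite(object@sig405)))
    return("samples must be finite")
  TRUE
})

#' ProcessedTrace: a single delta-F/F (or intermediate) trace
#'
#' @slot dff numeric trace (fractional delta-F/F once fully processed)
#' @slot fsHz sampling rate in Hz
#' @slot t0S time of the first sample, seconds from session start
#' @slot provenance list of processing parameters applied so far (fit
#'   coefficients, filter cutoffs, decimation factor)
#' @exportClass ProcessedTrace
setClass("ProcessedTrace", representation(
  dff = "numeric", fsHz = "numeric", t0S = "numeric", provenance = "list"
))

setValidity("ProcessedTrace", function(object) {
  if (length(object@fsHz) != 1L || object@fsHz <= 0)
    return("fsHz must be a single positive number")
  if (!all(is.finite(object@dff))) return("trace must be finite")
  TRUE
})

#' EpochedTensor: trials x frames, aligned to a task event
#'
#' Extends SummarizedExperiment: the \code{"values"} assay is trials x frames,
#' \code{rowData} carries per-trial metadata (outcome, delay, per-trial
#' baseline mean/SD), \code{colData} carries frame times relative to the
#' alignment event, and \code{metadata} records the alignment event, sampling
#' rate, baseline window and whether rows have been z-scored.
#'
#' @exportClass EpochedTensor
setClass("EpochedTensor", contains = "SummarizedExperiment")

setValidity("EpochedTensor", function(object) {
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    return("assay 'values' required")
  ft <- object$frame_time_s
  if (is.null(ft)) return("colData must contain frame_time_s")
  if (length(ft) > 1L) {
    d <- diff(ft)
    if (any(d <= 0)) return("frame times must be strictly increasing")
    if (max(d) - min(d) > 1e-6 * mean(d))
      return("frame times must be uniformly spaced")
  }
  md <- S4Vectors::metadata(object)
  for (f in c("alignEvent", "fsHz", "baselineWindowS", "zscored"))
    if (is.null(md[[f]])) return(paste("metadata field missing:", f))
  TRUE
})

#' GroupTraces: per-subject mean traces on a shared frame grid
#'
#' Substrate for the bootstrap and permutation stages: one mean trace per
#' subject (rat), all on the same frame grid, in z units.
#'
#' @slot traces subjects x frames numeric matrix
#' @slot frameTimesS frame times (s) relative to the alignment event
#' @slot label free-text label (outcome and/or group)
#' @exportClass GroupTraces
setClass("GroupTraces", representation(
  traces = "matrix", frameTimesS = "numeric", label = "character"
))

setValidity("GroupTraces", function(object) {
  if (ncol(object@traces) != length(object@frameTimesS))
    return("frameTimesS length must match trace columns")
  if (!all(is.finite(object@traces))) return("traces must be finite")
  TRUE
})

#' BootstrapResult: per-frame bootstrap confidence band for a group mean
#'
#' @slot lower,upper per-frame empirical quantiles of the bootstrapped means
#' @slot nIter number of bootstrap iterations
#' @slot alpha two-sided level (quantiles at alpha/2 and 1 - alpha/2)
#' @slot seed RNG seed used
#' @slot frameTimesS frame times (s)
#' @exportClass BootstrapResult
setClass("BootstrapResult", representation(
  lower = "numeric", upper = "numeric", nIter = "numeric", alpha = "numeric",
  seed = "numeric", frameTimesS = "numeric"
))

setValidity("BootstrapResult", function(object) {
  if (length(object@lower) != length(object@upper))
    return("lower and upper must have equal length")
  if (any(object@lower > object@upper + 1e-12))
    return("lower must not exceed upper")
  TRUE
})

#' SignificanceMask: per-frame significance plus contiguous windows
#'
#' Output of the bootstrap elevated-window detector and of the frame-wise
#' permutation comparison, after singleton filtering: isolated significant
#' frames (no significant neighbor) are discarded, so every retained window
#' spans at least \code{minRun} frames.
#'
#' @slot significant per-frame logical (post-filter)
#' @slot windows data.frame(start_s, end_s), half-open intervals
#' @slot frameTimesS frame times (s)
#' @slot meta list: alpha, nIter, comparison, minRun, and test-specific fields
#' @exportClass SignificanceMask
setClass("SignificanceMask", representation(
  significant = "logical", windows = "data.frame", frameTimesS = "numeric",
  meta = "list"
))

setValidity("SignificanceMask", function(object) {
  if (length(object@significant) != length(object@frameTimesS))
    return("significant length must match frameTimesS")
  if (!all(c("start_s", "end_s") %in% names(object@windows)))
    return("windows must have start_s and end_s")
  TRUE
})

#' EphysProtocol: a sweep set with stimulus metadata
#'
#' @slot sweeps sweeps x samples numeric matrix (mV for current clamp, pA for
#'   voltage clamp)
#' @slot fsHz sampling rate in Hz
#' @slot mode "current_clamp" or "voltage_clamp"
#' @slot stim list of stimulus metadata; for steps: \code{stepPa} (per sweep),
#'   \code{stepOnsetS}, \code{stepDurS}; for optogenetic pulse trains:
#'   \code{pulseOnsetsS}; for ramps: \code{rampRatePaPerS}, \code{rampStartS}
#' @slot truth list of simulation ground truth (empty for real data)
#' @exportClass EphysProtocol
setClass("EphysProtocol", representation(
  sweeps = "matrix", fsHz = "numeric", mode = "character", stim = "list",
  truth = "list"
))

setValidity("EphysProtocol", function(object) {
  if (!object@mode %in% c("current_clamp", "voltage_clamp"))
    return("mode must be current_clamp or voltage_clamp")
  if (length(object@fsHz) != 1L || object@fsHz <= 0)
    return("fsHz must be a single positive number")
  if (!is.null(object@stim$stepPa) &&
      length(object@stim$stepPa) != nrow(object@sweeps))
    return("stepPa must have one entry per sweep")
  TRUE
})
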