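.checkDelayEpochs <- function(epochs) {
  stopifnot(is(epochs, "EpochedTensor"))
  md <- S4Vectors::metadata(epochs)
  if (md$alignEvent != "trial_start")
    stop("delay metrics require epochs aligned on trial_start")
  if (!isTRUE(md$zscored))
    stop("delay metrics require z-scored epochs (see zscoreEpochs)")
}

# frames in [0, delay] (closed: includes the frame at the cue if on-grid);
# used by the integral/peak metrics so a constant trace integrates to exactly
# delay * value on the trapezoid rule
.delayFramesClosed <- function(ft, delay) which(ft >= -1e-9 & ft <= delay + 1e-9)

# frames in [0, delay) (half-open); used by the threshold/event metrics
.delayFramesOpen <- function(ft, delay) which(ft >= -1e-9 & ft < delay - 1e-9)

#' Area under the delay-period curve
#'
#' Trapezoidal integral of the z-scored trace from trial start to the cue
#' (z * seconds), per trial. For comparisons across delays, \code{fixedWindow
#' = TRUE} integrates every trial over [0, max delay] — the signal between
#' trial initiation and the cue time of the longest delay — instead of each
#' trial's own delay.
#'
#' @param epochs a z-scored \linkS4class{EpochedTensor} aligned on trial start
#' @param fixedWindow integrate [0, maxDelayS] for all trials?
#' @param maxDelayS upper limit for the fixed window (s)
#' @return numeric per-trial AUC (z * s).
#' @export
delayAuc <- function(epochs, fixedWindow = FALSE, maxDelayS = 12.5) {
  .checkDelayEpochs(epochs)
  ft <- frameTimes(epochs)
  fs <- S4Vectors::metadata(epochs)$fsHz
  vals <- epochValues(epochs)
  delays <- if (fixedWindow) rep(maxDelayS, nrow(vals)) else
    trialMeta(epochs)$delay_s
  vapply(seq_len(nrow(vals)), function(i) {
    idx <- .delayFramesClosed(ft, delays[i])
    y <- vals[i, idx]
    m <- length(y)
    if (m < 2L) return(NA_real_)
    (sum(y) - (y[1L] + y[m]) / 2) / fs
  }, numeric(1L))
}

#' Rise fraction at a fixed time after trial start
#'
#' The z value at the frame nearest \code{tS} divided by the trial's peak z
#' within its delay window — the early-rise kinetics measure. Trials with a
#' non-positive peak get NA.
#'
#' @param epochs a z-scored \linkS4class{EpochedTensor} aligned on trial start
#' @param tS evaluation time after trial start (s)
#' @return numeric per-trial fraction of peak.
#' @export
riseFractionAt <- function(epochs, tS = 1.0) {
  .checkDelayEpochs(epochs)
  ft <- frameTimes(epochs)
  vals <- epochValues(epochs)
  delays <- trialMeta(epochs)$delay_s
  iAt <- which.min(abs(ft - tS))
  vapply(seq_len(nrow(vals)), function(i) {
    if (tS > delays[i]) return(NA_real_)
    idx <- .delayFramesClosed(ft, delays[i])
    pk <- max(vals[i, idx])
    if (pk <= 0) return(NA_real_)
    vals[i, iAt] / pk
  }, numeric(1L))
}

#' Suprathreshold event timing and active time during the delay
#'
#' On baseline-z-scored trials, "above baseline + k SD" is simply z > k.
#' Returns, per trial, the time of the first suprathreshold frame within
#' [0, delay), the total suprathreshold time (frame count / fs), and the
#' boolean frame matrix over the epoch window. Trials that never cross get
#' \code{NA} first-crossing and 0 active time.
#'
#' @param epochs a z-scored \linkS4class{EpochedTensor} aligned on trial start
#' @param k threshold in baseline SD units (> 0)
#' @return list: \code{firstCrossingS}, \code{activeTimeS} (per trial),
#'   \code{above} (trials x frames logical over the delay-masked window).
#' @export
thresholdEvents <- function(epochs, k = 2) {
  .checkDelayEpochs(epochs)
  if (k <= 0) stop("threshold k must be positive")
  ft <- frameTimes(epochs)
  fs <- S4Vectors::metadata(epochs)$fsHz
  vals <- epochValues(epochs)
  delays <- trialMeta(epochs)$delay_s
  above <- matrix(FALSE, nrow(vals), ncol(vals))
  firstCrossingS <- rep(NA_real_, nrow(vals))
  activeTimeS <- numeric(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    idx <- .delayFramesOpen(ft, delays[i])
    hit <- vals[i, idx] > k
    above[i, idx] <- hit
    activeTimeS[i] <- sum(hit) / fs
    if (any(hit)) firstCrossingS[i] <- ft[idx[which(hit)[1L]]]
  }
  list(firstCrossingS = firstCrossingS, activeTimeS = activeTimeS,
       above = above)
}

# first index of each local maximum run: value strictly above the preceding
# and following *different* values; a boundary run counts if its single
# neighbor is lower (monotone rise to the cue still yields a peak)
.localMaxima <- function(y) {
  r <- rle(y)
  v <- r$values
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  isMax <- vapply(seq_along(v), function(j) {
    leftOk <- j == 1L || v[j - 1L] < v[j]
    rightOk <- j == length(v) || v[j + 1L] < v[j]
    leftOk && rightOk
  }, logical(1L))
  starts[isMax]
}

#' Peak fluorescence and time to peak during the delay
#'
#' \code{peakZ} is the maximum z in the delay window. \code{timeToPeakS} is
#' the time of the first local maximum exceeding 20% of that peak — an early
#' shoulder that reaches a fifth of the eventual maximum counts as "reaching
#' peak", which captures onset speed rather than absolute argmax. Plateau
#' ties resolve to the earliest frame of the plateau.
#'
#' @param epochs a z-scored \linkS4class{EpochedTensor} aligned on trial start
#' @param fraction local maxima must exceed this fraction of the global peak
#' @return data.frame with per-trial \code{peak_z} and \code{time_to_peak_s}.
#' @export
peakMetrics <- function(epochs, fraction = 0.20) {
  .checkDelayEpochs(epochs)
  ft <- frameTimes(epochs)
  vals <- epochValues(epochs)
  delays <- trialMeta(epochs)$delay_s
  out <- data.frame(peak_z = rep(NA_real_, nrow(vals)),
                    time_to_peak_s = rep(NA_real_, nrow(vals)))
  for (i in seq_len(nrow(vals))) {
    idx <- .delayFramesClosed(ft, delays[i])
    if (length(idx) < 3L) stop("delay window shorter than 3 frames")
    y <- vals[i, idx]
    pk <- max(y)
    out$peak_z[i] <- pk
    cand <- .localMaxima(y)
    cand <- cand[y[cand] > fraction * pk]
    if (length(cand)) out$time_to_peak_s[i] <- ft[idx[cand[1L]]]
  }
  out
}

#' Assemble the per-trial delay metric table
#'
#' One row per trial: AUC, rise fraction at 1 s, first suprathreshold event
#' time, total suprathreshold time, peak z and time to peak, alongside the
#' trial metadata. \code{aggregate = TRUE} adds the per-subject mean table
#' (undefined metrics excluded from means, with counts).
#'
#' @param epochs a z-scored \linkS4class{EpochedTensor} aligned on trial start
#' @param riseAtS evaluation time for the rise fraction (s)
#' @param k threshold (baseline SD units) for event metrics
#' @param aggregate also return per-subject means?
#' @return data.frame (or list(trials=, subjects=) when aggregating).
#' @export
delayMetrics <- function(epochs, riseAtS = 1.0, k = 2, aggregate = FALSE) {
  .checkDelayEpochs(epochs)
  te <- thresholdEvents(epochs, k = k)
  pk <- peakMetrics(epochs)
  tab <- cbind(trialMeta(epochs)[, c("trial_index", "session_id", "outcome",
                                     "delay_s")],
               data.frame(auc_zs = delayAuc(epochs),
                          rise_fraction = riseFractionAt(epochs, riseAtS),
                          first_event_s = te$firstCrossingS,
                          active_time_s = te$activeTimeS,
                          peak_z = pk$peak_z,
                          time_to_peak_s = pk$time_to_peak_s))
  if (!aggregate) return(tab)
  num <- c("auc_zs", "rise_fraction", "first_event_s", "active_time_s",
           "peak_z", "time_to_peak_s")
  ag <- stats::aggregate(tab[num], by = list(session_id = tab$session_id,
                                             outcome = tab$outcome),
                         FUN = function(v) mean(v, na.rm = TRUE))
  list(trials = tab, subjects = ag)
}
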