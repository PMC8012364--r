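#' Configuration for the two-channel photometry simulator
#'
#' The signal model mirrors what the isosbestic correction assumes: both
#' channels share a multiplicative slow bleach and a multiplicative motion
#' process, and only the 470 nm channel carries the calcium-dependent term.
#' The default raw rate of ~1017 Hz is chosen so that decimation by 64 lands
#' at ~15.9 Hz, the frame rate the downstream stages work at.
#'
#' @param fsRawHz raw sampling rate (Hz)
#' @param baselineF mean fluorescence of the 470 channel (a.u.)
#' @param baselineF405 mean fluorescence of the 405 channel (a.u.)
#' @param transientAmplitude fractional dF/F amplitude of the delay transient
#' @param riseTauS,decayTauS transient rise/decay time constants (s)
#' @param onsetLatencyS latency from trial start to transient onset (s)
#' @param plateauGain fraction of the amplitude sustained across the delay
#'   (1 = flat-topped plateau)
#' @param omissionAttenuation multiplier on amplitude for omission trials
#' @param motionAmplitude SD of the fractional multiplicative motion process
#' @param motionCutoffHz bandwidth of the motion process (Hz)
#' @param bleachTauS photobleaching time constant (s); Inf disables bleaching
#' @param noiseSd additive broadband sensor noise SD per channel, as a
#'   fraction of baseline (mostly removed by the smoothing lowpass)
#' @param signalNoiseSd SD of slow calcium-independent fluctuations confined
#'   to the 470 channel (fraction of baseline); these survive the full
#'   processing chain and set the realistic z-score scale of the output
#' @param signalNoiseCutoffHz bandwidth of those slow fluctuations (Hz)
#' @param seed integer RNG seed
#' @return A validated list of class \code{"PhotometryConfig"}.
#' @export
PhotometryConfig <- function(fsRawHz = 1017.25,
                             baselineF = 100,
                             baselineF405 = 80,
                             transientAmplitude = 0.05,
                             riseTauS = 0.3,
                             decayTauS = 0.6,
                             onsetLatencyS = 0.2,
                             plateauGain = 1,
                             omissionAttenuation = 0.8,
                             motionAmplitude = 0.02,
                             motionCutoffHz = 2,
                             bleachTauS = 3600,
                             noiseSd = 0.002,
                             signalNoiseSd = 0.005,
                             signalNoiseCutoffHz = 0.2,
                             seed = 1L) {
  if (fsRawHz <= 0) stop("fsRawHz must be positive")
  if (riseTauS <= 0 || decayTauS <= 0) stop("time constants must be positive")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (fsRawHz < 4 / riseTauS)
    stop("sampling rate too low to resolve riseTauS")
  structure(as.list(environment()), class = "PhotometryConfig")
}

#' Simulate a two-channel photometry recording for a session
#'
#' Builds, sample by sample, \code{405 = F405 * bleach(t) * motion(t) + noise}
#' and \code{470 = F470 * bleach(t) * motion(t) * (1 + ca(t)) + noise}, where
#' \code{ca(t)} is, per trial, an exponential-rise transient sustained across
#' the delay (plateau) that decays after the delay ends. Premature trials
#' truncate the plateau at the premature response; omission trials attenuate
#' the amplitude by \code{omissionAttenuation}. The injected windows and the
#' noise-free calcium term are returned as ground truth.
#'
#' @param events a \linkS4class{SessionEvents}
#' @param config a \code{\link{PhotometryConfig}}
#' @param durationS recording length (s); default covers the last trial plus
#'   20 s
#' @return list with \code{recording} (a
#'   \linkS4class{RawPhotometryRecording}), and \code{truth}: a list with
#'   \code{windows} (per-trial data.frame start_s/end_s of the injected
#'   transient), \code{ca} (noise-free fractional calcium trace) and the
#'   config.
#' @export
simulatePhotometry <- function(events, config, durationS = NULL) {
  stopifnot(is(events, "SessionEvents"), inherits(config, "PhotometryConfig"))
  ev <- eventTable(events)
  if (is.null(durationS)) {
    durationS <- if (nrow(ev)) max(ev$cue_onset_s) + 20 else 60
  }
  if (nrow(ev) && max(ev$trial_start_s) > durationS)
    stop("events extend beyond the requested recording duration")
  set.seed(config$seed)
  fs <- config$fsRawHz
  n <- ceiling(durationS * fs)
  t <- (seq_len(n) - 1L) / fs

  ca <- numeric(n)
  windows <- data.frame(trial_index = integer(0), start_s = numeric(0),
                        end_s = numeric(0))
  if (config$transientAmplitude > 0) {
    for (i in seq_len(nrow(ev))) {
      on <- ev$trial_start_s[i] + config$onsetLatencyS
      off <- ev$cue_onset_s[i]
      if (ev$outcome[i] == "premature" && !is.na(ev$response_time_s[i]))
        off <- min(off, ev$response_time_s[i])
      if (off <= on) next
      amp <- config$transientAmplitude *
        if (ev$outcome[i] == "omission") config$omissionAttenuation else 1
      amp <- amp * config$plateauGain
      rise <- t >= on & t < off
      ca[rise] <- ca[rise] + amp * (1 - exp(-(t[rise] - on) / config$riseTauS))
      ampOff <- amp * (1 - exp(-(off - on) / config$riseTauS))
      fall <- t >= off & t < off + 6 * config$decayTauS
      ca[fall] <- ca[fall] + ampOff * exp(-(t[fall] - off) / config$decayTauS)
      windows <- rbind(windows, data.frame(trial_index = ev$trial_index[i],
                                           start_s = on, end_s = off))
    }
  }

  bleach <- if (is.finite(config$bleachTauS))
    exp(-t / config$bleachTauS) else rep(1, n)
  motion <- rep(1, n)
  if (config$motionAmplitude > 0) {
    raw <- stats::rnorm(n)
    m <- .firLowpassFilter(raw, config$motionCutoffHz, fs)
    m <- m / stats::sd(m)
    motion <- 1 + config$motionAmplitude * m
  }
  sn <- numeric(n)
  if (config$signalNoiseSd > 0) {
    raw <- stats::rnorm(n)
    sn <- .firLowpassFilter(raw, config$signalNoiseCutoffHz, fs)
    sn <- config$signalNoiseSd * sn / stats::sd(sn)
  }
  shared <- bleach * motion
  sig405 <- config$baselineF405 * shared
  sig470 <- config$baselineF * shared * (1 + ca + sn)
  if (config$noiseSd > 0) {
    sig405 <- sig405 + config$baselineF405 * config$noiseSd * stats::rnorm(n)
    sig470 <- sig470 + config$baselineF * config$noiseSd * stats::rnorm(n)
  }
  rec <- RawPhotometryRecording(sig470, sig405, fs)
  list(recording = rec,
       truth = list(windows = windows, ca = ca, nTrials = nrow(ev),
                    config = config))
}

#' Simulate per-subject mean traces with a known elevated window
#'
#' Direct z-space simulation of a group of subjects (rats): each subject's
#' mean trace is the injected plateau plus i.i.d. Gaussian frame noise. This
#' is the substrate for calibrating the bootstrap elevated-window detector and
#' the frame-wise permutation comparison against known truth.
#'
#' @param nSubjects number of subjects
#' @param frameTimesS frame grid (s)
#' @param windowS numeric(2): half-open [start, end) of the elevated window
#'   (s); NULL for a null group
#' @param amplitudeZ plateau height (z units)
#' @param noiseSd per-frame between-subject noise SD (z units)
#' @param label group label
#' @return list with \code{group} (a \linkS4class{GroupTraces}) and
#'   \code{truthMask} (per-frame logical of the injected window).
#' @export
simulateGroupTraces <- function(nSubjects = 6, frameTimesS,
                                windowS = NULL, amplitudeZ = 1,
                                noiseSd = 0.3, label = "sim") {
  nF <- length(frameTimesS)
  mu <- numeric(nF)
  truthMask <- rep(FALSE, nF)
  if (!is.null(windowS)) {
    truthMask <- frameTimesS >= windowS[1] & frameTimesS < windowS[2]
    mu[truthMask] <- amplitudeZ
  }
  traces <- matrix(stats::rnorm(nSubjects * nF, sd = noiseSd),
                   nrow = nSubjects)
  traces <- sweep(traces, 2L, mu, "+")
  list(group = GroupTraces(traces, frameTimesS, label), truthMask = truthMask)
}
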