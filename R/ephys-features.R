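.pulseWindowS <- 0.090   # peak search window after each light onset

.baselineMask <- function(t, onsets, windowS = .pulseWindowS) {
  inResp <- rep(FALSE, length(t))
  for (on in onsets) inResp <- inResp | (t > on & t <= on + windowS)
  !inResp
}

#' Drift-corrected median PSC trace
#'
#' Per sweep, a robust (iteratively reweighted, Huber) linear fit to the
#' pre- and inter-stimulus baseline samples is subtracted, removing slow
#' holding-current drift without being pulled by the evoked responses; the
#' pointwise median across sweeps is returned.
#'
#' @param protocol a voltage-clamp \linkS4class{EphysProtocol} with
#'   \code{pulseOnsetsS} stimulus metadata (>= 3 sweeps)
#' @return numeric median trace (pA), drift-corrected.
#' @export
medianPscTrace <- function(protocol) {
  stopifnot(is(protocol, "EphysProtocol"))
  sweeps <- protocol@sweeps
  if (nrow(sweeps) < 3L) stop("median trace requires >= 3 sweeps")
  onsets <- protocol@stim$pulseOnsetsS
  if (is.null(onsets)) stop("stimulus onsets unknown")
  t <- (seq_len(ncol(sweeps)) - 1L) / protocol@fsHz
  base <- .baselineMask(t, onsets)
  corrected <- t(apply(sweeps, 1L, function(sw) {
    fit <- MASS::rlm(sw[base] ~ t[base], maxit = 50)
    sw - (coef(fit)[1L] + coef(fit)[2L] * t)
  }))
  apply(corrected, 2L, median)
}

.pulsePeaks <- function(trace, onsets, fsHz, windowS = .pulseWindowS,
                        baselineS = 0.005) {
  t <- (seq_along(trace) - 1L) / fsHz
  vapply(onsets, function(on) {
    idx <- which(t > on & t <= on + windowS)
    pre <- which(t > on - baselineS & t <= on)
    b <- if (length(pre)) mean(trace[pre]) else 0
    y <- trace[idx] - b
    y[which.max(abs(y))]
  }, numeric(1L))
}

#' Paired-pulse ratios from a median PSC trace
#'
#' Per pulse, the peak is the signed extremum of the locally
#' baseline-subtracted response in the (onset, onset + 90 ms] window; ratios
#' are \code{|PSC_n| / |PSC_1|} for n = 2..5. If the first PSC does not clear
#' the noise floor the ratios are undefined (all NA).
#'
#' @param medianTrace drift-corrected median trace (pA); see
#'   \code{\link{medianPscTrace}}
#' @param onsetsS light onsets (s)
#' @param fsHz sampling rate (Hz)
#' @param noiseFloorPa |PSC_1| must exceed this (pA); default 5 x the SD of
#'   the pre-stimulus baseline (the peak search takes an extremum over many
#'   samples, so its null distribution sits well above the per-sample SD)
#' @return numeric vector of ratios (length \code{length(onsetsS) - 1}).
#' @export
pairedPulseRatios <- function(medianTrace, onsetsS, fsHz,
                              noiseFloorPa = NULL) {
  peaks <- .pulsePeaks(medianTrace, onsetsS, fsHz)
  if (is.null(noiseFloorPa)) {
    t <- (seq_along(medianTrace) - 1L) / fsHz
    pre <- medianTrace[t < onsetsS[1L]]
    noiseFloorPa <- if (length(pre) > 10L) 5 * stats::sd(pre) else 0
  }
  if (abs(peaks[1L]) <= noiseFloorPa)
    return(rep(NA_real_, length(onsetsS) - 1L))
  abs(peaks[-1L]) / abs(peaks[1L])
}

#' PSC latency: time to 80% of peak from light onset
#'
#' Finds the first time after the onset at which the response crosses 80% of
#' its peak value, with linear interpolation between samples; returned in ms.
#'
#' @param medianTrace drift-corrected trace (pA)
#' @param lightOnsetS light onset (s)
#' @param fsHz sampling rate (Hz)
#' @param windowS peak search window after the onset (s)
#' @return latency in ms, or NA if the response never crosses.
#' @export
pscLatency <- function(medianTrace, lightOnsetS, fsHz,
                       windowS = .pulseWindowS) {
  t <- (seq_along(medianTrace) - 1L) / fsHz
  idx <- which(t > lightOnsetS & t <= lightOnsetS + windowS)
  pre <- which(t > lightOnsetS - 0.005 & t <= lightOnsetS)
  b <- if (length(pre)) mean(medianTrace[pre]) else 0
  y <- medianTrace[idx] - b
  pk <- y[which.max(abs(y))]
  if (pk == 0) return(NA_real_)
  s <- sign(pk)
  ys <- s * y               # peak now positive
  level <- 0.8 * abs(pk)
  k <- which(ys >= level)[1L]
  if (is.na(k)) return(NA_real_)
  tk <- t[idx[k]]
  if (k > 1L) {
    y0 <- ys[k - 1L]; y1 <- ys[k]
    tk <- t[idx[k - 1L]] + (level - y0) / (y1 - y0) / fsHz
  }
  1000 * (tk - lightOnsetS)
}

.stepSweepStats <- function(protocol) {
  sweeps <- protocol@sweeps
  fs <- protocol@fsHz
  on <- protocol@stim$stepOnsetS
  dur <- protocol@stim$stepDurS
  t <- (seq_len(ncol(sweeps)) - 1L) / fs
  pre <- t < on
  ssWin <- t >= on + dur - 0.2 & t < on + dur          # last 200 ms
  fifthWin <- t >= on + dur * 4 / 5 & t < on + dur     # last 1/5
  stepWin <- t >= on & t < on + dur
  data.frame(
    stepPa = protocol@stim$stepPa,
    baselineMv = apply(sweeps[, pre, drop = FALSE], 1L, mean),
    ssMv = apply(sweeps[, ssWin, drop = FALSE], 1L, mean),
    fifthMv = apply(sweeps[, fifthWin, drop = FALSE], 1L, mean),
    peakMv = vapply(seq_len(nrow(sweeps)), function(i) {
      y <- sweeps[i, stepWin]
      y[which.max(abs(y - mean(sweeps[i, pre])))]
    }, numeric(1L)))
}

#' Input resistance from negative current steps
#'
#' Steady-state voltage deflection (mean of the last 200 ms of the step,
#' minus the pre-step baseline) regressed on injected current over the
#' negative steps between 0 and -100 pA; the slope is the input resistance in
#' MOhm. The intercept is free, so baseline offsets are tolerated.
#'
#' @param protocol a current-clamp step \linkS4class{EphysProtocol}
#' @return input resistance (MOhm).
#' @export
inputResistance <- function(protocol) {
  stopifnot(is(protocol, "EphysProtocol"),
            protocol@mode == "current_clamp")
  st <- .stepSweepStats(protocol)
  use <- st$stepPa < 0 & st$stepPa >= -100
  if (sum(use) < 2L) stop("need >= 2 negative steps between 0 and -100 pA")
  dV <- st$ssMv[use] - st$baselineMv[use]
  fit <- stats::lm(dV ~ st$stepPa[use])
  unname(coef(fit)[2L]) * 1000     # mV/pA -> MOhm
}

#' Membrane time constant from small negative steps
#'
#' Fits \code{V(t) = Vinf + A exp(-t/tau)} over the first 300 ms of each
#' qualifying step (negative, |I| <= 50 pA); fits with R-squared at or below
#' 0.8 (computed on the fitted window) are discarded, and the median
#' surviving tau is returned in ms.
#'
#' @param protocol a current-clamp step \linkS4class{EphysProtocol}
#' @param fitWindowS fit window from the step onset (s)
#' @param r2Gate minimum goodness of fit
#' @return membrane time constant (ms).
#' @export
membraneTimeConstant <- function(protocol, fitWindowS = 0.3, r2Gate = 0.8) {
  stopifnot(is(protocol, "EphysProtocol"),
            protocol@mode == "current_clamp")
  sweeps <- protocol@sweeps
  fs <- protocol@fsHz
  on <- protocol@stim$stepOnsetS
  stepPa <- protocol@stim$stepPa
  use <- which(stepPa < 0 & stepPa >= -50)
  if (!length(use)) stop("no qualifying step (negative, |I| <= 50 pA)")
  t <- (seq_len(ncol(sweeps)) - 1L) / fs
  win <- which(t >= on & t < on + fitWindowS)
  tw <- t[win] - on
  taus <- c()
  for (i in use) {
    y <- sweeps[i, win]
    a0 <- y[1L] - y[length(y)]
    fit <- try(minpack.lm::nlsLM(
      y ~ vinf + a * exp(-tw / tau),
      start = list(vinf = y[length(y)], a = a0, tau = 0.03),
      lower = c(-Inf, -Inf, 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
    if (is.finite(r2) && r2 > r2Gate)
      taus <- c(taus, 1000 * coef(fit)[["tau"]])
  }
  if (!length(taus)) stop("no exponential fit passed the R^2 gate")
  median(taus)
}

#' Membrane capacitance from tau and input resistance
#'
#' \code{C = tau / R}: with tau in ms and R in MOhm this is
#' \code{1000 * tauMs / rMohm} pF, the unit-consistent form of the RC
#' identity \code{tau = R C}.
#'
#' @param rMohm input resistance (MOhm)
#' @param tauMs membrane time constant (ms)
#' @return capacitance (pF).
#' @export
cellCapacitance <- function(rMohm, tauMs) {
  if (rMohm <= 0 || tauMs <= 0) stop("inputs must be positive")
  1000 * tauMs / rMohm
}

#' Sag percentage from hyperpolarizing steps
#'
#' Selects the negative step whose baseline-referenced peak deflection is
#' closest to -20 mV; sag is the percentage difference between the peak and
#' steady-state deflections (steady state from the last fifth of the step),
#' on magnitudes: \code{100 (|dPeak| - |dSS|) / |dPeak|}.
#'
#' @param protocol a current-clamp step \linkS4class{EphysProtocol}
#' @return sag (percent).
#' @export
sagRatio <- function(protocol) {
  stopifnot(is(protocol, "EphysProtocol"),
            protocol@mode == "current_clamp")
  st <- .stepSweepStats(protocol)
  neg <- which(st$stepPa < 0)
  if (!length(neg)) stop("no negative steps")
  dPeak <- st$peakMv[neg] - st$baselineMv[neg]
  pick <- neg[which.min(abs(dPeak - (-20)))]
  dp <- abs(st$peakMv[pick] - st$baselineMv[pick])
  dss <- abs(st$fifthMv[pick] - st$baselineMv[pick])
  100 * (dp - dss) / dp
}

.spikeTimes <- function(v, fsHz, thresholdMv = 0) {
  up <- which(v[-1L] >= thresholdMv & v[-length(v)] < thresholdMv)
  up / fsHz
}

#' Burst and steady-state firing rates per positive step
#'
#' Action potentials are upward crossings of 0 mV. Burst rate counts spikes
#' in the 50 ms from the first spike; steady rate counts spikes in the last
#' 200 ms of the step. Steps from 0 to 200 pA in 50 pA increments are used;
#' sweeps recorded with other increments are matched to the nearest 50 pA
#' target within a 5 pA tolerance.
#'
#' @param protocol a current-clamp step \linkS4class{EphysProtocol}
#' @param targetsPa step amplitudes analyzed (pA)
#' @param tolPa matching tolerance (pA)
#' @return data.frame: step_pa, burst_hz, steady_hz (zero spikes give 0 Hz).
#' @export
firingProfile <- function(protocol, targetsPa = seq(0, 200, by = 50),
                          tolPa = 5) {
  stopifnot(is(protocol, "EphysProtocol"),
            protocol@mode == "current_clamp")
  fs <- protocol@fsHz
  on <- protocol@stim$stepOnsetS
  dur <- protocol@stim$stepDurS
  stepPa <- protocol@stim$stepPa
  rows <- list()
  for (tg in targetsPa) {
    d <- abs(stepPa - tg)
    if (min(d) > tolPa) next
    i <- which.min(d)
    sp <- .spikeTimes(protocol@sweeps[i, ], fs)
    sp <- sp[sp >= on & sp < on + dur]
    burst <- if (length(sp))
      sum(sp >= sp[1L] & sp <= sp[1L] + 0.05) / 0.05 else 0
    steady <- sum(sp >= on + dur - 0.2 & sp < on + dur) / 0.2
    rows[[length(rows) + 1L]] <- data.frame(step_pa = stepPa[i],
                                            burst_hz = burst,
                                            steady_hz = steady)
  }
  do.call(rbind, rows)
}

#' Rheobase from a current ramp
#'
#' The injected current at the first upward 0 mV crossing of a 0-500 pA ramp
#' sweep. Note the measured value depends on the ramp rate for cells with a
#' non-negligible membrane time constant; with no spike the result is NA.
#'
#' @param protocol an \linkS4class{EphysProtocol} holding a ramp sweep with
#'   \code{rampRatePaPerS}/\code{rampStartS} metadata
#' @return rheobase (pA), or NA if the ramp elicits no spike.
#' @export
rheobase <- function(protocol) {
  stopifnot(is(protocol, "EphysProtocol"))
  rate <- protocol@stim$rampRatePaPerS
  if (is.null(rate)) stop("ramp metadata absent")
  sp <- .spikeTimes(protocol@sweeps[1L, ], protocol@fsHz)
  if (!length(sp)) return(NA_real_)
  rate * (sp[1L] - protocol@stim$rampStartS)
}

#' Extract the full intrinsic + synaptic feature set for one cell
#'
#' Convenience wrapper returning one row: input resistance, tau, capacitance,
#' sag, firing rates (maximal step), rheobase, PPRs and PSC latency —
#' whichever protocols are supplied.
#'
#' @param steps negative/positive current-step protocol (or NULL)
#' @param ramp ramp protocol (or NULL)
#' @param psc PSC train protocol (or NULL)
#' @return one-row data.frame of features (NA where not measurable).
#' @export
ephysFeatures <- function(steps = NULL, ramp = NULL, psc = NULL) {
  out <- data.frame(r_input_mohm = NA_real_, tau_ms = NA_real_,
                    capacitance_pf = NA_real_, sag_pct = NA_real_,
                    burst_hz = NA_real_, steady_hz = NA_real_,
                    rheobase_pa = NA_real_, ppr2 = NA_real_, ppr3 = NA_real_,
                    ppr4 = NA_real_, ppr5 = NA_real_,
                    psc_latency_ms = NA_real_)
  if (!is.null(steps)) {
    out$r_input_mohm <- inputResistance(steps)
    out$tau_ms <- membraneTimeConstant(steps)
    out$capacitance_pf <- cellCapacitance(out$r_input_mohm, out$tau_ms)
    out$sag_pct <- sagRatio(steps)
    if (any(steps@stim$stepPa > 0)) {
      fp <- firingProfile(steps)
      if (!is.null(fp) && nrow(fp)) {
        top <- fp[which.max(fp$step_pa), ]
        out$burst_hz <- top$burst_hz
        out$steady_hz <- top$steady_hz
      }
    }
  }
  if (!is.null(ramp)) out$rheobase_pa <- rheobase(ramp)
  if (!is.null(psc)) {
    med <- medianPscTrace(psc)
    onsets <- psc@stim$pulseOnsetsS
    ppr <- pairedPulseRatios(med, onsets, psc@fsHz)
    out[c("ppr2", "ppr3", "ppr4", "ppr5")] <- as.list(ppr[1:4])
    out$psc_latency_ms <- pscLatency(med, onsets[1L], psc@fsHz)
  }
  out
}
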