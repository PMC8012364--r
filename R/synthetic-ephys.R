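#' Simulate a current-step protocol on an RC (optionally sagging) membrane
#'
#' Hyperpolarizing sweeps follow the RC charging curve
#' \code{V(t) = Vrest + I R (1 - exp(-t/tau))}; with \code{sagFraction = s}
#' a slower opposing relaxation is added so the voltage peaks near
#' \code{I R} and settles at \code{I R (1 - s)} — i.e. a sag percentage of
#' \code{100 s} by construction. Depolarizing sweeps spike under a simple
#' integrate-and-fire rule: when the subthreshold RC voltage passes
#' \code{thresholdMv}, a 1 ms spike to \code{+30 mV} is pasted in and the
#' membrane resets.
#'
#' @param rMohm input resistance (MOhm)
#' @param tauMs membrane time constant (ms)
#' @param restMv resting potential (mV)
#' @param stepsPa step amplitudes (pA), one sweep each
#' @param stepOnsetS,stepDurS step timing (s)
#' @param sagFraction sag amplitude as a fraction of the peak deflection
#' @param sagTauMs sag relaxation time constant (ms)
#' @param thresholdMv spike threshold for depolarizing steps (mV)
#' @param noiseSdMv additive voltage noise SD (mV)
#' @param fsHz sampling rate (Hz)
#' @param seed integer RNG seed
#' @return An \linkS4class{EphysProtocol} (current clamp) whose \code{truth}
#'   records the cell parameters. A \code{warningFlag} is set in \code{stim}
#'   when the step is shorter than 5 tau (steady state undefined).
#' @export
simulateCurrentSteps <- function(rMohm = 100, tauMs = 20, restMv = -65,
                                 stepsPa = seq(0, -100, by = -20),
                                 stepOnsetS = 0.1, stepDurS = 0.5,
                                 sagFraction = 0, sagTauMs = 150,
                                 thresholdMv = -45, noiseSdMv = 0,
                                 fsHz = 20000, seed = 1L) {
  stopifnot(rMohm > 0, tauMs > 0)
  set.seed(seed)
  tauS <- tauMs / 1000
  shortStep <- stepDurS < 5 * tauS
  if (shortStep)
    warning("step shorter than 5 tau: steady state not reached")
  nS <- round((stepOnsetS + stepDurS + 0.2) * fsHz)
  t <- (seq_len(nS) - 1L) / fsHz
  inStep <- t >= stepOnsetS & t < stepOnsetS + stepDurS
  ts <- t - stepOnsetS
  sweeps <- matrix(restMv, length(stepsPa), nS)
  for (i in seq_along(stepsPa)) {
    I <- stepsPa[i]
    dv <- I * rMohm * 1e-3   # pA * MOhm = 1e-3 mV
    v <- rep(restMv, nS)
    resp <- dv * (1 - exp(-ts[inStep] / tauS))
    if (sagFraction > 0 && I < 0) {
      # sag relaxation begins once the RC charge is essentially complete
      # (7 tau), so the peak deflection stays ~= I*R and the steady state
      # settles at I*R*(1 - sagFraction): measured sag ~= 100*sagFraction
      tPk <- 7 * tauS
      late <- ts[inStep] > tPk
      resp[late] <- resp[late] - sagFraction * dv *
        (1 - exp(-(ts[inStep][late] - tPk) / (sagTauMs / 1000)))
    }
    v[inStep] <- restMv + resp
    # relaxation after step offset
    post <- t >= stepOnsetS + stepDurS
    vEnd <- v[max(which(inStep))]
    v[post] <- restMv + (vEnd - restMv) * exp(-(t[post] -
                                                  (stepOnsetS + stepDurS)) / tauS)
    if (I > 0 && restMv + dv > thresholdMv) {
      # integrate-and-fire on the step: recompute with spike/reset dynamics
      v <- .ifTrace(I, rMohm, tauS, restMv, thresholdMv, t, inStep)
    }
    if (noiseSdMv > 0) v <- v + stats::rnorm(nS, sd = noiseSdMv)
    sweeps[i, ] <- v
  }
  EphysProtocol(sweeps, fsHz, "current_clamp",
                stim = list(stepPa = stepsPa, stepOnsetS = stepOnsetS,
                            stepDurS = stepDurS, warningFlag = shortStep),
                truth = list(rTrueMohm = rMohm, tauTrueMs = tauMs,
                             sagTruePct = 100 * sagFraction,
                             thresholdMv = thresholdMv, restMv = restMv))
}

.ifTrace <- function(ipA, rMohm, tauS, restMv, thresholdMv, t, inStep,
                     spikePeakMv = 30, refracS = 0.002) {
  dt <- t[2L] - t[1L]
  v <- rep(restMv, length(t))
  vm <- restMv
  refracUntil <- -Inf
  for (k in seq_along(t)) {
    I <- if (inStep[k]) ipA else 0
    vInf <- restMv + I * rMohm * 1e-3
    vm <- vInf + (vm - vInf) * exp(-dt / tauS)
    if (t[k] < refracUntil) { v[k] <- restMv; vm <- restMv; next }
    if (vm >= thresholdMv) {
      v[k] <- spikePeakMv
      vm <- restMv
      refracUntil <- t[k] + refracS
    } else v[k] <- vm
  }
  v
}

#' Simulate a current-ramp sweep for rheobase measurement
#'
#' Injects a linear ramp (default 0 to 500 pA) into an integrate-and-fire
#' RC membrane. In the zero-noise, slow-ramp limit the first spike occurs
#' where the instantaneous current crosses the cell's threshold current
#' \code{(thresholdMv - restMv) / R}; faster ramps lag behind the membrane
#' time constant, which is exactly the dependence \code{\link{rheobase}}
#' documentation warns about.
#'
#' @param rMohm input resistance (MOhm)
#' @param tauMs membrane time constant (ms)
#' @param restMv resting potential (mV)
#' @param thresholdMv spike threshold (mV)
#' @param maxPa ramp endpoint (pA)
#' @param durS ramp duration (s)
#' @param noiseSdMv additive noise SD (mV)
#' @param fsHz sampling rate (Hz)
#' @param seed integer RNG seed
#' @return An \linkS4class{EphysProtocol} with one ramp sweep;
#'   \code{truth$rheobaseTruePa} holds the threshold current.
#' @export
simulateCurrentRamp <- function(rMohm = 100, tauMs = 20, restMv = -65,
                                thresholdMv = -45, maxPa = 500, durS = 5,
                                noiseSdMv = 0, fsHz = 20000, seed = 1L) {
  set.seed(seed)
  n <- round(durS * fsHz)
  t <- (seq_len(n) - 1L) / fsHz
  ipA <- maxPa * t / durS
  tauS <- tauMs / 1000
  dt <- 1 / fsHz
  v <- numeric(n)
  vm <- restMv
  for (k in seq_len(n)) {
    vInf <- restMv + ipA[k] * rMohm * 1e-3
    vm <- vInf + (vm - vInf) * exp(-dt / tauS)
    if (vm >= thresholdMv) { v[k] <- 30; vm <- restMv } else v[k] <- vm
  }
  if (noiseSdMv > 0) v <- v + stats::rnorm(n, sd = noiseSdMv)
  EphysProtocol(matrix(v, 1L), fsHz, "current_clamp",
                stim = list(rampRatePaPerS = maxPa / durS, rampStartS = 0,
                            rampMaxPa = maxPa),
                truth = list(rheobaseTruePa = (thresholdMv - restMv) /
                               (rMohm * 1e-3)))
}

#' Analytic per-pulse amplitudes of a short-term-plasticity synapse
#'
#' Tsodyks-Markram recursion for a train of \code{nPulses} at interval
#' \code{dtS}: resources \code{R} recover with \code{tauRecS}, utilization
#' \code{u} facilitates with \code{tauFacS}; pulse n releases \code{u_n R_n}.
#' Returned amplitudes are normalized to the first pulse and scaled by
#' \code{a1Pa}.
#'
#' @param U baseline release probability
#' @param tauFacS facilitation time constant (s)
#' @param tauRecS recovery time constant (s)
#' @param nPulses pulses in the train
#' @param dtS inter-pulse interval (s); 0.1 for a 10 Hz train
#' @param a1Pa amplitude of the first PSC (pA)
#' @return numeric vector of pulse amplitudes (pA).
#' @export
tmAmplitudes <- function(U = 0.2, tauFacS = 0.5, tauRecS = 0.2,
                         nPulses = 5L, dtS = 0.1, a1Pa = 10) {
  R <- 1; u <- U
  amps <- numeric(nPulses)
  for (k in seq_len(nPulses)) {
    amps[k] <- u * R
    Rafter <- R * (1 - u)
    R <- 1 - (1 - Rafter) * exp(-dtS / tauRecS)
    u <- U + u * (1 - U) * exp(-dtS / tauFacS)
  }
  a1Pa * amps / amps[1L]
}

#' Simulate an optogenetically evoked PSC train
#'
#' 10 sweeps of 5 PSCs at 10 Hz (100 ms spacing), voltage clamp at -60 mV:
#' each pulse evokes a difference-of-exponentials current of known peak
#' amplitude (given directly, or from the \code{\link{tmAmplitudes}}
#' recursion), inward (negative) by default, plus additive noise and an
#' optional linear baseline drift across the sweep to exercise drift
#' correction downstream.
#'
#' @param amplitudesPa per-pulse peak magnitudes (pA), length 5 by default
#' @param nSweeps sweeps
#' @param pulseHz train rate (Hz)
#' @param firstOnsetS onset of the first pulse (s)
#' @param riseMs,decayMs PSC kinetics (ms)
#' @param inward inward (negative) currents?
#' @param noiseSdPa additive noise SD (pA)
#' @param driftPaPerS linear baseline drift slope (pA/s)
#' @param durS sweep duration (s)
#' @param fsHz sampling rate (Hz)
#' @param seed integer RNG seed
#' @return An \linkS4class{EphysProtocol} (voltage clamp);
#'   \code{truth$amplitudesPa} holds the injected peak magnitudes and
#'   \code{truth$pprTrue} the implied paired-pulse ratios.
#' @export
simulatePscTrain <- function(amplitudesPa = tmAmplitudes(), nSweeps = 10L,
                             pulseHz = 10, firstOnsetS = 0.5,
                             riseMs = 1, decayMs = 8, inward = TRUE,
                             noiseSdPa = 0, driftPaPerS = 0, durS = 1.2,
                             fsHz = 20000, seed = 1L) {
  if (any(amplitudesPa < 0)) stop("amplitudes must be non-negative")
  set.seed(seed)
  n <- round(durS * fsHz)
  t <- (seq_len(n) - 1L) / fsHz
  onsets <- firstOnsetS + (seq_along(amplitudesPa) - 1L) / pulseHz
  riseS <- riseMs / 1000; decayS <- decayMs / 1000
  # difference of exponentials normalized to unit peak
  tpk <- riseS * decayS / (decayS - riseS) * log(decayS / riseS)
  norm <- exp(-tpk / decayS) - exp(-tpk / riseS)
  clean <- numeric(n)
  for (k in seq_along(onsets)) {
    idx <- t >= onsets[k]
    dtk <- t[idx] - onsets[k]
    clean[idx] <- clean[idx] + amplitudesPa[k] *
      (exp(-dtk / decayS) - exp(-dtk / riseS)) / norm
  }
  if (inward) clean <- -clean
  sweeps <- matrix(0, nSweeps, n)
  for (s in seq_len(nSweeps)) {
    sw <- clean + driftPaPerS * t
    if (noiseSdPa > 0) sw <- sw + stats::rnorm(n, sd = noiseSdPa)
    sweeps[s, ] <- sw
  }
  EphysProtocol(sweeps, fsHz, "voltage_clamp",
                stim = list(pulseOnsetsS = onsets, pulseHz = pulseHz),
                truth = list(amplitudesPa = amplitudesPa,
                             pprTrue = amplitudesPa[-1L] / amplitudesPa[1L],
                             driftPaPerS = driftPaPerS))
}
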