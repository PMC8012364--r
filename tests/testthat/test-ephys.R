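test_that("noiseless RC sweeps match the closed-form charging curve", {
  st <- simulateCurrentSteps(rMohm = 100, tauMs = 20, restMv = -65,
                             stepsPa = c(-20, -60), stepOnsetS = 0.1,
                             stepDurS = 0.5, fsHz = 20000)
  sw <- sweepMatrix(st)
  t <- (seq_len(ncol(sw)) - 1L) / 20000
  inStep <- t >= 0.1 & t < 0.6
  vAnalytic <- -65 + (-20 * 100 * 1e-3) * (1 - exp(-(t[inStep] - 0.1) / 0.02))
  expect_equal(unname(sw[1, inStep]), vAnalytic, tolerance = 1e-10)
})

test_that("intrinsic properties are recovered exactly from clean cells", {
  st <- simulateCurrentSteps(rMohm = 100, tauMs = 20,
                             stepsPa = seq(0, -100, by = -20), stepDurS = 0.5)
  r <- inputResistance(st)
  tau <- membraneTimeConstant(st)
  expect_lt(abs(r - 100) / 100, 0.001)
  expect_lt(abs(tau - 20) / 20, 0.001)
  expect_equal(cellCapacitance(r, tau), 1000 * tau / r)
  # units: R = 150 MOhm, tau = 15 ms -> 100 pF; doubling R halves C
  expect_equal(cellCapacitance(150, 15), 100)
  expect_equal(cellCapacitance(100, 20), 200)
  expect_equal(cellCapacitance(300, 15), 50)
  expect_error(cellCapacitance(-1, 10), "positive")
  zeroOnly <- simulateCurrentSteps(stepsPa = c(0, 0))
  expect_error(inputResistance(zeroOnly), "negative steps")
})

test_that("tau recovery tolerates realistic voltage noise", {
  set.seed(21)
  errs <- replicate(100, {
    st <- simulateCurrentSteps(rMohm = 120, tauMs = 15,
                               stepsPa = c(-20, -35, -50), stepDurS = 0.5,
                               noiseSdMv = 0.2, fsHz = 10000,
                               seed = sample.int(1e6, 1))
    abs(membraneTimeConstant(st) - 15) / 15
  })
  expect_lt(median(errs), 0.05)
})

test_that("the exponential R^2 gate rejects pure noise", {
  set.seed(22)
  noise <- matrix(rnorm(2 * 10000, -65, 2), 2)
  prot <- EphysProtocol(noise, 10000, "current_clamp",
                        stim = list(stepPa = c(-20, -40), stepOnsetS = 0.1,
                                    stepDurS = 0.5))
  expect_error(membraneTimeConstant(prot), "gate")
})

test_that("sag measurement follows the nearest-to--20 mV rule", {
  # constructed sweeps: step 0.1-1.1 s; known dPeak and dSS from baseline 0
  fs <- 1000
  mkSweep <- function(dPeak, dSS) {
    n <- 1300
    t <- (seq_len(n) - 1) / fs
    v <- numeric(n)
    inStep <- t >= 0.1 & t < 1.1
    v[inStep] <- dSS
    v[t >= 0.15 & t < 0.35] <- dPeak     # early peak
    v
  }
  prot <- EphysProtocol(rbind(mkSweep(-12, -10), mkSweep(-19, -15.2),
                              mkSweep(-27, -22)),
                        fs, "current_clamp",
                        stim = list(stepPa = c(-20, -40, -60),
                                    stepOnsetS = 0.1, stepDurS = 1))
  # -19 is closest to -20; sag = 100 * (19 - 15.2) / 19
  expect_equal(sagRatio(prot), 100 * (19 - 15.2) / 19)
  # simulated sag cell: measured percentage tracks the configured fraction
  st <- simulateCurrentSteps(sagFraction = 0.2, stepsPa = c(-20, -40, -60),
                             stepDurS = 1, sagTauMs = 100)
  expect_equal(sagRatio(st), 20, tolerance = 0.01)
  stats <- csrttpipe:::.stepSweepStats(st)
  dPeak <- stats$peakMv - stats$baselineMv
  dSS <- stats$fifthMv - stats$baselineMv
  expect_true(all(abs(dPeak[stats$stepPa < 0]) >
                    abs(dSS[stats$stepPa < 0])))
  # no-sag RC cell: peak equals steady state -> 0%
  st0 <- simulateCurrentSteps(sagFraction = 0, stepsPa = c(-20, -40),
                              stepDurS = 1)
  expect_equal(sagRatio(st0), 0, tolerance = 0.01)
  expect_error(sagRatio(simulateCurrentSteps(stepsPa = c(0, 20))),
               "no negative steps")
})

test_that("firing rates count 0 mV crossings in their windows", {
  fs <- 10000
  n <- 8000                          # 0.8 s, step 0.1-0.6 s
  mkSpikes <- function(timesS) {
    v <- rep(-65, n)
    for (ts in timesS) v[round(ts * fs) + (0:5)] <- 30
    v
  }
  # 3 spikes within 50 ms of the first; 4 spikes in the last 200 ms
  sw <- rbind(mkSpikes(c(0.15, 0.17, 0.19)),
              mkSpikes(c(0.42, 0.47, 0.52, 0.57)),
              rep(-65, n))
  prot <- EphysProtocol(sw, fs, "current_clamp",
                        stim = list(stepPa = c(100, 150, 50),
                                    stepOnsetS = 0.1, stepDurS = 0.5))
  fp <- firingProfile(prot)
  expect_equal(fp$burst_hz[fp$step_pa == 100], 60)
  expect_equal(fp$steady_hz[fp$step_pa == 150], 20)
  expect_equal(fp$burst_hz[fp$step_pa == 50], 0)
  expect_equal(fp$steady_hz[fp$step_pa == 50], 0)
  # 15 pA-increment sweeps match 50 pA targets within 5 pA only
  prot2 <- EphysProtocol(sw, fs, "current_clamp",
                         stim = list(stepPa = c(45, 120, 150),
                                     stepOnsetS = 0.1, stepDurS = 0.5))
  fp2 <- firingProfile(prot2)
  expect_setequal(fp2$step_pa, c(45, 150))        # 120 matches nothing
})

test_that("ramp rheobase reads the current at the first spike", {
  rp <- simulateCurrentRamp(rMohm = 100, tauMs = 20, restMv = -65,
                            thresholdMv = -45, maxPa = 500, durS = 5)
  expect_equal(groundTruth(rp)$rheobaseTruePa, 200)
  expect_lt(abs(rheobase(rp) - 200), 5)
  # a steeper ramp lags more but stays within 10%
  rpFast <- simulateCurrentRamp(rMohm = 100, tauMs = 20, thresholdMv = -45,
                                maxPa = 500, durS = 1)
  expect_lt(abs(rheobase(rpFast) - 200) / 200, 0.10)
  # no spike on a subthreshold ramp
  rpNone <- simulateCurrentRamp(rMohm = 20, thresholdMv = -20, maxPa = 100,
                                durS = 1)
  expect_true(is.na(rheobase(rpNone)))
  expect_error(rheobase(simulateCurrentSteps()), "ramp metadata")
})

test_that("holding-potential offsets do not change intrinsic features", {
  st <- simulateCurrentSteps(rMohm = 150, tauMs = 25, sagFraction = 0.1,
                             stepsPa = c(-20, -40, -60, -80), stepDurS = 1)
  shifted <- EphysProtocol(sweepMatrix(st) + 7.3, samplingRate(st),
                           "current_clamp", stim = stimMeta(st))
  expect_equal(inputResistance(shifted), inputResistance(st))
  expect_equal(membraneTimeConstant(shifted), membraneTimeConstant(st),
               tolerance = 1e-6)
  expect_equal(sagRatio(shifted), sagRatio(st), tolerance = 1e-9)
})
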