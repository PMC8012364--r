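# Shared fixture builders. Everything is generated in code; photometry
# fixtures use a reduced raw rate (128 Hz, decimation 8 -> 16 Hz frames) so
# the full chain stays fast while exercising the same code paths as the
# ~1017 Hz / 64 default.

makeEventRow <- function(trial_index, start, delay, outcome,
                         response = NA_real_, magazine = NA_real_,
                         cueDur = 1, session = "s1") {
  reward <- if (!is.na(magazine)) response + magazine else NA_real_
  data.frame(session_id = session, trial_index = trial_index,
             trial_start_s = start, delay_s = delay,
             cue_onset_s = start + delay, cue_duration_s = cueDur,
             response_time_s = response, outcome = outcome,
             reward_collect_s = reward, magazine_latency_s = magazine,
             stringsAsFactors = FALSE)
}

# event log with exact outcome counts; trials spaced regularly
makeCountedEvents <- function(nCorrect, nIncorrect, nOmission, nPremature,
                              delay = 5, spacing = 25, magazine = 1) {
  outcomes <- rep(c("correct", "incorrect", "omission", "premature"),
                  c(nCorrect, nIncorrect, nOmission, nPremature))
  rows <- lapply(seq_along(outcomes), function(i) {
    start <- 10 + (i - 1) * spacing
    o <- outcomes[i]
    resp <- switch(o, correct = , incorrect = start + delay + 0.5,
                   premature = start + delay / 2, NA_real_)
    mag <- if (o == "correct") magazine else NA_real_
    makeEventRow(i, start, delay, o, resp, mag)
  })
  SessionEvents(do.call(rbind, rows))
}

# already-z-scored epoch tensor on a 16 Hz grid, for metric unit tests
makeZEpochs <- function(values, delays, fsHz = 16, windowS = c(-5, 15),
                        outcome = "correct", session = "s1") {
  values <- as.matrix(values)
  ks <- seq.int(ceiling(windowS[1] * fsHz), ceiling(windowS[2] * fsHz) - 1L)
  stopifnot(ncol(values) == length(ks))
  meta <- data.frame(trial_index = seq_len(nrow(values)),
                     outcome = rep_len(outcome, nrow(values)),
                     delay_s = rep_len(delays, nrow(values)),
                     session_id = rep_len(session, nrow(values)),
                     baseline_mean = 0, baseline_sd = 1)
  EpochedTensor(values, ks / fsHz, meta, "trial_start", fsHz,
                zscored = TRUE, extraMeta = list(droppedTrials = 0L,
                                                 nBaselineFrames = 64L))
}

# small full-chain fixture: simulate -> preprocess -> z-scored epochs
smallChainFixture <- function(nTrials = 15, seed = 7, transientAmplitude = 0.05,
                              motionAmplitude = 0.02, noiseSd = 0.002,
                              fsRawHz = 128, decimation = 8L, ...) {
  ev <- simulateSessionEvents(SessionConfig(nTrials = nTrials, seed = seed))
  pc <- PhotometryConfig(fsRawHz = fsRawHz,
                         transientAmplitude = transientAmplitude,
                         motionAmplitude = motionAmplitude,
                         noiseSd = noiseSd, seed = seed + 1L, ...)
  sim <- simulatePhotometry(ev, pc)
  trace <- preprocessRecording(sim$recording, decimation = decimation)
  epochs <- zscoreEpochs(epochTrials(trace, ev))
  list(events = ev, sim = sim, trace = trace, epochs = epochs)
}
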