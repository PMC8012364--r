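test_that("epoch window arithmetic matches the frame-grid contract", {
  fs <- 16
  trace <- ProcessedTrace(rnorm(fs * 200), fs)
  ev <- SessionEvents(makeEventRow(1, 100, 5, "correct", 105.5, 1))
  ep <- epochTrials(trace, ev, windowS = c(-5, 15))
  expect_identical(dim(ep), c(1L, 320L))
  ft <- frameTimes(ep)
  expect_equal(ft[1], -5)
  expect_equal(ft[320], 15 - 1 / 16)
  expect_equal(unique(round(diff(ft), 12)), 1 / 16)
})

test_that("trials truncated by the recording edges are dropped and logged", {
  fs <- 16
  trace <- ProcessedTrace(rnorm(fs * 120), fs)
  ev <- SessionEvents(rbind(
    makeEventRow(1, 2, 5, "correct", 7.5, 1),     # baseline starts at -3 s
    makeEventRow(2, 50, 5, "correct", 55.5, 1),
    makeEventRow(3, 115, 5, "omission")))         # window past trace end
  ep <- epochTrials(trace, ev)
  expect_identical(nrow(ep), 1L)
  expect_identical(S4Vectors::metadata(ep)$droppedTrials, 2L)
  expect_identical(nrow(ep) + S4Vectors::metadata(ep)$droppedTrials,
                   nTrials(ev))
})

test_that("constant traces yield constant epochs and are unusable baselines", {
  fs <- 16
  trace <- ProcessedTrace(rep(0.3, fs * 200), fs)
  ev <- SessionEvents(makeEventRow(1, 100, 5, "correct", 105.5, 1))
  ep <- epochTrials(trace, ev)
  expect_true(all(SummarizedExperiment::assay(ep) == 0.3))
  expect_warning(expect_error(zscoreEpochs(ep), "usable baseline"),
                 "zero or undefined")
})

test_that("z-scoring applies the per-trial baseline transform", {
  fs <- 16
  n <- fs * 200
  x <- rep(0, n)
  start <- 100
  baseIdx <- which((0:(n - 1)) / fs >= start - 5 & (0:(n - 1)) / fs < start - 1)
  x[baseIdx] <- rep(c(3, 7), length.out = length(baseIdx))   # mean 5
  delayIdx <- which((0:(n - 1)) / fs >= start & (0:(n - 1)) / fs < start + 5)
  x[delayIdx] <- 9
  ev <- SessionEvents(makeEventRow(1, start, 5, "correct", 105.5, 1))
  ep <- zscoreEpochs(epochTrials(ProcessedTrace(x, fs), ev))
  tm <- trialMeta(ep)
  expect_equal(tm$baseline_mean, 5)
  z <- SummarizedExperiment::assay(ep)[1, ]
  ft <- frameTimes(ep)
  expected <- (9 - tm$baseline_mean) / tm$baseline_sd
  expect_equal(unname(z[ft >= 0 & ft < 5]),
               rep(expected, sum(ft >= 0 & ft < 5)))
  expect_equal(expected, 2, tolerance = 0.02)   # sd of {3,7} pattern ~ 2
  # idempotence: z-scoring a z-scored tensor is a no-op
  expect_identical(SummarizedExperiment::assay(zscoreEpochs(ep)),
                   SummarizedExperiment::assay(ep))
})

test_that("z-scored baselines pool to mean 0, SD 1 across many null trials", {
  fs <- 16
  set.seed(31)
  n <- fs * 30000
  trace <- ProcessedTrace(rnorm(n), fs)
  starts <- seq(20, n / fs - 20, by = 29.5)[1:1000]
  ev <- SessionEvents(do.call(rbind, lapply(seq_along(starts), function(i)
    makeEventRow(i, starts[i], 5, "omission"))))
  ep <- zscoreEpochs(epochTrials(trace, ev, windowS = c(-5, 10)))
  ft <- frameTimes(ep)
  zb <- SummarizedExperiment::assay(ep)[, ft >= -5 & ft < -1]
  expect_lt(abs(mean(zb)), 0.01)
  expect_lt(abs(sd(zb) - 1), 0.02)
})

test_that("z-scoring is invariant to affine transforms of the trace", {
  fx <- smallChainFixture(nTrials = 8, seed = 13)
  dff <- traceValues(fx$trace)
  fs <- samplingRate(fx$trace)
  ep1 <- zscoreEpochs(epochTrials(ProcessedTrace(dff, fs), fx$events))
  ep2 <- zscoreEpochs(epochTrials(ProcessedTrace(3.7 * dff + 0.42, fs),
                                  fx$events))
  expect_equal(SummarizedExperiment::assay(ep1),
               SummarizedExperiment::assay(ep2), tolerance = 1e-9)
})

test_that("trial selection filters rows, preserves metadata and commutes", {
  fx <- smallChainFixture(nTrials = 25, seed = 17)
  ep <- fx$epochs
  tab <- eventTable(fx$events)
  co <- selectTrials(ep, outcome = "correct")
  expect_identical(nrow(co), sum(trialMeta(ep)$outcome == "correct"))
  expect_true(all(trialMeta(co)$outcome == "correct"))
  lng <- selectTrials(ep, delay = 12.5)
  expect_true(all(trialMeta(lng)$delay_s == 12.5))
  ab <- selectTrials(selectTrials(ep, outcome = "correct"), delay = 12.5)
  ba <- selectTrials(selectTrials(ep, delay = 12.5), outcome = "correct")
  both <- selectTrials(ep, outcome = "correct", delay = 12.5)
  expect_identical(SummarizedExperiment::assay(ab),
                   SummarizedExperiment::assay(ba))
  expect_identical(SummarizedExperiment::assay(ab),
                   SummarizedExperiment::assay(both))
  expect_error(selectTrials(ep, outcome = "banana"), "unknown outcome")
  expect_warning(selectTrials(ep, delay = 99), "empty")
  expect_identical(nrow(suppressWarnings(selectTrials(ep, delay = 99))), 0L)
})

test_that("response-aligned epochs still use the pre-trial baseline", {
  fx <- smallChainFixture(nTrials = 15, seed = 19)
  epR <- epochTrials(fx$trace, fx$events, alignEvent = "response",
                     windowS = c(-3, 3))
  epT <- epochTrials(fx$trace, fx$events)
  tmR <- trialMeta(epR); tmT <- trialMeta(epT)
  shared <- intersect(tmR$trial_index, tmT$trial_index)
  expect_gt(length(shared), 0)
  expect_equal(tmR$baseline_mean[match(shared, tmR$trial_index)],
               tmT$baseline_mean[match(shared, tmT$trial_index)])
  # omissions have no response: dropped from response-aligned epochs
  expect_false(any(tmR$outcome == "omission"))
})

test_that("subject mean traces average within subject on the shared grid", {
  ep <- makeZEpochs(rbind(rep(1, 320), rep(3, 320), rep(5, 320)),
                    delays = 5,
                    session = c("a", "a", "b"))
  g <- subjectMeanTraces(ep)
  expect_identical(nSubjects(g), 2L)
  expect_equal(unname(groupTraces(g)[1, 1]), 2)
  expect_equal(unname(groupTraces(g)[2, 1]), 5)
})
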