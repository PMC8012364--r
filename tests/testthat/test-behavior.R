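test_that("session percentages follow their defining formulas", {
  ev <- makeCountedEvents(80, 20, 10, 10)
  s <- summarizeSession(ev)
  expect_identical(s$overall$n_started, 120L)
  expect_equal(s$overall$accuracy_pct, 80)
  expect_equal(s$overall$omission_pct, 100 * 10 / 120)
  expect_equal(s$overall$premature_pct, 100 * 10 / 120)
  expect_identical(s$nExcluded, 0L)
  # counts reconstruct exactly from the percentages
  N <- s$overall$n_started
  expect_equal(round(s$overall$premature_pct * N / 100), 10)
  expect_equal(round(s$overall$omission_pct * N / 100), 10)
})

test_that("slow magazine collection excludes the whole trial by default", {
  ev <- eventTable(makeCountedEvents(10, 5, 3, 2))
  ev$magazine_latency_s[1] <- 12           # one slow correct trial
  ev$reward_collect_s[1] <- ev$response_time_s[1] + 12
  events <- SessionEvents(ev)
  s <- summarizeSession(events)
  expect_identical(s$nExcluded, 1L)
  expect_identical(s$overall$n_started, 19L)
  expect_identical(s$overall$n_correct, 9L)
  expect_equal(s$overall$accuracy_pct, 100 * 9 / 14)
  # latency-only mode keeps the trial in the outcome tallies
  s2 <- summarizeSession(events, excludeFrom = "latency")
  expect_identical(s2$overall$n_started, 20L)
  expect_identical(s2$overall$n_correct, 10L)
  expect_false(any(is.na(s2$overall$accuracy_pct)))
  expect_lt(s2$overall$magazine_latency_s, 10)
})

test_that("edge cases summarize with explicit undefined flags", {
  empty <- SessionEvents(eventTable(makeCountedEvents(1, 0, 0, 0))[0, ])
  s <- summarizeSession(empty)
  expect_identical(s$overall$n_started, 0L)
  expect_true(is.na(s$overall$accuracy_pct))
  onlyOm <- makeCountedEvents(0, 0, 5, 0)
  expect_true(is.na(summarizeSession(onlyOm)$overall$accuracy_pct))
  expect_equal(summarizeSession(onlyOm)$overall$omission_pct, 100)
})

test_that("per-delay and per-cue breakdowns partition the session", {
  ev <- simulateSessionEvents(SessionConfig(nTrials = 300, seed = 4,
                                            sessionLengthS = 2e5))
  s <- summarizeSession(ev)
  expect_equal(sum(s$byDelay$n_started), s$overall$n_started)
  expect_identical(sort(s$byDelay$delay_s), c(5, 7.5, 12.5))
  expect_equal(sum(s$byCueDuration$n_started), s$overall$n_started)
})

test_that("block splitting uses half-open 30-min windows", {
  rows <- rbind(
    makeEventRow(1, 100, 5, "correct", 105.5, 1),
    makeEventRow(2, 1799, 5, "omission"),
    makeEventRow(3, 1800, 5, "correct", 1805.5, 1),   # exactly 30:00
    makeEventRow(4, 5000, 5, "premature", 5002))
  b <- splitBlocks(SessionEvents(rows))
  expect_identical(nrow(b), 5L)
  expect_identical(b$n_started, c(2L, 1L, 1L, 0L, 0L))
  expect_identical(b$n_correct[2], 1L)                 # boundary trial
  expect_error(splitBlocks(SessionEvents(rows), blockMinutes = 0),
               "non-positive")
})

test_that("uniform trial times distribute evenly over blocks", {
  set.seed(7)
  starts <- sort(runif(500, 0, 150 * 60))
  rows <- do.call(rbind, lapply(seq_along(starts), function(i)
    makeEventRow(i, starts[i], 5, "omission")))
  b <- splitBlocks(SessionEvents(rows))
  se <- sqrt(500 * 0.2 * 0.8)
  expect_true(all(abs(b$n_started - 100) <= 3 * se))
  expect_identical(sum(b$n_started), 500L)
})

test_that("premature latency distributions respect filters and bins", {
  rows <- rbind(
    makeEventRow(1, 10, 5, "premature", 14.9),
    makeEventRow(2, 40, 5, "premature", 14.9 + 30),
    makeEventRow(3, 70, 12.5, "premature", 76))
  d <- prematureLatencyDistribution(SessionEvents(rows), delay = 5)
  expect_identical(length(d$latencies), 2L)
  expect_true(all(abs(d$latencies - 4.9) < 1e-9))
  expect_identical(sum(d$counts > 0), 1L)              # point mass in one bin
  dLong <- prematureLatencyDistribution(SessionEvents(rows), delay = 12.5)
  expect_identical(length(dLong$latencies), 1L)
  expect_warning(prematureLatencyDistribution(SessionEvents(rows),
                                              delay = 7.5),
                 "no premature")
})

test_that("uniform premature latencies pass a KS check against uniform", {
  set.seed(9)
  passes <- replicate(10, {
    lat <- runif(500, 0, 12.5)
    starts <- seq(10, by = 30, length.out = 500)
    rows <- do.call(rbind, lapply(1:500, function(i)
      makeEventRow(i, starts[i], 12.5, "premature", starts[i] + lat[i])))
    d <- prematureLatencyDistribution(SessionEvents(rows))
    ks <- suppressWarnings(stats::ks.test(d$latencies, "punif", 0, 12.5))
    ks$statistic < 1.36 / sqrt(500)
  })
  expect_gte(sum(passes), 8)
})

test_that("double-label percentages reproduce the printed quantification", {
  expect_identical(doubleLabelPercentage(6, 747), 0.80)
  expect_identical(doubleLabelPercentage(7, 1101), 0.64)
  expect_identical(doubleLabelPercentage(0, 100), 0)
  expect_error(doubleLabelPercentage(5, 0), "positive")
  expect_error(doubleLabelPercentage(8, 7), "nDouble")
})

test_that("simulate -> summarize round-trips the outcome probabilities", {
  p <- c(correct = 0.6, incorrect = 0.1, omission = 0.12, premature = 0.18)
  cfg <- SessionConfig(nTrials = 5000, outcomeProbabilities = p,
                       sessionLengthS = 5e6, seed = 77)
  ev <- simulateSessionEvents(cfg)
  s <- summarizeSession(ev, magazineMaxS = Inf)$overall
  N <- s$n_started
  for (nm in c("premature", "omission")) {
    se <- 100 * sqrt(p[[nm]] * (1 - p[[nm]]) / N)
    obs <- if (nm == "premature") s$premature_pct else s$omission_pct
    expect_lt(abs(obs - 100 * p[[nm]]), 2 * se + 1e-9)
  }
  accTrue <- 100 * p[["correct"]] / (p[["correct"]] + p[["incorrect"]])
  expect_lt(abs(s$accuracy_pct - accTrue), 2)
})
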