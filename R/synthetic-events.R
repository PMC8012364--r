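#' Configuration for a simulated self-paced 5-CSRTT session
#'
#' Defaults reproduce the variable-delay challenge sessions: delays drawn
#' uniformly from {5, 7.5, 12.5} s, a 1 s cue, a 2 s limited hold, and a 5 s
#' timeout after errors. Outcome probabilities may be one vector over
#' {correct, incorrect, omission, premature} applied to every delay, or a
#' named list keyed by delay (as character, e.g. \code{"12.5"}) so premature
#' rates can rise with delay length, as observed in long-delay trials.
#'
#' @param nTrials number of started trials
#' @param delaySetS candidate delays (s)
#' @param cueDurationS cue duration (s); use \code{c(0.2, 0.5, 1)} for
#'   variable-cue attention sessions (drawn uniformly per trial)
#' @param limitedHoldS limited hold after cue offset (s)
#' @param timeoutS timeout after errors (s)
#' @param itiS inter-trial interval appended after each trial (s); the task
#'   enforces a quiet period so pre-trial baselines are task-free
#' @param outcomeProbabilities numeric vector of length 4 (named
#'   correct/incorrect/omission/premature) or a list of such vectors keyed by
#'   delay
#' @param sessionLengthS session duration cap (s)
#' @param seed integer RNG seed
#' @return A validated list of class \code{"SessionConfig"}.
#' @export
SessionConfig <- function(nTrials = 100,
                          delaySetS = c(5, 7.5, 12.5),
                          cueDurationS = 1,
                          limitedHoldS = 2,
                          timeoutS = 5,
                          itiS = 10,
                          outcomeProbabilities = c(correct = 0.65,
                                                   incorrect = 0.1,
                                                   omission = 0.1,
                                                   premature = 0.15),
                          sessionLengthS = 9000,
                          seed = 1L) {
  stopifnot(length(nTrials) == 1L)
  if (!is.numeric(nTrials) || nTrials < 1)
    stop("nTrials must be a positive count")
  if (!length(delaySetS) || any(delaySetS <= 0))
    stop("delaySetS must be non-empty and positive")
  if (any(c(cueDurationS, limitedHoldS, timeoutS, itiS, sessionLengthS) <= 0))
    stop("all durations must be positive")
  probs <- .normalizeOutcomeProbs(outcomeProbabilities, delaySetS)
  structure(list(nTrials = as.integer(nTrials), delaySetS = delaySetS,
                 cueDurationS = cueDurationS, limitedHoldS = limitedHoldS,
                 timeoutS = timeoutS, itiS = itiS,
                 outcomeProbabilities = probs,
                 sessionLengthS = sessionLengthS, seed = as.integer(seed)),
            class = "SessionConfig")
}

.normalizeOutcomeProbs <- function(p, delaySetS) {
  checkOne <- function(v) {
    if (is.null(names(v)) && length(v) == 4L) names(v) <- .OUTCOMES
    if (!all(.OUTCOMES %in% names(v)))
      stop("outcome probabilities must be named correct/incorrect/omission/premature")
    v <- v[.OUTCOMES]
    v[is.na(v)] <- 0
    if (abs(sum(v) - 1) > 1e-8)
      stop("outcome probabilities must sum to 1")
    if (any(v < 0)) stop("outcome probabilities must be non-negative")
    v
  }
  keys <- as.character(delaySetS)
  if (is.list(p)) {
    if (!all(keys %in% names(p)))
      stop("outcomeProbabilities list must have an entry per delay")
    lapply(setNames(p[keys], keys), checkOne)
  } else {
    v <- checkOne(p)
    setNames(rep(list(v), length(keys)), keys)
  }
}

#' Simulate a 5-CSRTT session event log
#'
#' Trials are laid down sequentially: each trial's delay is drawn uniformly
#' from the configured delay set, its outcome from the delay-conditional
#' outcome distribution, and response/reward times from the task structure
#' (premature responses fall strictly inside the delay, correct and incorrect
#' responses inside cue + limited hold, omissions carry no response). Rewarded
#' trials get a magazine latency from a right-skewed (log-normal) distribution
#' capped only by construction, so the >10 s exclusion rule downstream has
#' work to do when its tail parameter is raised.
#'
#' @param config a \code{\link{SessionConfig}}
#' @param sessionId session label for the event log
#' @return A \linkS4class{SessionEvents} object. Trials that would start after
#'   \code{sessionLengthS} are not generated (the log may hold fewer than
#'   \code{nTrials} rows).
#' @export
simulateSessionEvents <- function(config, sessionId = "sim") {
  stopifnot(inherits(config, "SessionConfig"))
  set.seed(config$seed)
  rows <- vector("list", config$nTrials)
  t <- 5   # first trial a few seconds into the recording
  n <- 0L
  for (i in seq_len(config$nTrials)) {
    delay <- sample(config$delaySetS, 1L)
    cueDur <- if (length(config$cueDurationS) > 1L)
      sample(config$cueDurationS, 1L) else config$cueDurationS
    p <- config$outcomeProbabilities[[as.character(delay)]]
    outcome <- sample(.OUTCOMES, 1L, prob = p)
    cueOn <- t + delay
    resp <- NA_real_; rewardCollect <- NA_real_; magLat <- NA_real_
    if (outcome == "premature") {
      # strictly inside the delay, biased late (animals fail close to the cue)
      resp <- t + delay * stats::rbeta(1L, 3, 1.2)
      tEnd <- resp + config$timeoutS
    } else if (outcome %in% c("correct", "incorrect")) {
      resp <- cueOn + (cueDur + config$limitedHoldS) * stats::rbeta(1L, 1.5, 3)
      if (outcome == "correct") {
        magLat <- stats::rlnorm(1L, meanlog = 0.3, sdlog = 0.5)
        rewardCollect <- resp + magLat
        tEnd <- rewardCollect
      } else {
        tEnd <- resp + config$timeoutS
      }
    } else {                         # omission
      tEnd <- cueOn + cueDur + config$limitedHoldS + config$timeoutS
    }
    if (t > config$sessionLengthS) break
    n <- n + 1L
    rows[[n]] <- data.frame(
      session_id = sessionId, trial_index = n, trial_start_s = t,
      delay_s = delay, cue_onset_s = cueOn, cue_duration_s = cueDur,
      response_time_s = resp, outcome = outcome,
      reward_collect_s = rewardCollect, magazine_latency_s = magLat,
      stringsAsFactors = FALSE)
    t <- tEnd + config$itiS + stats::rexp(1L, rate = 0.5)  # self-paced start
  }
  SessionEvents(do.call(rbind, rows[seq_len(n)]))
}
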