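#' Bootstrap confidence band for a group-mean trace
#'
#' Subject-level percentile bootstrap: each iteration draws \code{n} subjects
#' with replacement from the \code{n} per-subject mean traces and averages
#' them; per frame, the band is the empirical \code{alpha/2} and
#' \code{1 - alpha/2} quantiles of the bootstrapped means. The default
#' \code{alpha = 0.001} with 5000 iterations matches the elevated-window
#' detection settings used throughout.
#'
#' @param group a \linkS4class{GroupTraces} (>= 2 subjects)
#' @param nIter bootstrap iterations (>= 100)
#' @param alpha two-sided level in (0, 0.5)
#' @param seed integer RNG seed
#' @return A \linkS4class{BootstrapResult}.
#' @export
bootstrapMeanCI <- function(group, nIter = 5000L, alpha = 0.001,
                            seed = 1L) {
  stopifnot(is(group, "GroupTraces"))
  M <- group@traces
  n <- nrow(M)
  if (n < 2L) stop("bootstrap requires >= 2 subjects")
  if (nIter < 100L) stop("nIter must be >= 100")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)")
  set.seed(seed)
  draws <- matrix(sample.int(n, n * nIter, replace = TRUE), nrow = nIter)
  W <- matrix(0L, nIter, n)
  for (j in seq_len(n)) W[, j] <- rowSums(draws == j)
  boot <- (W %*% M) / n
  qs <- apply(boot, 2L, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  new("BootstrapResult", lower = qs[1L, ], upper = qs[2L, ],
      nIter = as.numeric(nIter), alpha = alpha, seed = as.numeric(seed),
      frameTimesS = group@frameTimesS)
}

#' Per-subject bootstrap with averaged bounds (alternative construction)
#'
#' For each subject, bootstraps that subject's own trials and takes the
#' per-frame percentile interval of the resampled trial means; the group band
#' is the frame-wise average of the per-subject bounds. Provided for
#' comparison with \code{\link{bootstrapMeanCI}}; requires trial-level data.
#'
#' @param trialTraces list of trials x frames matrices, one per subject
#' @param frameTimesS shared frame grid (s)
#' @param nIter bootstrap iterations
#' @param alpha two-sided level
#' @param seed integer RNG seed
#' @return A \linkS4class{BootstrapResult}.
#' @export
bootstrapSubjectCI <- function(trialTraces, frameTimesS, nIter = 5000L,
                               alpha = 0.001, seed = 1L) {
  if (length(trialTraces) < 2L) stop("requires >= 2 subjects")
  set.seed(seed)
  bounds <- lapply(trialTraces, function(M) {
    M <- as.matrix(M)
    k <- nrow(M)
    draws <- matrix(sample.int(k, k * nIter, replace = TRUE), nrow = nIter)
    W <- matrix(0L, nIter, k)
    for (j in seq_len(k)) W[, j] <- rowSums(draws == j)
    boot <- (W %*% M) / k
    apply(boot, 2L, quantile, probs = c(alpha / 2, 1 - alpha / 2),
          names = FALSE)
  })
  lower <- colMeans(do.call(rbind, lapply(bounds, function(b) b[1L, ])))
  upper <- colMeans(do.call(rbind, lapply(bounds, function(b) b[2L, ])))
  new("BootstrapResult", lower = lower, upper = upper,
      nIter = as.numeric(nIter), alpha = alpha, seed = as.numeric(seed),
      frameTimesS = frameTimesS)
}

#' Remove isolated significant frames
#'
#' Runs of TRUE shorter than \code{minRun} are set to FALSE; longer runs are
#' untouched. With the default \code{minRun = 2} this is exactly the
#' singleton rule: a significant frame with no significant neighbor is
#' discarded.
#'
#' @param mask logical vector
#' @param minRun minimum surviving run length
#' @return logical vector of the same length.
#' @export
singletonFilter <- function(mask, minRun = 2L) {
  stopifnot(is.logical(mask))
  if (!length(mask)) return(mask)
  r <- rle(mask)
  r$values <- r$values & r$lengths >= minRun
  inverse.rle(r)
}

.runsToWindows <- function(mask, frameTimesS) {
  if (!any(mask))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  dt <- if (length(frameTimesS) > 1L) diff(frameTimesS[1:2]) else 0
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_s = frameTimesS[starts[keep]],
             end_s = frameTimesS[ends[keep]] + dt)
}

#' Windows of significantly elevated activity
#'
#' A frame is significant when the bootstrap lower bound exceeds zero — on
#' traces z-scored to a zero baseline, the one-direction readout "elevated
#' above baseline". Singleton filtering then removes runs shorter than
#' \code{minRun}.
#'
#' @param result a \linkS4class{BootstrapResult} on z-scored traces
#' @param minRun minimum run length (frames)
#' @return A \linkS4class{SignificanceMask}.
#' @export
elevatedWindows <- function(result, minRun = 2L) {
  stopifnot(is(result, "BootstrapResult"))
  sig <- singletonFilter(result@lower > 0, minRun)
  new("SignificanceMask", significant = sig,
      windows = .runsToWindows(sig, result@frameTimesS),
      frameTimesS = result@frameTimesS,
      meta = list(test = "bootstrap", alpha = result@alpha,
                  nIter = result@nIter, minRun = minRun))
}

.permutationPvalues <- function(A, B, nIter, paired, seed, exhaustive = FALSE) {
  nA <- nrow(A); nB <- nrow(B)
  obs <- colMeans(A) - colMeans(B)
  if (paired) {
    if (nA != nB) stop("paired mode requires matched subjects")
    D <- A - B
    if (exhaustive) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), nA)))
      Tp <- (signs %*% D) / nA
      p <- colMeans(sweep(abs(Tp), 2L, .tieThreshold(obs), ">="))
      return(list(p = p, obs = obs, nIter = nrow(signs), exact = TRUE))
    }
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), nIter * nA, replace = TRUE), nrow = nIter)
    Tp <- (S %*% D) / nA
  } else {
    M <- rbind(A, B)
    n <- nA + nB
    if (exhaustive) {
      sel <- utils::combn(n, nA)
      W <- matrix(-1 / nB, ncol(sel), n)
      for (i in seq_len(ncol(sel))) W[i, sel[, i]] <- 1 / nA
      Tp <- W %*% M
      p <- colMeans(sweep(abs(Tp), 2L, .tieThreshold(obs), ">="))
      return(list(p = p, obs = obs, nIter = ncol(sel), exact = TRUE))
    }
    set.seed(seed)
    W <- matrix(-1 / nB, nIter, n)
    for (i in seq_len(nIter)) W[i, sample.int(n, nA)] <- 1 / nA
    Tp <- W %*% M
  }
  exceed <- colSums(sweep(abs(Tp), 2L, .tieThreshold(obs), ">="))
  list(p = (1 + exceed) / (1 + nIter), obs = obs, nIter = nIter,
       exact = FALSE)
}

# permutation statistics exactly tied with the observed one must count as
# exceedances; a hair of relative slack keeps the count stable under affine
# transforms of the input (floating-point rounding would otherwise flip ties)
.tieThreshold <- function(obs) abs(obs) * (1 - 1e-9)

#' Frame-wise permutation comparison of two groups
#'
#' Per frame, the statistic is the difference of group means; the null is
#' built by label permutation — reshuffling the subject-to-group assignment
#' (unpaired) or randomly swapping the two within-subject traces (paired).
#' Two-sided Monte-Carlo p per frame uses the +1 correction,
#' \code{p = (1 + #(|T_perm| >= |T_obs|)) / (1 + nIter)}; frames with
#' \code{p < alpha} are significant and singleton filtering is applied.
#' \code{exhaustive = TRUE} enumerates all assignments/sign patterns instead
#' (small groups only) and drops the +1 correction.
#'
#' @param groupA,groupB \linkS4class{GroupTraces} on the same frame grid; in
#'   paired mode, rows are matched subjects
#' @param nIter permutations
#' @param alpha per-frame significance level
#' @param paired within-subject comparison?
#' @param seed integer RNG seed
#' @param minRun minimum run length for singleton filtering
#' @param exhaustive enumerate the full permutation null?
#' @return A \linkS4class{SignificanceMask}; \code{meta$p} holds the
#'   per-frame p-values, \code{meta$rawSignificant} the pre-filter mask.
#' @export
permutationDifferenceMask <- function(groupA, groupB, nIter = 5000L,
                                      alpha = 0.01, paired = FALSE,
                                      seed = 1L, minRun = 2L,
                                      exhaustive = FALSE) {
  stopifnot(is(groupA, "GroupTraces"), is(groupB, "GroupTraces"))
  A <- groupA@traces; B <- groupB@traces
  if (ncol(A) != ncol(B)) stop("groups must share the frame grid")
  if (nrow(A) < 2L || nrow(B) < 2L)
    stop("each group needs >= 2 subjects")
  res <- .permutationPvalues(A, B, nIter, paired, seed,
                             exhaustive = exhaustive)
  raw <- res$p < alpha
  sig <- singletonFilter(raw, minRun)
  new("SignificanceMask", significant = sig,
      windows = .runsToWindows(sig, groupA@frameTimesS),
      frameTimesS = groupA@frameTimesS,
      meta = list(test = "permutation", alpha = alpha, nIter = res$nIter,
                  paired = paired, exact = res$exact, p = res$p,
                  observed = res$obs, rawSignificant = raw, minRun = minRun,
                  comparison = paste(groupA@label, "vs", groupB@label)))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard step-up procedure (via \code{stats::p.adjust}): adjusted p-values
#' are monotone and a hypothesis is rejected when its adjusted p is at most
#' \code{q}. Used to gate post hoc comparisons.
#'
#' @param p numeric p-values in [0, 1]
#' @param q FDR level
#' @return list with \code{adjusted} and logical \code{reject}.
#' @export
bhFdr <- function(p, q = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Jaccard overlap between two frame masks
#'
#' Intersection over union of two logical masks; 1 when both are empty.
#' Convenience for recovery analyses against simulation ground truth.
#'
#' @param a,b logical vectors of equal length
#' @return numeric in [0, 1].
#' @export
maskJaccard <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}
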