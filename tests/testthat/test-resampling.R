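ftGrid <- seq(0, 10, by = 1 / 16)

test_that("degenerate groups collapse the bootstrap band", {
  z <- GroupTraces(matrix(0, 5, 30), seq_len(30))
  b0 <- bootstrapMeanCI(z, nIter = 500, alpha = 0.05, seed = 1)
  expect_true(all(slot(b0, "lower") == 0) && all(slot(b0, "upper") == 0))
  cc <- GroupTraces(matrix(2.5, 5, 30), seq_len(30))
  bc <- bootstrapMeanCI(cc, nIter = 500, alpha = 0.05, seed = 1)
  expect_true(all(slot(bc, "lower") == 2.5) && all(slot(bc, "upper") == 2.5))
  expect_error(bootstrapMeanCI(GroupTraces(matrix(0, 1, 30), seq_len(30)),
                               nIter = 500, seed = 1), ">= 2 subjects")
  expect_error(bootstrapMeanCI(z, nIter = 50, seed = 1), "nIter")
  expect_error(bootstrapMeanCI(z, nIter = 500, alpha = 0.7, seed = 1),
               "alpha")
})

test_that("bootstrap bands are reproducible and nested across alpha", {
  set.seed(3)
  g <- GroupTraces(matrix(rnorm(6 * 40, 1, 0.3), 6), seq_len(40))
  b1 <- bootstrapMeanCI(g, nIter = 2000, alpha = 0.01, seed = 5)
  b2 <- bootstrapMeanCI(g, nIter = 2000, alpha = 0.01, seed = 5)
  expect_identical(slot(b1, "lower"), slot(b2, "lower"))
  wide <- bootstrapMeanCI(g, nIter = 2000, alpha = 0.001, seed = 5)
  narrow <- bootstrapMeanCI(g, nIter = 2000, alpha = 0.05, seed = 5)
  expect_true(all(slot(wide, "upper") - slot(wide, "lower") >=
                    slot(narrow, "upper") - slot(narrow, "lower") - 1e-12))
})

test_that("percentile bootstrap coverage matches the small-n analysis", {
  # the percentile interval at n subjects behaves like xbar +/- z * s_n/sqrt(n)
  # with the divisor-n SD, so its true coverage at nominal 95% and n = 6 is
  # P(|t_5| <= qnorm(.975) * sqrt((n-1)/n)) ~= 0.866 -- anti-conservative, as
  # expected for a small-n percentile bootstrap
  nSub <- 6
  target <- 2 * stats::pt(stats::qnorm(0.975) * sqrt((nSub - 1) / nSub),
                          df = nSub - 1) - 1
  set.seed(4)
  nRep <- 500
  covered <- replicate(nRep, {
    g <- GroupTraces(matrix(rnorm(nSub * 10, mean = 1, sd = 0.3), nSub),
                     seq_len(10))
    b <- bootstrapMeanCI(g, nIter = 1000, alpha = 0.05,
                         seed = sample.int(1e6, 1))
    mean(slot(b, "lower") <= 1 & 1 <= slot(b, "upper"))
  })
  expect_lt(abs(mean(covered) - target), 0.04)
})

test_that("singleton filtering implements the neighbor rule", {
  expect_identical(singletonFilter(c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_identical(singletonFilter(rep(FALSE, 5)), rep(FALSE, 5))
  expect_identical(singletonFilter(rep(TRUE, 5)), rep(TRUE, 5))
  expect_identical(singletonFilter(c(TRUE, FALSE, TRUE, TRUE, TRUE), 3),
                   c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(singletonFilter(logical(0)), logical(0))
})

test_that("elevated windows read the lower bound against the zero baseline", {
  nF <- 100
  lower <- rep(-0.5, nF); lower[31:51] <- 0.2
  lower[80] <- 0.3                       # singleton
  b <- new("BootstrapResult", lower = lower, upper = lower + 1,
           nIter = 5000, alpha = 0.001, seed = 1,
           frameTimesS = seq_len(nF) / 16)
  m <- elevatedWindows(b)
  expect_identical(which(significantFrames(m)), 31:51)
  w <- significanceWindows(m)
  expect_identical(nrow(w), 1L)
  expect_equal(w$start_s, 31 / 16)
  expect_equal(w$end_s, 52 / 16)
})

test_that("identical groups produce no significant permutation frames", {
  set.seed(8)
  tr <- matrix(rnorm(6 * 50), 6)
  a <- GroupTraces(tr, seq_len(50), "A")
  b <- GroupTraces(tr, seq_len(50), "B")
  m <- permutationDifferenceMask(a, b, nIter = 500, seed = 2)
  expect_false(any(significantFrames(m)))
  expect_true(all(slot(m, "meta")$p == 1))
})

test_that("permutation p-values are invariant to common affine transforms", {
  set.seed(9)
  A <- matrix(rnorm(6 * 30), 6); B <- matrix(rnorm(6 * 30, 0.5), 6)
  m1 <- permutationDifferenceMask(GroupTraces(A, 1:30), GroupTraces(B, 1:30),
                                  nIter = 1000, seed = 7)
  m2 <- permutationDifferenceMask(GroupTraces(2 * A + 3, 1:30),
                                  GroupTraces(2 * B + 3, 1:30),
                                  nIter = 1000, seed = 7)
  expect_equal(slot(m1, "meta")$p, slot(m2, "meta")$p, tolerance = 1e-12)
})

test_that("Monte-Carlo p matches exhaustive enumeration on small groups", {
  set.seed(10)
  A <- matrix(rnorm(5 * 20), 5)
  B <- matrix(rnorm(5 * 20, 0.8), 5)
  gA <- GroupTraces(A, 1:20); gB <- GroupTraces(B, 1:20)
  mc <- permutationDifferenceMask(gA, gB, nIter = 5000, seed = 11)
  ex <- permutationDifferenceMask(gA, gB, exhaustive = TRUE)
  expect_true(slot(ex, "meta")$exact)
  expect_equal(slot(ex, "meta")$nIter, choose(10, 5))
  expect_lt(max(abs(slot(mc, "meta")$p - slot(ex, "meta")$p)), 2 / sqrt(5000))
})

test_that("paired permutations swap within subjects", {
  set.seed(12)
  A <- matrix(rnorm(6 * 25, 1), 6); B <- matrix(rnorm(6 * 25), 6)
  m <- permutationDifferenceMask(GroupTraces(A, 1:25), GroupTraces(B, 1:25),
                                 nIter = 1000, paired = TRUE, seed = 3)
  expect_true(is.numeric(slot(m, "meta")$p))
  # exhaustive paired null on identical groups: all p = 1
  same <- GroupTraces(A, 1:25)
  mEx <- permutationDifferenceMask(same, same, paired = TRUE,
                                   exhaustive = TRUE)
  expect_true(all(slot(mEx, "meta")$p == 1))
  expect_error(permutationDifferenceMask(
    GroupTraces(A, 1:25), GroupTraces(B[1:5, ], 1:25), paired = TRUE,
    nIter = 100, seed = 1), "matched")
})

test_that("detected permutation windows recover an injected offset", {
  set.seed(13)
  nF <- 120
  hits <- replicate(20, {
    mu <- numeric(nF); mu[40:70] <- 2
    A <- matrix(rnorm(6 * nF, sd = 0.5), 6) +
      matrix(mu, 6, nF, byrow = TRUE)
    B <- matrix(rnorm(6 * nF, sd = 0.5), 6)
    m <- permutationDifferenceMask(GroupTraces(A, seq_len(nF)),
                                   GroupTraces(B, seq_len(nF)),
                                   nIter = 2000, seed = sample.int(1e6, 1))
    truth <- seq_len(nF) %in% 40:70
    maskJaccard(significantFrames(m), truth) >= 0.7
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Benjamini-Hochberg matches the hand step-up procedure", {
  r <- bhFdr(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(r$reject))
  r1 <- bhFdr(0.04, q = 0.05)
  expect_true(r1$reject)
  expect_equal(r1$adjusted, 0.04)
  r2 <- bhFdr(c(0.001, 0.9))
  expect_equal(r2$adjusted, c(0.002, 0.9))
  # independent step-up oracle on a random vector
  set.seed(14)
  p <- runif(50)^2
  r3 <- bhFdr(p, q = 0.1)
  o <- order(p)
  padjOracle <- numeric(50)
  cummin_rev <- rev(cummin(rev(sort(p) * 50 / seq_len(50))))
  padjOracle[o] <- pmin(1, cummin_rev)
  expect_equal(r3$adjusted, padjOracle)
  expect_error(bhFdr(numeric(0)), "empty")
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("the per-subject averaged-bounds bootstrap runs and brackets 0", {
  set.seed(15)
  trialTraces <- lapply(1:4, function(i)
    matrix(rnorm(20 * 30), 20))
  b <- bootstrapSubjectCI(trialTraces, seq_len(30), nIter = 500,
                          alpha = 0.05, seed = 2)
  expect_true(all(slot(b, "lower") <= slot(b, "upper")))
  expect_gt(mean(slot(b, "lower") < 0 & slot(b, "upper") > 0), 0.8)
})
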