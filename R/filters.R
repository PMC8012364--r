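# Zero-phase FIR helpers shared by the simulator and the preprocessing chain.
# Kernels come from signal::fir1 (Hamming-windowed sinc) and are renormalized
# to unit DC gain so constant traces pass through exactly; application is a
# single centered convolution (symmetric kernel => zero phase) with
# edge-replication padding, computed via FFT.

.firKernel <- function(fcNorm, nTaps) {
  nTaps <- max(5L, as.integer(nTaps))
  if (nTaps %% 2L == 0L) nTaps <- nTaps + 1L
  b <- signal::fir1(nTaps - 1L, fcNorm)
  b / sum(b)
}

# FFT convolution at a 2-3-5-smooth length (arbitrary trace lengths can have
# large prime factors, for which the mixed-radix FFT is quadratic)
.fftConvValid <- function(x, b) {
  n <- length(x); m <- length(b)
  L <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
  y <- Re(stats::fft(stats::fft(c(x, numeric(L - n))) *
                       stats::fft(c(b, numeric(L - m))), inverse = TRUE)) / L
  y[m:n]
}

.zeroPhaseFir <- function(x, b) {
  n <- length(x)
  half <- (length(b) - 1L) %/% 2L
  if (half == 0L) return(x * sum(b))
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  .fftConvValid(xp, b)
}

.firLowpassFilter <- function(x, cutoffHz, fsHz, nTaps = NULL) {
  fcNorm <- cutoffHz / (fsHz / 2)
  if (fcNorm >= 1) stop("cutoff must be below the Nyquist frequency")
  if (is.null(nTaps)) nTaps <- ceiling(13.2 / fcNorm)
  nTaps <- min(nTaps, 2L * length(x) - 1L)
  .zeroPhaseFir(x, .firKernel(fcNorm, nTaps))
}

# Spectral baseline removal: mirror-extend (continuity at the edges), FFT,
# zero everything at or below cutoffHz with a raised-cosine transition up to
# 2*cutoffHz, invert, keep the first half. DC is removed exactly.
.spectralDetrend <- function(x, cutoffHz, fsHz) {
  n <- length(x)
  xe <- c(x, rev(x))
  # pad the even extension to a 2-3-5-smooth length by continuing its own
  # period, keeping the junction continuous and the FFT fast
  L <- stats::nextn(2L * n, c(2L, 3L, 5L))
  if (L > 2L * n) xe <- c(xe, xe[seq_len(L - 2L * n)])
  m <- length(xe)
  k <- seq_len(m) - 1L
  freq <- pmin(k, m - k) * fsHz / m
  gain <- rep(1, m)
  gain[freq <= cutoffHz] <- 0
  trans <- freq > cutoffHz & freq < 2 * cutoffHz
  gain[trans] <- 0.5 * (1 - cos(pi * (freq[trans] - cutoffHz) / cutoffHz))
  y <- Re(stats::fft(stats::fft(xe) * gain, inverse = TRUE)) / m
  y[seq_len(n)]
}
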