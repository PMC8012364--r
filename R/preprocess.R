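#' Fit the isosbestic channel to the signal channel
#'
#' Least-squares fit of the 405 nm (calcium-independent) channel to the
#' 470 nm channel over the whole session: \code{fitted = a * sig405 + b}
#' minimizing squared error against \code{sig470}. Because motion and
#' bleaching enter both channels multiplicatively, the fitted control carries
#' the shared artifact structure scaled into 470-channel units, ready for
#' division. A robust (Huber) fit is available for sessions with large
#' transient duty cycles.
#'
#' @param raw a \linkS4class{RawPhotometryRecording}
#' @param robust logical: use an M-estimator (\code{MASS::rlm}) instead of OLS
#' @return list with \code{fitted} (numeric trace) and \code{coefficients}
#'   (named c(slope, intercept)).
#' @export
fitIsosbestic <- function(raw, robust = FALSE) {
  stopifnot(is(raw, "RawPhotometryRecording"))
  x <- raw@sig405; y <- raw@sig470
  if (stats::sd(x) == 0) stop("degenerate control channel (constant 405 nm)")
  if (robust) {
    fit <- MASS::rlm(y ~ x, maxit = 50)
  } else {
    fit <- stats::lm.fit(cbind(1, x), y)
  }
  cf <- coef(fit)
  slope <- unname(cf[2L]); intercept <- unname(cf[1L])
  list(fitted = slope * x + intercept,
       coefficients = c(slope = slope, intercept = intercept))
}

#' Compute the raw delta-F/F trace from a fitted control
#'
#' \code{dff = (sig470 - fitted) / fitted} per sample, so that a null signal
#' (470 fully explained by the shared-artifact control) maps to exactly zero,
#' matching the zero-baseline convention of the downstream z-scoring.
#'
#' @param raw a \linkS4class{RawPhotometryRecording}
#' @param fitted the fitted control trace from \code{\link{fitIsosbestic}}
#'   (or the list it returns)
#' @return A \linkS4class{ProcessedTrace} at the raw sampling rate.
#' @export
computeDff <- function(raw, fitted) {
  stopifnot(is(raw, "RawPhotometryRecording"))
  cf <- NULL
  if (is.list(fitted)) {
    cf <- fitted$coefficients
    fitted <- fitted$fitted
  }
  if (length(fitted) != length(raw@sig470))
    stop("fitted control length must match the recording")
  bad <- which(fitted <= 0)
  if (length(bad))
    stop("non-positive fitted control at sample indices: ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L))
  ProcessedTrace((raw@sig470 - fitted) / fitted, raw@fsHz, raw@t0S,
                 provenance = list(dff = list(coefficients = cf)))
}

#' Smooth and detrend a delta-F/F trace
#'
#' Two-stage cleanup: (1) zero-phase FIR lowpass at \code{lowpassHz} removes
#' high-frequency noise without biasing event latencies; (2) a spectral
#' baseline estimate (mirror-padded FFT) removes DC and components below
#' \code{detrendHz}, i.e. residual slow drift that survives the isosbestic
#' division. Components between \code{detrendHz} and the lowpass cutoff — the
#' band task transients live in — pass essentially unattenuated.
#'
#' @param trace a \linkS4class{ProcessedTrace}
#' @param lowpassHz smoothing cutoff (Hz)
#' @param detrendHz drift-removal cutoff (Hz); 0 skips detrending
#' @return A \linkS4class{ProcessedTrace} at the same rate.
#' @export
filterDetrend <- function(trace, lowpassHz = 1, detrendHz = 0.005) {
  stopifnot(is(trace, "ProcessedTrace"))
  fs <- trace@fsHz
  if (lowpassHz >= fs / 2 || detrendHz >= fs / 2)
    stop("filter cutoffs must be below the Nyquist frequency")
  x <- .firLowpassFilter(trace@dff, lowpassHz, fs)
  if (detrendHz > 0) x <- .spectralDetrend(x, detrendHz, fs)
  ProcessedTrace(x, fs, trace@t0S,
                 provenance = c(trace@provenance,
                                list(filter = list(lowpassHz = lowpassHz,
                                                   detrendHz = detrendHz))))
}

#' Decimate a trace with anti-alias filtering
#'
#' Applies a zero-phase FIR anti-alias lowpass at 80% of the new Nyquist
#' frequency, then keeps every \code{factor}-th sample. \code{factor = 1} is
#' the identity. The default factor of 64 takes a ~1017 Hz acquisition down
#' to ~15.9 Hz, the frame rate the trial-level analyses work at.
#'
#' @param trace a \linkS4class{ProcessedTrace}
#' @param factor integer decimation factor
#' @return A \linkS4class{ProcessedTrace} with \code{fsHz = fs/factor} and
#'   \code{floor(n/factor)} frames.
#' @export
decimateTrace <- function(trace, factor = 64L) {
  stopifnot(is(trace, "ProcessedTrace"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  n <- length(trace@dff)
  if (factor > n) stop("decimation factor exceeds trace length")
  x <- trace@dff
  if (factor > 1L) {
    b <- .firKernel(0.8 / factor, 33L * factor)
    x <- .zeroPhaseFir(x, b)
  }
  keep <- seq.int(1L, by = factor, length.out = n %/% factor)
  ProcessedTrace(x[keep], trace@fsHz / factor, trace@t0S,
                 provenance = c(trace@provenance,
                                list(decimate = list(factor = factor))))
}

#' Full preprocessing chain: raw recording to final delta-F/F
#'
#' Isosbestic fit and division, smoothing + spectral detrend, then decimation.
#' Parameters default to the standard pipeline settings (1 Hz smoothing,
#' 0.005 Hz drift cutoff, decimation by 64).
#'
#' @param raw a \linkS4class{RawPhotometryRecording}
#' @param lowpassHz smoothing cutoff (Hz)
#' @param detrendHz drift-removal cutoff (Hz)
#' @param decimation integer decimation factor
#' @param robust robust isosbestic fit?
#' @return A \linkS4class{ProcessedTrace}: the final delta-F/F.
#' @export
preprocessRecording <- function(raw, lowpassHz = 1, detrendHz = 0.005,
                                decimation = 64L, robust = FALSE) {
  fit <- fitIsosbestic(raw, robust = robust)
  dff <- computeDff(raw, fit)
  dff <- filterDetrend(dff, lowpassHz = lowpassHz, detrendHz = detrendHz)
  decimateTrace(dff, decimation)
}
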