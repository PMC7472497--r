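# Spectral estimation for 3 s windows: single-segment Hann-tapered
# periodogram (384 samples at 128 Hz are too short for multi-segment
# averaging), trapezoidal band integration, and the freezing index.

#' Hann-tapered periodogram of one window
#'
#' One-sided power spectral density of a single window, normalized so that
#' the integral over frequency equals the signal's mean power (Parseval,
#' within taper normalization).
#'
#' @param x numeric vector of samples (one axis of one window)
#' @param fs sampling rate, Hz
#' @param expectedLength if non-NULL, \code{length(x)} must equal it
#' @return list with \code{freq} (Hz, 0..fs/2) and \code{psd} (power/Hz)
#' @export
psdEstimate <- function(x, fs, expectedLength = NULL) {
  n <- length(x)
  if (!is.null(expectedLength) && n != expectedLength)
    stop(sprintf("expected %d samples, got %d", expectedLength, n))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))  # Hann
  X <- stats::fft(x * w)
  nf <- floor(n / 2) + 1L
  scale <- 1 / (fs * sum(w^2))
  psd <- (Mod(X[1:nf])^2) * scale
  # one-sided: double everything except DC (and Nyquist when n is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / n, psd = psd * dbl)
}

#' Integrated power in a frequency band
#'
#' Trapezoidal integral of the PSD over the grid points falling inside
#' \code{band} (edges inclusive).
#'
#' @param spec list with \code{freq} and \code{psd} (from
#'   \code{\link{psdEstimate}})
#' @param band numeric length-2, c(lo, hi) in Hz
#' @export
bandPower <- function(spec, band) {
  sel <- spec$freq >= band[1] - 1e-12 & spec$freq <= band[2] + 1e-12
  if (sum(sel) < 2L) return(0)
  pracma::trapz(spec$freq[sel], spec$psd[sel])
}

#' Frequency of the PSD maximum inside a band
#'
#' A zero-power band returns the band's lower edge by convention.
#' @inheritParams bandPower
#' @export
peakFrequency <- function(spec, band) {
  sel <- which(spec$freq >= band[1] - 1e-12 & spec$freq <= band[2] + 1e-12)
  if (!length(sel) || all(spec$psd[sel] <= 0)) return(band[1])
  spec$freq[sel[which.max(spec$psd[sel])]]
}

#' Shannon spectral entropy inside a band
#'
#' Entropy (nats) of the PSD normalized to sum one within the band; a
#' zero-power band has entropy 0.
#' @inheritParams bandPower
#' @export
spectralEntropy <- function(spec, band) {
  sel <- spec$freq >= band[1] - 1e-12 & spec$freq <= band[2] + 1e-12
  p <- spec$psd[sel]
  tot <- sum(p)
  if (tot <= 0) return(0)
  p <- p[p > 0] / tot
  -sum(p * log(p))
}

#' Sample skewness of the PSD values inside a band
#'
#' Zero-variance (or zero-power) bands return 0 by convention.
#' @inheritParams bandPower
#' @export
spectralSkewness <- function(spec, band) {
  sel <- spec$freq >= band[1] - 1e-12 & spec$freq <= band[2] + 1e-12
  sampleSkewness(spec$psd[sel])
}

# skewness with the 0 convention for degenerate input
sampleSkewness <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean(((x - m) / s)^3)
}

#' Freezing index of one leg window
#'
#' Ratio of the integrated PSD in the freeze band (3-8 Hz) to that in the
#' walk band (0.5-3 Hz); 0/0 is defined as 0.
#'
#' @param x one 3 s axis window (anterior-posterior leg acceleration in the
#'   canonical use)
#' @param fs sampling rate, Hz
#' @export
freezingIndexSignal <- function(x, fs) {
  spec <- psdEstimate(x, fs)
  fz <- bandPower(spec, FREEZE_BAND)
  wk <- bandPower(spec, WALK_BAND)
  if (wk <= 0) {
    if (fz <= 0) 0 else Inf
  } else fz / wk
}

#' Freezing index of a window, maximum over the two legs
#'
#' Computed per leg on the anterior-posterior acceleration axis of a 3 s
#' window; the maximum of the two per-leg values is returned.
#'
#' @param trial a (filtered) \linkS4class{TrialRecording}
#' @param startS window start time (s)
#' @param lengthS window length (s)
#' @export
freezingIndex <- function(trial, startS, lengthS = WINDOW_LENGTH_S) {
  fs <- samplingRate(trial)
  fi <- vapply(LEG_SITES, function(site) {
    x <- windowSamples(axisSignal(trial, site, "accel", "AP"), startS, fs,
                       lengthS)
    freezingIndexSignal(x, fs)
  }, numeric(1))
  max(fi)
}
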