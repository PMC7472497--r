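# Preprocessing: zero-phase Butterworth low-pass, annotation cleaning
# (merge < 1 s gaps then drop < 1 s episodes), and window extraction with
# the asymmetric FOG / non-FOG training steps.

#' Zero-phase low-pass filter a trial
#'
#' Applies a second-order Butterworth low-pass (default cutoff 15 Hz)
#' forward-backward (\code{signal::filtfilt}) to every accelerometer and
#' gyroscope axis of every site, so the effective attenuation is the squared
#' magnitude response and no phase shift is introduced that could move
#' episode boundaries.
#'
#' @param trial a \linkS4class{TrialRecording}
#' @param cutoffHz low-pass cutoff, Hz
#' @param order filter order (of the one-way design)
#' @return a filtered \linkS4class{TrialRecording} of identical dimensions
#' @export
lowpassTrial <- function(trial, cutoffHz = 15, order = 2L) {
  fs <- samplingRate(trial)
  if (fs <= 2 * cutoffHz)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz cutoff", fs,
                 cutoffHz))
  bf <- signal::butter(order, cutoffHz / (fs / 2), type = "low")
  # odd-reflection padding suppresses the forward-backward startup
  # transients (filtfilt alone assumes zero initial conditions)
  pad <- function(x) {
    n <- length(x)
    p <- min(n - 1L, as.integer(ceiling(10 * fs / cutoffHz)))
    c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  }
  zerophase <- function(x) {
    n <- length(x)
    p <- (length(pad(x)) - n) / 2
    signal::filtfilt(bf, pad(x))[(p + 1L):(p + n)]
  }
  recs <- lapply(trial@recordings, function(rec) {
    filt <- function(m) {
      out <- t(apply(m, 1L, zerophase))
      rownames(out) <- rownames(m)
      out
    }
    SensorRecording(rec@site, filt(rec@accel), filt(rec@gyro), rec@fs)
  })
  TrialRecording(recs, subjectId = trial@subjectId,
                 medState = trial@medState, difficulty = trial@difficulty)
}

#' Clean a FOG annotation track
#'
#' Merges episodes separated by less than \code{mergeGapS} seconds, then
#' drops episodes shorter than \code{minDurationS} seconds (merge first, so
#' fragmented real episodes are preserved). Idempotent.
#'
#' @param track an \linkS4class{AnnotationTrack}
#' @param mergeGapS gaps strictly shorter than this are merged (s)
#' @param minDurationS episodes strictly shorter than this are dropped (s)
#' @return a cleaned \linkS4class{AnnotationTrack}
#' @export
cleanAnnotations <- function(track, mergeGapS = 1.0, minDurationS = 1.0) {
  iv <- intervals(track)
  if (nrow(iv) == 0L) return(track)
  merged <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    k <- nrow(merged)
    if (iv[i, 1] - merged[k, 2] < mergeGapS) {
      merged[k, 2] <- max(merged[k, 2], iv[i, 2])
    } else {
      merged <- rbind(merged, iv[i, , drop = FALSE])
    }
  }
  keep <- (merged[, 2] - merged[, 1]) >= minDurationS
  AnnotationTrack(merged[keep, , drop = FALSE])
}

# Total overlap (s) of [start, start+len) with a set of disjoint intervals.
intervalOverlap <- function(start, len, iv) {
  if (nrow(iv) == 0L) return(rep(0, length(start)))
  end <- start + len
  vapply(seq_along(start), function(i) {
    lo <- pmax(start[i], iv[, 1]); hi <- pmin(end[i], iv[, 2])
    sum(pmax(0, hi - lo))
  }, numeric(1))
}

windowGrid <- function(durationS, stepS, lengthS) {
  if (durationS < lengthS - 1e-9) return(numeric(0))
  nSteps <- floor((durationS - lengthS) / stepS + 1e-9)
  (0:nSteps) * stepS
}

#' Cut labeled fixed-length windows from a trial
#'
#' Three-second windows labeled FOG when they overlap the (cleaned)
#' annotations by at least 1.5 s. Training windows use a 0.6 s step (80%
#' overlap) for FOG windows and a 1.5 s step (50% overlap) for non-FOG
#' windows: both grids are anchored at t = 0, each candidate is labeled by
#' the overlap rule, and a window is kept when its label matches its grid
#' (duplicate starts kept once). Test windows lie on the uniform 1.5 s grid.
#' Windows extending past the trial end are discarded.
#'
#' @param trial a \linkS4class{TrialRecording} (typically filtered)
#' @param track a cleaned \linkS4class{AnnotationTrack}
#' @param role "train" or "test"
#' @param lengthS window length in seconds
#' @return a \linkS4class{WindowSet}
#' @export
makeWindows <- function(trial, track, role = c("train", "test"),
                        lengthS = WINDOW_LENGTH_S) {
  role <- match.arg(role)
  dur <- durationS(trial)
  iv <- intervals(track)
  if (dur < lengthS - 1e-9) {
    warning(sprintf("trial shorter than %g s: empty window set", lengthS))
    starts <- numeric(0)
  } else if (role == "test") {
    starts <- windowGrid(dur, STEP_NONFOG_S, lengthS)
  } else {
    fogGrid <- windowGrid(dur, STEP_FOG_S, lengthS)
    nonGrid <- windowGrid(dur, STEP_NONFOG_S, lengthS)
    fogKeep <- fogGrid[intervalOverlap(fogGrid, lengthS, iv) >=
                         FOG_OVERLAP_MIN_S - 1e-12]
    nonKeep <- nonGrid[intervalOverlap(nonGrid, lengthS, iv) <
                         FOG_OVERLAP_MIN_S - 1e-12]
    starts <- sort(unique(c(fogKeep, nonKeep)))
  }
  ov <- intervalOverlap(starts, lengthS, iv)
  w <- data.frame(start_s = starts,
                  label = ifelse(ov >= FOG_OVERLAP_MIN_S - 1e-12,
                                 "FOG", "nonFOG"),
                  fog_overlap_s = ov,
                  stringsAsFactors = FALSE)
  new("WindowSet", windows = w, role = role, lengthS = lengthS,
      trialDuration = dur)
}

#' Extract the sample block of one window from one axis signal
#'
#' @param x numeric sample vector
#' @param startS window start (s)
#' @param fs sampling rate (Hz)
#' @param lengthS window length (s)
#' @keywords internal
windowSamples <- function(x, startS, fs, lengthS = WINDOW_LENGTH_S) {
  i0 <- round(startS * fs)
  n <- round(lengthS * fs)
  if (i0 + n > length(x)) stop("window extends past the signal end")
  x[(i0 + 1L):(i0 + n)]
}
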