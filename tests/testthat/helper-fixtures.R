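# Fixtures built in code: tiny trials with controlled per-axis content.

FS <- 128

# a trial whose axis signals are all zero except those given in `signals`,
# a named list like list(left_ankle.accel.AP = <vector>)
trialFromSignals <- function(n = 384, signals = list(), fs = FS,
                             subject = "t1") {
  recs <- lapply(c("lower_back", "left_ankle", "right_ankle"), function(site) {
    accel <- matrix(0, 3, n, dimnames = list(c("V", "AP", "ML"), NULL))
    gyro <- accel
    for (key in names(signals)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (parts[1] != site) next
      if (parts[2] == "accel") accel[parts[3], ] <- signals[[key]]
      else gyro[parts[3], ] <- signals[[key]]
    }
    SensorRecording(site, accel, gyro, fs)
  })
  TrialRecording(recs, subjectId = subject)
}

sine <- function(freqHz, n = 384, amp = 1, fs = FS, phase = 0) {
  amp * sin(2 * pi * freqHz * (0:(n - 1)) / fs + phase)
}

# fundamental amplitude of a sinusoid buried in x, by projection
sineAmplitude <- function(x, freqHz, fs = FS) {
  t <- (seq_along(x) - 1) / fs
  2 * sqrt(mean(x * sin(2 * pi * freqHz * t))^2 +
             mean(x * cos(2 * pi * freqHz * t))^2)
}

# brute-force per-sample FOG overlap of [start, start+len) with intervals
bruteOverlap <- function(start, len, iv, fs = FS) {
  if (nrow(iv) == 0) return(0)
  ts <- start + (0:(round(len * fs) - 1) + 0.5) / fs  # sample midpoints
  inFog <- vapply(ts, function(t)
    any(t >= iv[, 1] & t < iv[, 2]), logical(1))
  sum(inFog) / fs
}

randomTrack <- function(durationS, maxEpisodes = 6) {
  k <- sample(0:maxEpisodes, 1)
  if (k == 0) return(AnnotationTrack())
  pts <- sort(runif(2 * k, 0, durationS))
  iv <- cbind(pts[seq(1, 2 * k, 2)], pts[seq(2, 2 * k, 2)])
  iv <- iv[iv[, 2] - iv[, 1] > 1e-6, , drop = FALSE]
  AnnotationTrack(iv)
}

# small labeled feature data set with planted signal, grouped by subject
plantedFeatures <- function(nPerSubject = 30, nSubjects = 6, nNoise = 5,
                            sep = 3) {
  n <- nPerSubject * nSubjects
  labels <- rep(c("FOG", "nonFOG"), length.out = n)
  subjects <- rep(sprintf("p%d", seq_len(nSubjects)), each = nPerSubject)
  X <- cbind(signal1 = (labels == "FOG") * sep + rnorm(n),
             matrix(rnorm(n * nNoise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(nNoise)))))
  list(X = X, labels = labels, subjects = subjects)
}
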