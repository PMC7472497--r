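test_that("low-pass filter has unity DC gain and the analytic attenuation", {
  n <- 1280
  dc <- trialFromSignals(n, list(lower_back.accel.V = rep(2.5, n)))
  out <- lowpassTrial(dc)
  expect_lt(max(abs(axisSignal(out, "lower_back", "accel", "V") - 2.5)), 1e-9)

  # zero-phase 2nd-order Butterworth: |H|^2 = 1 / (1 + (f/fc)^4), valid in
  # the passband where the digital design tracks the analog response
  trial5 <- trialFromSignals(n, list(left_ankle.accel.AP = sine(5, n)))
  y5 <- axisSignal(lowpassTrial(trial5), "left_ankle", "accel", "AP")
  expect_equal(sineAmplitude(y5[200:1080], 5), 1 / (1 + (5 / 15)^4),
               tolerance = 0.02)
  trial30 <- trialFromSignals(n, list(left_ankle.accel.AP = sine(30, n)))
  y30 <- axisSignal(lowpassTrial(trial30), "left_ankle", "accel", "AP")
  expect_lte(sineAmplitude(y30[200:1080], 30), 0.10)
})

test_that("filtering rejects sampling rates at or below twice the cutoff", {
  slow <- trialFromSignals(n = 64, fs = 30)
  expect_error(lowpassTrial(slow), "30")
})

test_that("annotation cleaning merges sub-second gaps before dropping short episodes", {
  clean <- function(iv) intervals(cleanAnnotations(AnnotationTrack(iv)))
  expect_equal(clean(cbind(c(0, 2.5), c(2, 4))), cbind(0, 4),
               ignore_attr = TRUE)
  expect_equal(nrow(clean(cbind(0, 0.8))), 0)
  # merge-first order: two short fragments merge into one surviving episode
  expect_equal(clean(cbind(c(0, 1.2), c(0.6, 1.9))), cbind(0, 1.9),
               ignore_attr = TRUE)
})

test_that("annotation cleaning is idempotent and moves total time the right way", {
  set.seed(42)
  for (rep in 1:200) {
    track <- randomTrack(30)
    once <- cleanAnnotations(track)
    twice <- cleanAnnotations(once)
    expect_equal(intervals(once), intervals(twice))
    tot <- function(tr) {
      iv <- intervals(tr)
      if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0
    }
    mergedOnly <- cleanAnnotations(track, minDurationS = 0)
    expect_gte(tot(mergedOnly) + 1e-12, tot(track))    # merging never loses
    expect_lte(tot(once) - 1e-12, tot(mergedOnly))     # dropping never gains
  }
})

test_that("test windows tile the trial on the 1.5 s grid", {
  trial <- trialFromSignals(n = 10 * FS)
  ws <- makeWindows(trial, AnnotationTrack(), role = "test")
  expect_equal(windowInfo(ws)$start_s, c(0, 1.5, 3.0, 4.5, 6.0))
  expect_true(all(windowInfo(ws)$label == "nonFOG"))
})

test_that("the FOG label boundary sits at exactly 1.5 s of overlap", {
  trial <- trialFromSignals(n = 10 * FS)
  w14 <- makeWindows(trial, AnnotationTrack(cbind(0, 1.4)), role = "test")
  expect_equal(windowInfo(w14)$label[1], "nonFOG")
  w15 <- makeWindows(trial, AnnotationTrack(cbind(0, 1.5)), role = "test")
  expect_equal(windowInfo(w15)$label[1], "FOG")
  expect_equal(windowInfo(w15)$fog_overlap_s[1], 1.5)
})

test_that("training FOG windows use the 0.6 s grid", {
  trial <- trialFromSignals(n = 10 * FS)
  allFog <- AnnotationTrack(cbind(0, 10))
  ws <- makeWindows(trial, allFog, role = "train")
  w <- windowInfo(ws)
  expect_equal(nrow(w), 12)  # floor((10 - 3) / 0.6) + 1
  expect_true(all(w$label == "FOG"))
  expect_equal(w$start_s, seq(0, by = 0.6, length.out = 12))
})

test_that("trials shorter than one window give an empty set with a warning", {
  trial <- trialFromSignals(n = 2 * FS)
  expect_warning(ws <- makeWindows(trial, AnnotationTrack(), role = "test"),
                 "shorter")
  expect_equal(nrow(windowInfo(ws)), 0)
})

test_that("window FOG overlap matches a per-sample brute-force count", {
  set.seed(7)
  trial <- trialFromSignals(n = 20 * FS)
  for (rep in 1:50) {
    track <- cleanAnnotations(randomTrack(20))
    ws <- makeWindows(trial, track, role = sample(c("train", "test"), 1))
    w <- windowInfo(ws)
    if (!nrow(w)) next
    iv <- intervals(track)
    expect_lt(max(abs(w$fog_overlap_s -
                        vapply(w$start_s, bruteOverlap, numeric(1),
                               len = 3, iv = iv))), 1 / FS)
  }
})
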