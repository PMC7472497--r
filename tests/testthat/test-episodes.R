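# brute-force per-sample vote oracle for episode fusion
bruteVote <- function(starts, preds, durationS, lenS = 3, fs = 128) {
  n <- round(durationS * fs)
  fog <- integer(n); all <- integer(n)
  for (i in seq_along(starts)) {
    ix <- (round(starts[i] * fs) + 1):min(n, round((starts[i] + lenS) * fs))
    all[ix] <- all[ix] + 1
    if (preds[i] == "FOG") fog[ix] <- fog[ix] + 1
  }
  all > 0 & fog > all - fog
}

test_that("window fusion follows the per-sample majority vote with FOG ties", {
  trial <- trialFromSignals(n = 12 * FS)
  ws <- makeWindows(trial, AnnotationTrack(), role = "test")
  starts <- windowInfo(ws)$start_s

  allNon <- rep("nonFOG", length(starts))
  expect_equal(nrow(intervals(windowsToEpisodes(ws, allNon, 12))), 0)

  # three consecutive FOG windows at 0, 1.5, 3.0: FOG carries the vote up
  # to 4.5 s, where the nonFOG neighbour ties (and a tie is not a majority)
  preds <- allNon
  preds[starts %in% c(0, 1.5, 3.0)] <- "FOG"
  ep <- windowsToEpisodes(ws, preds, 12)
  expect_equal(nrow(intervals(ep)), 1)
  expect_equal(intervals(ep)[1, ], c(start_s = 0, end_s = 4.5),
               tolerance = 0.05, ignore_attr = TRUE)

  # an isolated FOG window outvoted by overlapping nonFOG neighbours
  # leaves no episode
  lone <- allNon
  lone[starts == 4.5] <- "FOG"
  expect_equal(nrow(intervals(windowsToEpisodes(ws, lone, 12))), 0)

  # random predictions agree with the brute-force vote + cleaning oracle
  set.seed(30)
  for (rep in 1:100) {
    preds <- sample(c("FOG", "nonFOG"), length(starts), replace = TRUE)
    got <- windowsToEpisodes(ws, preds, 12)
    flag <- bruteVote(starts, preds, 12)
    want <- cleanAnnotations(AnnotationTrack(
      fogkit:::runsToIntervals(flag, 128)))
    expect_equal(intervals(got), intervals(want))
  }
})

test_that("derived outcomes match their definitions and a per-sample oracle", {
  ep1 <- AnnotationTrack(cbind(10, 16))
  o <- deriveOutcomes(ep1, 60)
  expect_equal(o$percent_time_frozen, 10)
  expect_equal(o$total_time_frozen_s, 6)
  expect_equal(o$n_episodes, 1)
  o0 <- deriveOutcomes(AnnotationTrack(), 60)
  expect_equal(unlist(o0), c(percent_time_frozen = 0, total_time_frozen_s = 0,
                             n_episodes = 0))
  o2 <- deriveOutcomes(AnnotationTrack(cbind(c(0, 10), c(3, 13))), 60)
  expect_equal(o2$percent_time_frozen, 10)
  expect_equal(o2$n_episodes, 2)
  expect_error(deriveOutcomes(ep1, 0), "positive")

  set.seed(31)
  for (rep in 1:50) {
    dur <- runif(1, 10, 60)
    track <- cleanAnnotations(randomTrack(dur))
    pct <- deriveOutcomes(track, dur)$percent_time_frozen
    ts <- ((1:round(dur * 128)) - 0.5) / 128
    iv <- intervals(track)
    brute <- if (nrow(iv)) mean(vapply(ts, function(t)
      any(t >= iv[, 1] & t < iv[, 2]), logical(1))) * 100 else 0
    expect_equal(pct, brute, tolerance = 100 / (128 * dur) + 1e-9)
  }
})

test_that("window metrics implement the stated definitions and conventions", {
  pred <- c(rep("FOG", 8), rep("nonFOG", 2), rep("nonFOG", 10))
  truth <- c(rep("FOG", 10), rep("nonFOG", 10))
  m <- windowMetrics(pred, truth)
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 100)
  expect_equal(m$accuracy, 90)
  # no FOG in the truth -> sensitivity 100 by convention
  m2 <- windowMetrics(rep("FOG", 5), rep("nonFOG", 5))
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$specificity, 0)
  expect_error(windowMetrics("FOG", c("FOG", "FOG")), "length")
  # perfectly ordered scores
  m3 <- windowMetrics(truth, truth, scores = 20:1)
  expect_equal(m3$auc, 1.0)
  expect_equal(m3$oop, c(fpr = 0, tpr = 1))
})

test_that("the freezing-index detector fires on tremor and not on gait or silence", {
  n <- 10 * FS
  mk <- function(f, amp = 1) lowpassTrial(trialFromSignals(n, list(
    left_ankle.accel.AP = sine(f, n, amp = amp),
    right_ankle.accel.AP = sine(f, n, amp = amp))))
  ws <- makeWindows(mk(5), AnnotationTrack(), role = "test")
  expect_true(all(freezingIndexDetector(mk(5), ws)$label == "FOG"))
  expect_true(all(freezingIndexDetector(mk(1), ws)$label == "nonFOG"))
  zero <- lowpassTrial(trialFromSignals(n))
  d0 <- freezingIndexDetector(zero, ws)
  expect_true(all(d0$label == "nonFOG"))
  expect_true(all(d0$score == 0))
})

test_that("ground truth passed through the fusion cleaning equals direct cleaning", {
  set.seed(32)
  trial <- trialFromSignals(n = 30 * FS)
  for (rep in 1:20) {
    raw <- randomTrack(30)
    direct <- cleanAnnotations(raw)
    ws <- makeWindows(trial, direct, role = "test")
    # re-clean the already-clean truth through the episode path
    reclean <- cleanAnnotations(direct)
    expect_equal(intervals(reclean), intervals(direct))
  }
})
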