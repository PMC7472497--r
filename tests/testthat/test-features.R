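test_that("the manifest has 86 unique features containing the final 14", {
  man <- featureManifest()
  expect_equal(nrow(man), 86)
  expect_equal(anyDuplicated(man$feature_id), 0)
  final <- finalModelFeatureIds()
  expect_equal(length(final), 14)
  expect_true(all(final %in% man$feature_id))
})

test_that("PSD estimator is Parseval-consistent and concentrates sine power", {
  # zero in, zero out
  z <- psdEstimate(rep(0, 384), 128)
  expect_true(all(z$psd == 0))
  # 5 Hz sits on the grid: >= 95% of power within 4-6 Hz
  s <- psdEstimate(sine(5), 128)
  inBand <- s$freq >= 4 & s$freq <= 6
  expect_gte(sum(s$psd[inBand]) / sum(s$psd), 0.95)
  # total integrated power ~ amplitude^2/2 for a sinusoid
  expect_equal(pracma::trapz(s$freq, s$psd), 0.5, tolerance = 0.05)
  # white noise: mean PSD flat across the spectrum
  set.seed(1)
  acc <- rowMeans(vapply(1:400, function(i)
    psdEstimate(rnorm(384), 128)$psd, numeric(193)))
  mid <- acc[10:180]
  expect_lt(stats::sd(mid) / mean(mid), 0.15)
})

test_that("freezing index separates tremor from gait and takes the leg maximum", {
  n <- 384
  mk <- function(sigs) lowpassTrial(trialFromSignals(n, sigs))
  # both legs silent -> 0/0 -> 0
  expect_equal(freezingIndex(mk(list()), 0), 0)
  # leg A tremor at 5 Hz, leg B gait at 1 Hz: max over legs is A's
  trial <- mk(list(left_ankle.accel.AP = sine(5, n),
                   right_ankle.accel.AP = sine(1, n)))
  fiA <- freezingIndexSignal(
    windowSamples(axisSignal(trial, "left_ankle", "accel", "AP"), 0, 128), 128)
  fiB <- freezingIndexSignal(
    windowSamples(axisSignal(trial, "right_ankle", "accel", "AP"), 0, 128), 128)
  expect_gt(fiA, 2.5)
  expect_lt(fiB, 0.1)
  expect_equal(freezingIndex(trial, 0), fiA)
  # gait on both legs stays far below threshold
  walk <- mk(list(left_ankle.accel.AP = sine(1, n),
                  right_ankle.accel.AP = sine(1, n)))
  expect_lt(freezingIndex(walk, 0), 0.1)
})

test_that("an all-zero window triggers every degenerate convention", {
  trial <- trialFromSignals(384)
  ws <- makeWindows(trial, AnnotationTrack(), role = "test")
  fm <- computeFeatures(trial, ws)
  v <- featureValues(fm)[1, ]
  expect_equal(unname(v["legsgyr_rms3d"]), 0)
  expect_equal(unname(v["ratio_legsgyr_backacc_rms"]), 0)     # 0/0 -> 0
  expect_equal(unname(v["legsgyr_ML_interleg_corr"]), 0)      # zero variance
  expect_equal(unname(v["legsgyr_ML_meanmag_ratio"]), 0)
  expect_equal(unname(v["backgyr_ent_walk"]), 0)
  expect_equal(unname(v["legsacc_fi"]), 0)
  expect_equal(unname(v["legsacc_pf_freeze"]), 3)             # band lower edge
  expect_equal(unname(v["legsgyr_pf_walk"]), 0.5)
  expect_true(all(is.finite(v)))
})

test_that("trembling raises the back-to-legs ratio and freezing index above walking", {
  n <- 384
  tremble <- trialFromSignals(n, list(
    left_ankle.accel.AP = sine(5, n), right_ankle.accel.AP = sine(5, n),
    left_ankle.gyro.V = sine(5, n, amp = 1),
    right_ankle.gyro.V = sine(5, n, amp = 1),
    lower_back.accel.AP = sine(5, n, amp = 0.05)))
  walk <- trialFromSignals(n, list(
    left_ankle.accel.AP = sine(1, n), right_ankle.accel.AP = sine(1, n),
    left_ankle.gyro.V = sine(1, n, amp = 1),
    right_ankle.gyro.V = sine(1, n, amp = 1),
    lower_back.accel.AP = sine(1, n, amp = 0.8)))
  ws <- function(tr) makeWindows(tr, AnnotationTrack(), role = "test")
  vT <- featureValues(computeFeatures(tremble, ws(tremble)))[1, ]
  vW <- featureValues(computeFeatures(walk, ws(walk)))[1, ]
  expect_gt(vT["ratio_legsgyr_backacc_rms"], vW["ratio_legsgyr_backacc_rms"])
  expect_gt(vT["legsacc_fi"], vW["legsacc_fi"])
})

test_that("scale-invariant features ignore gain; amplitude features scale linearly", {
  set.seed(5)
  n <- 384
  randSigs <- function() {
    keys <- as.vector(outer(
      c("lower_back", "left_ankle", "right_ankle"),
      as.vector(outer(c("accel", "gyro"), c("V", "AP", "ML"), paste,
                      sep = ".")), paste, sep = "."))
    sigs <- lapply(keys, function(k) rnorm(n) + sine(runif(1, 1, 6), n))
    names(sigs) <- keys
    sigs
  }
  invariant <- c("legsgyr_ML_interleg_corr", "legsgyr_ML_meanmag_ratio",
                 "backacc_ent_walk", "backgyr_ent_freeze", "legsacc_fi",
                 "legsacc_pf_freeze", "legsgyr_pf_walk",
                 "ratio_legsgyr_backacc_rms", "ratio_legsgyr_backgyr_rms")
  linear <- c("backacc_V_sd", "legsgyr_ML_rcs", "legsacc_rms3d",
              "backgyr_AP_mean")
  for (rep in 1:5) {
    sigs <- randSigs()
    c0 <- runif(1, 2, 5)
    scaled <- lapply(sigs, function(x) c0 * x)
    tr1 <- trialFromSignals(n, sigs)
    tr2 <- trialFromSignals(n, scaled)
    wsets <- makeWindows(tr1, AnnotationTrack(), role = "test")
    v1 <- featureValues(computeFeatures(tr1, wsets))[1, ]
    v2 <- featureValues(computeFeatures(tr2, wsets))[1, ]
    expect_equal(v2[invariant], v1[invariant], tolerance = 1e-8)
    expect_equal(v2[linear], c0 * v1[linear], tolerance = 1e-8)
  }
})

test_that("swapping the leg sensors leaves leg-aggregated features unchanged", {
  set.seed(6)
  n <- 384
  sigsL <- list(left_ankle.accel.AP = rnorm(n), left_ankle.gyro.ML = rnorm(n),
                left_ankle.accel.V = sine(4, n),
                right_ankle.accel.AP = sine(2, n),
                right_ankle.gyro.ML = rnorm(n) * 2)
  swap <- function(key) {
    k <- sub("left_ankle", "TMP", key)
    k <- sub("right_ankle", "left_ankle", k)
    sub("TMP", "right_ankle", k)
  }
  sigsR <- sigsL
  names(sigsR) <- vapply(names(sigsL), swap, character(1))
  tr1 <- trialFromSignals(n, sigsL)
  tr2 <- trialFromSignals(n, sigsR)
  ws <- makeWindows(tr1, AnnotationTrack(), role = "test")
  v1 <- featureValues(computeFeatures(tr1, ws))[1, ]
  v2 <- featureValues(computeFeatures(tr2, ws))[1, ]
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("time-domain features match direct formulas on the raw samples", {
  set.seed(8)
  n <- 384
  x <- rnorm(n); y <- rnorm(n); b <- rnorm(n)
  trial <- trialFromSignals(n, list(left_ankle.gyro.ML = x,
                                    right_ankle.gyro.ML = y,
                                    lower_back.gyro.ML = b))
  ws <- makeWindows(trial, AnnotationTrack(), role = "test")
  v <- featureValues(computeFeatures(trial, ws))[1, ]
  expect_equal(unname(v["backgyr_ML_mean"]), mean(b), tolerance = 1e-8)
  expect_equal(unname(v["backgyr_ML_sd"]), sd(b), tolerance = 1e-8)
  expect_equal(unname(v["backgyr_ML_rcs"]),
               max(cumsum(b)) - min(cumsum(b)), tolerance = 1e-8)
  skew <- function(z) mean(((z - mean(z)) / sqrt(mean((z - mean(z))^2)))^3)
  expect_equal(unname(v["backgyr_ML_skew"]), skew(b), tolerance = 1e-8)
  expect_equal(unname(v["legsgyr_ML_interleg_corr"]), cor(x, y),
               tolerance = 1e-8)
  expect_equal(unname(v["legsgyr_ML_meanmag_ratio"]),
               min(abs(mean(x)), abs(mean(y))) /
                 max(abs(mean(x)), abs(mean(y))), tolerance = 1e-8)
  expect_equal(unname(v["legsgyr_ML_rcs"]),  # min over legs per the manifest
               min(max(cumsum(x)) - min(cumsum(x)),
                   max(cumsum(y)) - min(cumsum(y))), tolerance = 1e-8)
})
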