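test_that("a zero episode rate gives an empty track; same seed, same trial", {
  cfg <- simConfig(durationS = 20, fogTimeFraction = 0)
  st <- simulateTrial(cfg, seed = 1)
  expect_equal(nrow(intervals(st$annotations)), 0)

  cfg2 <- simConfig(durationS = 20)
  a <- simulateTrial(cfg2, seed = 5)
  b <- simulateTrial(cfg2, seed = 5)
  expect_identical(getRecording(a$trial, "left_ankle")@accel,
                   getRecording(b$trial, "left_ankle")@accel)
  expect_identical(intervals(a$annotations), intervals(b$annotations))
  c <- simulateTrial(cfg2, seed = 6)
  expect_false(identical(getRecording(a$trial, "left_ankle")@accel,
                         getRecording(c$trial, "left_ankle")@accel))
})

test_that("simulated tremor and gait land in their spectral bands", {
  cfg <- simConfig(durationS = 60)
  set.seed(40)
  fiTrem <- c(); fiWalk <- c(); fracTrem <- c(); fracWalk <- c()
  for (s in 1:4) {
    st <- simulateTrial(cfg, subject = "s", seed = 100 + s)
    filt <- lowpassTrial(st$trial)
    ws <- makeWindows(filt, cleanAnnotations(st$annotations), role = "test")
    w <- windowInfo(ws)
    states <- st$states
    stateOf <- function(start) {
      ix <- (round(start * 128) + 1):(round(start * 128) + 384)
      tab <- table(states[ix])
      names(tab)[which.max(tab)]
    }
    st3 <- vapply(w$start_s, stateOf, character(1))
    pure <- vapply(seq_len(nrow(w)), function(i) {
      ix <- (round(w$start_s[i] * 128) + 1):(round(w$start_s[i] * 128) + 384)
      length(unique(states[ix])) == 1
    }, logical(1))
    for (i in which(pure)) {
      x <- fogkit:::windowSamples(
        axisSignal(filt, "left_ankle", "accel", "AP"), w$start_s[i], 128)
      spec <- psdEstimate(x, 128)
      wk <- bandPower(spec, c(0.5, 3)); fz <- bandPower(spec, c(3, 8))
      fi <- freezingIndex(filt, w$start_s[i])
      if (st3[i] == "tremble") {
        fiTrem <- c(fiTrem, fi); fracTrem <- c(fracTrem, fz / (fz + wk))
      } else if (st3[i] == "walk") {
        fiWalk <- c(fiWalk, fi); fracWalk <- c(fracWalk, wk / (fz + wk))
      }
    }
  }
  expect_gt(mean(fiTrem), 2.5)
  expect_lt(mean(fiWalk), 2.5)
  expect_true(mean(fracTrem >= 0.7) >= 0.9)  # leg AP energy in freeze band
  expect_true(mean(fracWalk >= 0.7) >= 0.9)  # leg AP energy in walk band
})

test_that("generated annotations are already clean under the default scheduler", {
  cfg <- simConfig(durationS = 60)
  for (s in 1:5) {
    st <- simulateTrial(cfg, seed = 200 + s)
    iv <- intervals(st$annotations)
    expect_equal(intervals(cleanAnnotations(st$annotations)), iv)
    if (nrow(iv)) expect_true(all(iv[, 2] - iv[, 1] >= 1.0))
  }
})

test_that("cohort bookkeeping: one trial file set and annotation per trial", {
  cfg <- simConfig(nSubjects = 3, trialsPerSubject = 3, durationS = 10)
  cohort <- simulateCohort(cfg, seed = 2)
  expect_equal(length(cohort), 3)
  expect_equal(lengths(cohort), c(s01 = 3, s02 = 3, s03 = 3))
  dir <- withr::local_tempdir()
  prefixes <- writeCohort(cohort, dir)
  expect_equal(length(prefixes), 9)
  for (p in prefixes) {
    expect_true(file.exists(paste0(p, "_lower_back.csv")))
    expect_true(file.exists(paste0(p, "_annotations.json")))
  }
  # different seeds draw different subject tremor frequencies
  c2 <- simulateCohort(cfg, seed = 3)
  t1 <- getRecording(cohort$s01[[1]]$trial, "left_ankle")@accel
  t2 <- getRecording(c2$s01[[1]]$trial, "left_ankle")@accel
  expect_false(identical(t1, t2))
})

test_that("the cohort's FOG window fraction tracks the configured time fraction", {
  cfg <- simConfig(nSubjects = 4, durationS = 60, fogTimeFraction = 0.25)
  cohort <- simulateCohort(cfg, seed = 4)
  labs <- character(0)
  for (sid in names(cohort)) {
    st <- cohort[[sid]][[1]]
    ws <- makeWindows(st$trial, cleanAnnotations(st$annotations),
                      role = "test")
    labs <- c(labs, windowInfo(ws)$label)
  }
  frac <- mean(labs == "FOG")
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.35)
})
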