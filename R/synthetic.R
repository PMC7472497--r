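# Synthetic three-site gait/FOG cohort generator. Walking is a cadence
# sinusoid (plus first harmonic) on legs and trunk; trembling freezing is a
# 3-8 Hz leg oscillation with trunk movement attenuated by a dissociation
# factor (the mechanism behind the back-to-legs ratio features); akinetic
# freezing and quiet standing are near-zero movement above sensor noise.
# Episodes are scheduled with minimum durations and gaps so ground truth is
# stable under annotation cleaning; gravity rides on the vertical
# accelerometer axis as a 9.81 m/s^2 offset.

#' Default simulation configuration
#'
#' @param nSubjects cohort size
#' @param trialsPerSubject trials per subject (difficulty cycles 1..3)
#' @param durationS trial duration, seconds
#' @param fs sampling rate, Hz
#' @param cadenceHz mean walking cadence (within the 0.5-3 Hz walk band)
#' @param tremorRange per-subject tremor frequency range, Hz (freeze band)
#' @param fogTimeFraction target fraction of trial time spent frozen
#' @param akineticFraction probability an episode is akinetic rather than
#'   trembling
#' @param standRate expected quiet-standing bouts per trial (not annotated
#'   FOG; the designed hard negative against akinetic freezing)
#' @param noiseSd accelerometer white-noise SD, m/s^2
#' @param gyroNoiseSd gyroscope white-noise SD, deg/s
#' @param dirty relax the scheduler's 1.2 s minimum durations/gaps to
#'   exercise annotation cleaning
#' @return configuration list
#' @export
simConfig <- function(nSubjects = 20L, trialsPerSubject = 1L,
                      durationS = 90, fs = 128, cadenceHz = 1.8,
                      tremorRange = c(4, 7), fogTimeFraction = 0.25,
                      akineticFraction = 0.2, standRate = 1,
                      noiseSd = 0.05, gyroNoiseSd = 1.0, dirty = FALSE) {
  list(nSubjects = as.integer(nSubjects),
       trialsPerSubject = as.integer(trialsPerSubject),
       durationS = durationS, fs = fs, cadenceHz = cadenceHz,
       tremorRange = tremorRange, fogTimeFraction = fogTimeFraction,
       akineticFraction = akineticFraction, standRate = standRate,
       standDurRange = c(2, 4),
       episodeDurMeanLog = log(5), episodeDurSdLog = 0.5,
       minEpisodeS = if (dirty) 0.4 else 1.2,
       minGapS = if (dirty) 0.4 else 1.2,
       amp = list(legAccWalk = 1.0, backAccWalk = 0.8,
                  legGyrWalk = 30, backGyrWalk = 25,
                  legAccTremor = 1.0, legGyrTremor = 40,
                  backTremorFactor = 0.05, harmonic = 0.4),
       noiseSd = noiseSd, gyroNoiseSd = gyroNoiseSd,
       crossfadeS = 0.2, gravity = 9.81, dirty = dirty)
}

# schedule disjoint episodes totalling ~ targetS inside [0, durationS],
# respecting minimum duration and inter-episode gap
scheduleEpisodes <- function(durationS, targetS, cfg) {
  if (targetS <= 0) return(matrix(numeric(0), ncol = 2))
  durs <- numeric(0)
  while (sum(durs) < targetS && length(durs) < 50L) {
    d <- stats::rlnorm(1, cfg$episodeDurMeanLog, cfg$episodeDurSdLog)
    if (d < cfg$minEpisodeS) d <- cfg$minEpisodeS
    durs <- c(durs, d)
  }
  # drop episodes until the schedule fits with gaps
  repeat {
    k <- length(durs)
    need <- sum(durs) + (k + 1) * cfg$minGapS
    if (need <= durationS || k == 0L) break
    durs <- durs[-k]
  }
  k <- length(durs)
  if (k == 0L) return(matrix(numeric(0), ncol = 2))
  slack <- durationS - sum(durs) - (k + 1) * cfg$minGapS
  u <- stats::runif(k + 1)
  gaps <- cfg$minGapS + slack * u / sum(u)
  starts <- cumsum(gaps[1:k]) + c(0, cumsum(durs))[1:k]
  cbind(starts, starts + durs)
}

# place standing bouts in regions at least minGapS clear of FOG episodes
scheduleStanding <- function(durationS, fogIv, cfg) {
  nStand <- stats::rpois(1, cfg$standRate)
  out <- matrix(numeric(0), ncol = 2)
  if (nStand == 0L) return(out)
  blocked <- fogIv
  for (i in seq_len(nStand)) {
    d <- stats::runif(1, cfg$standDurRange[1], cfg$standDurRange[2])
    for (try in 1:20) {
      s <- stats::runif(1, 0, durationS - d)
      conflict <- nrow(blocked) > 0 &&
        any(pmin(s + d + cfg$minGapS, blocked[, 2]) >
              pmax(s - cfg$minGapS, blocked[, 1]))
      conflictOut <- nrow(out) > 0 &&
        any(pmin(s + d, out[, 2]) > pmax(s, out[, 1]))
      if (!conflict && !conflictOut) {
        out <- rbind(out, c(s, s + d))
        break
      }
    }
  }
  out
}

# smooth 0/1 state indicators with a Hann kernel (crossfadeS wide) and
# renormalize so the per-sample weights sum to one
stateWeights <- function(states, fs, crossfadeS) {
  lev <- c("walk", "tremble", "akinetic", "stand")
  n <- length(states)
  kLen <- max(1L, 2L * round(crossfadeS * fs / 2) + 1L)
  kern <- 0.5 - 0.5 * cos(2 * pi * seq_len(kLen) / (kLen + 1))
  kern <- kern / sum(kern)
  W <- sapply(lev, function(l) {
    ind <- as.numeric(states == l)
    if (kLen == 1L) return(ind)
    sm <- stats::filter(ind, kern, sides = 2)
    sm[is.na(sm)] <- ind[is.na(sm)]
    as.numeric(sm)
  })
  W / rowSums(W)
}

# one axis bundle of periodic movement: fundamental + first harmonic
periodic <- function(t, freq, amp, phase, harmonic) {
  amp * (sin(2 * pi * freq * t + phase) +
           harmonic * sin(2 * pi * 2 * freq * t + 2 * phase))
}

#' Simulate one trial
#'
#' @param cfg configuration from \code{\link{simConfig}}
#' @param subject subject id string
#' @param params per-subject parameters (list with cadenceHz, tremorHz,
#'   ampScale); drawn by \code{\link{simulateCohort}}
#' @param seed integer seed (same seed, same trial, bit for bit)
#' @param difficulty test difficulty 1..3; higher levels provoke more FOG
#' @return list(trial, annotations, states): a
#'   \linkS4class{TrialRecording}, the ground-truth
#'   \linkS4class{AnnotationTrack}, and the per-sample state sequence
#' @export
simulateTrial <- function(cfg, subject = "s1", params = NULL, seed = 1L,
                          difficulty = 1L) {
  if (is.null(params))
    params <- list(cadenceHz = cfg$cadenceHz,
                   tremorHz = mean(cfg$tremorRange), ampScale = 1)
  withSeed(seed, {
    fs <- cfg$fs
    n <- round(cfg$durationS * fs)
    t <- (0:(n - 1)) / fs
    frac <- min(0.6, cfg$fogTimeFraction * c(0.7, 1, 1.3)[difficulty])
    fogIv <- scheduleEpisodes(cfg$durationS, frac * cfg$durationS, cfg)
    akinetic <- if (nrow(fogIv))
      stats::runif(nrow(fogIv)) < cfg$akineticFraction else logical(0)
    standIv <- scheduleStanding(cfg$durationS, fogIv, cfg)

    states <- rep("walk", n)
    markIv <- function(states, iv, label) {
      for (r in seq_len(nrow(iv))) {
        i0 <- max(1L, round(iv[r, 1] * fs) + 1L)
        i1 <- min(n, round(iv[r, 2] * fs))
        states[i0:i1] <- label
      }
      states
    }
    if (nrow(fogIv)) {
      states <- markIv(states, fogIv[!akinetic, , drop = FALSE], "tremble")
      states <- markIv(states, fogIv[akinetic, , drop = FALSE], "akinetic")
    }
    states <- markIv(states, standIv, "stand")
    W <- stateWeights(states, fs, cfg$crossfadeS)

    a <- cfg$amp
    scl <- params$ampScale
    cad <- params$cadenceHz
    trem <- params$tremorHz
    mkSite <- function(site) {
      isBack <- site == "lower_back"
      legSign <- if (site == "right_ankle") pi else 0  # legs antiphase
      walkAcc <- if (isBack) a$backAccWalk * scl else a$legAccWalk * scl
      walkGyr <- if (isBack) a$backGyrWalk * scl else a$legGyrWalk * scl
      tremAcc <- a$legAccTremor * scl *
        (if (isBack) a$backTremorFactor else 1)
      tremGyr <- a$legGyrTremor * scl *
        (if (isBack) a$backTremorFactor else 1)
      axAmp <- c(V = 1, AP = 0.8, ML = 0.3)
      trAmp <- c(V = 0.8, AP = 1, ML = 0.5)
      mk <- function(base, tremBase, noiseSd) {
        m <- matrix(0, 3, n, dimnames = list(AXES, NULL))
        for (ax in AXES) {
          walk <- periodic(t, cad, base * axAmp[[ax]],
                           legSign + match(ax, AXES), a$harmonic)
          tremble <- tremBase * trAmp[[ax]] *
            sin(2 * pi * trem * t + legSign)
          m[ax, ] <- W[, "walk"] * walk + W[, "tremble"] * tremble +
            stats::rnorm(n, sd = noiseSd)
        }
        m
      }
      accel <- mk(walkAcc, tremAcc, cfg$noiseSd)
      accel["V", ] <- accel["V", ] + cfg$gravity
      gyro <- mk(walkGyr, tremGyr, cfg$gyroNoiseSd)
      SensorRecording(site, accel, gyro, fs)
    }
    trial <- TrialRecording(lapply(SITES, mkSite), subjectId = subject,
                            medState = "OFF",
                            difficulty = as.integer(difficulty))
    list(trial = trial, annotations = AnnotationTrack(fogIv),
         states = states)
  })
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject walking cadence, tremor frequency and amplitude scale
#' so that leave-one-patient-out validation is meaningful, then simulates
#' \code{trialsPerSubject} trials per subject with difficulty cycling
#' 1..3.
#'
#' @param cfg configuration from \code{\link{simConfig}}
#' @param seed root seed; per-trial seeds are derived from it
#' @return list of subjects, each a list of \code{\link{simulateTrial}}
#'   results
#' @export
simulateCohort <- function(cfg, seed = 1L) {
  params <- withSeed(seed, lapply(seq_len(cfg$nSubjects), function(i) {
    list(cadenceHz = min(2.6, max(1.2, stats::rnorm(1, cfg$cadenceHz, 0.15))),
         tremorHz = stats::runif(1, cfg$tremorRange[1], cfg$tremorRange[2]),
         ampScale = stats::runif(1, 0.8, 1.2))
  }))
  cohort <- list()
  for (i in seq_len(cfg$nSubjects)) {
    sid <- sprintf("s%02d", i)
    trials <- lapply(seq_len(cfg$trialsPerSubject), function(j) {
      simulateTrial(cfg, subject = sid, params = params[[i]],
                    seed = seed + 1000L * i + j,
                    difficulty = ((j - 1L) %% 3L) + 1L)
    })
    cohort[[sid]] <- trials
  }
  cohort
}

#' Write a simulated cohort in the trial CSV / annotation JSON dialects
#'
#' @param cohort result of \code{\link{simulateCohort}}
#' @param dir output directory (one subdirectory per subject)
#' @return the written trial prefixes, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  prefixes <- character(0)
  for (sid in names(cohort)) {
    sdir <- file.path(dir, sid)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_along(cohort[[sid]])) {
      prefix <- file.path(sdir, sprintf("trial%02d", j))
      writeTrial(cohort[[sid]][[j]]$trial, prefix)
      writeAnnotations(cohort[[sid]][[j]]$annotations,
                       paste0(prefix, "_annotations.json"))
      prefixes <- c(prefixes, prefix)
    }
  }
  invisible(prefixes)
}
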