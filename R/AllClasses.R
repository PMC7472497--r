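#' @import methods
NULL

AXES <- c("V", "AP", "ML")
SITES <- c("lower_back", "left_ankle", "right_ankle")
LEG_SITES <- c("left_ankle", "right_ankle")
WINDOW_LENGTH_S <- 3.0
FOG_OVERLAP_MIN_S <- 1.5
STEP_FOG_S <- 0.6     # 80% overlap of a 3 s window
STEP_NONFOG_S <- 1.5  # 50% overlap
WALK_BAND <- c(0.5, 3)
FREEZE_BAND <- c(3, 8)
FI_THRESHOLD <- 2.5

#' Single-site inertial recording
#'
#' Holds the tri-axial accelerometer (m/s^2) and gyroscope (deg/s) signals of
#' one body-worn sensor, rows ordered vertical (V), anterior-posterior (AP),
#' medio-lateral (ML).
#'
#' @slot site one of "lower_back", "left_ankle", "right_ankle"
#' @slot accel 3 x N numeric matrix, rownames V/AP/ML, m/s^2
#' @slot gyro 3 x N numeric matrix, rownames V/AP/ML, deg/s
#' @slot fs sampling rate in Hz
#' @exportClass SensorRecording
setClass("SensorRecording",
  representation(site = "character", accel = "matrix", gyro = "matrix",
                 fs = "numeric"))

setValidity("SensorRecording", function(object) {
  msg <- character()
  if (!(object@site %in% SITES))
    msg <- c(msg, sprintf("unknown site '%s'", object@site))
  if (!identical(rownames(object@accel), AXES))
    msg <- c(msg, "accel rownames must be exactly V, AP, ML")
  if (!identical(rownames(object@gyro), AXES))
    msg <- c(msg, "gyro rownames must be exactly V, AP, ML")
  if (ncol(object@accel) != ncol(object@gyro))
    msg <- c(msg, "accel and gyro must have identical sample counts")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a SensorRecording
#'
#' @param site sensor location ("lower_back", "left_ankle", "right_ankle")
#' @param accel,gyro 3 x N matrices with rows V, AP, ML
#' @param fs sampling rate (Hz)
#' @return a validated \linkS4class{SensorRecording}
#' @export
SensorRecording <- function(site, accel, gyro, fs) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  rownames(accel) <- AXES; rownames(gyro) <- AXES
  new("SensorRecording", site = site, accel = accel, gyro = gyro, fs = fs)
}

#' One trial of synchronized three-site recordings
#'
#' @slot recordings named list with one \linkS4class{SensorRecording} per site
#' @slot subjectId opaque subject identifier
#' @slot medState "OFF" or "ON" antiparkinsonian-medication state
#' @slot difficulty test difficulty level 1..3
#' @exportClass TrialRecording
setClass("TrialRecording",
  representation(recordings = "list", subjectId = "character",
                 medState = "character", difficulty = "integer"))

setValidity("TrialRecording", function(object) {
  msg <- character()
  if (!setequal(names(object@recordings), SITES))
    msg <- c(msg, sprintf("all three sites required; got: %s",
                          paste(names(object@recordings), collapse = ", ")))
  fss <- vapply(object@recordings, function(r) r@fs, numeric(1))
  ns <- vapply(object@recordings, function(r) ncol(r@accel), numeric(1))
  if (length(unique(fss)) > 1L) msg <- c(msg, "all sites must share fs")
  if (length(unique(ns)) > 1L)
    msg <- c(msg, "all sites must share the sample count")
  if (!(object@medState %in% c("OFF", "ON")))
    msg <- c(msg, "medState must be OFF or ON")
  if (!(object@difficulty %in% 1:3))
    msg <- c(msg, "difficulty must be 1, 2 or 3")
  if (length(msg)) msg else TRUE
})

#' Construct a TrialRecording
#'
#' @param recordings list of three \linkS4class{SensorRecording}s (any order;
#'   matched by their site slot)
#' @param subjectId subject identifier
#' @param medState "OFF" or "ON"
#' @param difficulty integer 1..3
#' @export
TrialRecording <- function(recordings, subjectId = "anonymous",
                           medState = "OFF", difficulty = 1L) {
  names(recordings) <- vapply(recordings, function(r) r@site, character(1))
  new("TrialRecording", recordings = recordings[SITES],
      subjectId = subjectId, medState = medState,
      difficulty = as.integer(difficulty))
}

#' Ground-truth or predicted FOG intervals
#'
#' Ordered, disjoint half-open intervals [start, end) in seconds from trial
#' start.
#'
#' @slot intervals n x 2 numeric matrix, columns start_s and end_s
#' @exportClass AnnotationTrack
setClass("AnnotationTrack", representation(intervals = "matrix"))

setValidity("AnnotationTrack", function(object) {
  iv <- object@intervals
  if (ncol(iv) != 2L) return("intervals must have two columns")
  if (nrow(iv) == 0L) return(TRUE)
  bad <- which(iv[, 1] >= iv[, 2])
  if (length(bad))
    return(sprintf("inverted interval at index %d", bad[1] - 1L))
  if (any(iv[, 1] < 0)) return("negative interval start")
  if (nrow(iv) > 1L) {
    ov <- which(iv[-1L, 1] < iv[-nrow(iv), 2])
    if (length(ov))
      return(sprintf("overlapping intervals at index %d", ov[1]))
  }
  TRUE
})

#' Construct an AnnotationTrack
#'
#' Intervals are sorted by start before validation; overlapping or inverted
#' intervals are rejected.
#'
#' @param intervals n x 2 matrix or data.frame of (start_s, end_s), half-open
#' @param durationS optional trial duration; intervals must fit inside it
#' @export
AnnotationTrack <- function(intervals = matrix(numeric(0), ncol = 2),
                            durationS = NULL) {
  iv <- matrix(as.numeric(as.matrix(intervals)), ncol = 2)
  colnames(iv) <- c("start_s", "end_s")
  if (nrow(iv) > 0L) {
    bad <- which(iv[, 1] >= iv[, 2])
    if (length(bad))
      stop(sprintf("inverted interval at index %d", bad[1] - 1L))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (!is.null(durationS) && any(iv[, 2] > durationS + 1e-9))
      stop("interval extends past trial duration")
  }
  new("AnnotationTrack", intervals = iv)
}

#' Labeled fixed-length windows cut from one trial
#'
#' @slot windows data.frame with columns start_s, label ("FOG"/"nonFOG"),
#'   fog_overlap_s
#' @slot role "train" or "test"
#' @slot lengthS window length, seconds
#' @slot trialDuration duration of the parent trial, seconds
#' @exportClass WindowSet
setClass("WindowSet",
  representation(windows = "data.frame", role = "character",
                 lengthS = "numeric", trialDuration = "numeric"))

setValidity("WindowSet", function(object) {
  w <- object@windows
  msg <- character()
  if (!all(c("start_s", "label", "fog_overlap_s") %in% names(w)))
    msg <- c(msg, "windows needs start_s, label, fog_overlap_s")
  if (!(object@role %in% c("train", "test")))
    msg <- c(msg, "role must be train or test")
  if (nrow(w)) {
    if (any(w$start_s < -1e-9) ||
        any(w$start_s + object@lengthS > object@trialDuration + 1e-9))
      msg <- c(msg, "window outside trial bounds")
    lab <- ifelse(w$fog_overlap_s >= FOG_OVERLAP_MIN_S - 1e-12, "FOG", "nonFOG")
    if (!all(lab == w$label))
      msg <- c(msg, "label inconsistent with the >= 1.5 s overlap rule")
  }
  if (length(msg)) msg else TRUE
})

#' Windows x features matrix with manifest
#'
#' @slot values numeric matrix, one row per window, columns named by
#'   feature id
#' @slot manifest data.frame describing each feature (see
#'   \code{\link{featureManifest}})
#' @slot windowInfo data.frame of per-window metadata (subject, trial,
#'   start_s, label, fog_overlap_s)
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", manifest = "data.frame",
                 windowInfo = "data.frame"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!identical(colnames(object@values), object@manifest$feature_id))
    msg <- c(msg, "value columns must match manifest feature ids in order")
  if (nrow(object@values) != nrow(object@windowInfo))
    msg <- c(msg, "one windowInfo row per value row required")
  if (anyDuplicated(object@manifest$feature_id))
    msg <- c(msg, "feature ids must be unique")
  if (length(msg)) msg else TRUE
})

FeatureMatrix <- function(values, manifest, windowInfo) {
  new("FeatureMatrix", values = values, manifest = manifest,
      windowInfo = windowInfo)
}

#' Trained window-level FOG classifier
#'
#' A standardization recipe (training-set means/SDs), the selected feature
#' ids, and a fitted SVM-RBF with an orientation sign so that larger scores
#' always mean more FOG-like.
#'
#' @slot featureIds character vector of selected feature ids
#' @slot center,scale per-feature standardization parameters
#' @slot fit the fitted e1071 svm object
#' @slot orientation +1/-1 applied to decision values
#' @slot hyper list(cost, gamma)
#' @slot subjects training subject ids
#' @slot seed integer seed recorded at training
#' @exportClass FogModel
setClass("FogModel",
  representation(featureIds = "character", center = "numeric",
                 scale = "numeric", fit = "ANY", orientation = "numeric",
                 hyper = "list", subjects = "character", seed = "integer"))

# ---- accessors -------------------------------------------------------------

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @export
setGeneric("windowInfo", function(x) standardGeneric("windowInfo"))
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @describeIn SensorRecording-class sampling rate (Hz)
#' @export
setMethod("samplingRate", "SensorRecording", function(x) x@fs)
#' @export
setMethod("samplingRate", "TrialRecording",
          function(x) x@recordings[[1]]@fs)
#' @export
setMethod("nSamples", "SensorRecording", function(x) ncol(x@accel))
#' @export
setMethod("nSamples", "TrialRecording",
          function(x) ncol(x@recordings[[1]]@accel))
#' @export
setMethod("durationS", "SensorRecording", function(x) ncol(x@accel) / x@fs)
#' @export
setMethod("durationS", "TrialRecording",
          function(x) nSamples(x) / samplingRate(x))
#' @export
setMethod("intervals", "AnnotationTrack", function(x) x@intervals)
#' @export
setMethod("subjectId", "TrialRecording", function(x) x@subjectId)
#' @export
setMethod("windowInfo", "WindowSet", function(x) x@windows)
#' @export
setMethod("windowInfo", "FeatureMatrix", function(x) x@windowInfo)
#' @export
setMethod("featureIds", "FeatureMatrix", function(x) colnames(x@values))
#' @export
setMethod("featureIds", "FogModel", function(x) x@featureIds)
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' Extract one site's recording from a trial
#'
#' @param trial a \linkS4class{TrialRecording}
#' @param site one of "lower_back", "left_ankle", "right_ankle"
#' @export
getRecording <- function(trial, site) {
  site <- match.arg(site, SITES)
  trial@recordings[[site]]
}

#' Axis signal of one channel of one site
#'
#' @param trial TrialRecording
#' @param site sensor site
#' @param channel "accel" or "gyro"
#' @param axis "V", "AP" or "ML"
#' @return numeric vector of samples
#' @export
axisSignal <- function(trial, site, channel = c("accel", "gyro"),
                       axis = c("V", "AP", "ML")) {
  channel <- match.arg(channel); axis <- match.arg(axis)
  rec <- getRecording(trial, site)
  if (channel == "accel") rec@accel[axis, ] else rec@gyro[axis, ]
}

setMethod("show", "TrialRecording", function(object) {
  cat(sprintf(
    "TrialRecording: subject %s, %s state, difficulty %d\n  %d samples @ %g Hz (%.1f s), sites: %s\n",
    object@subjectId, object@medState, object@difficulty,
    nSamples(object), samplingRate(object), durationS(object),
    paste(names(object@recordings), collapse = ", ")))
})

setMethod("show", "AnnotationTrack", function(object) {
  n <- nrow(object@intervals)
  cat(sprintf("AnnotationTrack: %d FOG interval(s), total %.2f s\n",
              n, sum(object@intervals[, 2] - object@intervals[, 1])))
})

setMethod("show", "WindowSet", function(object) {
  w <- object@windows
  cat(sprintf("WindowSet (%s role): %d windows of %g s (%d FOG / %d nonFOG)\n",
              object@role, nrow(w), object@lengthS,
              sum(w$label == "FOG"), sum(w$label == "nonFOG")))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d windows x %d features\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "FogModel", function(object) {
  cat(sprintf(
    "FogModel: SVM-RBF on %d features (cost=%g, gamma=%g), %d training subjects\n",
    length(object@featureIds), object@hyper$cost, object@hyper$gamma,
    length(object@subjects)))
})
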