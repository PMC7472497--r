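# Episode reconstruction from overlapping window predictions, derived
# outcomes (percent time frozen, episode counts) and the window-level
# evaluation metrics, plus the freezing-index threshold baseline.

#' Fuse overlapping window predictions into FOG episodes
#'
#' Per-sample majority vote over all windows covering each sample (a
#' strict majority is required, so an isolated FOG window outvoted by its
#' two overlapping neighbours leaves no episode), converted to intervals
#' and cleaned with the same merge/drop rules as the ground-truth
#' annotations so predicted and annotated episodes are comparable objects.
#'
#' @param windows a test-role \linkS4class{WindowSet}
#' @param predictions "FOG"/"nonFOG" per window
#' @param durationS trial duration (s)
#' @param fs voting grid rate (Hz)
#' @return an \linkS4class{AnnotationTrack} of predicted episodes
#' @export
windowsToEpisodes <- function(windows, predictions, durationS, fs = 128) {
  w <- windowInfo(windows)
  if (nrow(w) == 0L) return(AnnotationTrack())
  stopifnot(length(predictions) == nrow(w))
  n <- round(durationS * fs)
  votesFog <- integer(n); votesAll <- integer(n)
  len <- windows@lengthS
  for (i in seq_len(nrow(w))) {
    i0 <- round(w$start_s[i] * fs) + 1L
    i1 <- min(n, round((w$start_s[i] + len) * fs))
    votesAll[i0:i1] <- votesAll[i0:i1] + 1L
    if (predictions[i] == "FOG") votesFog[i0:i1] <- votesFog[i0:i1] + 1L
  }
  fog <- votesAll > 0L & votesFog > (votesAll - votesFog)  # strict majority
  iv <- runsToIntervals(fog, fs)
  cleanAnnotations(AnnotationTrack(iv))
}

runsToIntervals <- function(flag, fs) {
  if (!any(flag)) return(matrix(numeric(0), ncol = 2))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind((starts[r$values]) / fs, ends[r$values] / fs)
}

#' Derived scalar FOG outcomes
#'
#' @param episodes an \linkS4class{AnnotationTrack} (cleaned)
#' @param durationS trial duration, seconds (> 0)
#' @return list(percent_time_frozen, total_time_frozen_s, n_episodes)
#' @export
deriveOutcomes <- function(episodes, durationS) {
  if (durationS <= 0) stop("duration must be positive")
  iv <- intervals(episodes)
  total <- if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0
  list(percent_time_frozen = 100 * total / durationS,
       total_time_frozen_s = total,
       n_episodes = nrow(iv))
}

#' Window-level detection metrics
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), accuracy =
#' (TP + TN) / n, in percent. When the truth contains no FOG windows,
#' sensitivity is 100% by convention. With scores, the empirical ROC, its
#' trapezoidal AUC and the optimal operating point are included.
#'
#' @param predicted,truth equal-length "FOG"/"nonFOG" vectors
#' @param scores optional continuous scores (larger = more FOG-like)
#' @return list with counts, rates (percent), and optionally roc/auc/oop
#' @export
windowMetrics <- function(predicted, truth, scores = NULL) {
  if (length(predicted) != length(truth))
    stop("predicted and truth lengths differ")
  tp <- sum(predicted == "FOG" & truth == "FOG")
  fn <- sum(predicted == "nonFOG" & truth == "FOG")
  tn <- sum(predicted == "nonFOG" & truth == "nonFOG")
  fp <- sum(predicted == "FOG" & truth == "nonFOG")
  sens <- if (tp + fn == 0L) 100 else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0L) 100 else 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / length(truth)
  out <- list(sensitivity = sens, specificity = spec, accuracy = acc,
              tp = tp, fp = fp, tn = tn, fn = fn)
  if (!is.null(scores) && length(unique(truth)) == 2L) {
    roc <- rocCurve(scores, truth)
    out$roc <- roc
    out$auc <- aucTrapezoid(roc)
    out$oop <- rocOptimalPoint(roc)
  }
  out
}

#' Freezing-index threshold detector
#'
#' The single-feature baseline: a window is FOG when the maximum freezing
#' index over the two legs (anterior-posterior acceleration) exceeds the
#' 2.5 (AU) threshold.
#'
#' @param trial a filtered \linkS4class{TrialRecording}
#' @param windows a \linkS4class{WindowSet}
#' @param threshold detection threshold in arbitrary units
#' @return list(label, score): per-window labels and the FI values
#' @export
freezingIndexDetector <- function(trial, windows, threshold = FI_THRESHOLD) {
  w <- windowInfo(windows)
  fi <- vapply(w$start_s, function(s)
    freezingIndex(trial, s, windows@lengthS), numeric(1))
  list(label = ifelse(fi > threshold, "FOG", "nonFOG"), score = fi)
}
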