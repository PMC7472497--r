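# Comparator feature set computed from the lower-back accelerometer only:
# axis-mean differences, per-axis SD/skewness, inter-axis correlations,
# skewness of the per-sample magnitude, and spectral features of the summed
# axis signal (band SDs and skewnesses, harmonic peaks, spectral center of
# mass, and the first three principal-component projections of the
# 0.04-8 Hz spectrum, with the PCA basis fit on training windows only).

SAMA_BANDS_SD <- list(c(0.04, 0.68), c(0.68, 3), c(3, 8), c(8, 20),
                      c(0.1, 8))
SAMA_BANDS_SKEW <- list(c(0.04, 0.68), c(0.68, 3), c(3, 8))
SAMA_PCA_BAND <- c(0.04, 8)

#' Manifest of the back-sensor comparator feature set
#'
#' @return data.frame with columns feature_id and domain
#' @export
samaManifest <- function() {
  ids <- c("sama_meandiff_AP_V", "sama_meandiff_V_ML", "sama_meandiff_AP_ML",
           "sama_sd_AP", "sama_sd_V", "sama_sd_ML",
           "sama_corr_V_AP", "sama_corr_AP_ML", "sama_corr_V_ML",
           "sama_skew_AP", "sama_skew_V", "sama_skew_ML",
           "sama_skew_rms",
           vapply(SAMA_BANDS_SD, function(b)
             sprintf("sama_bandsd_%g_%g", b[1], b[2]), character(1)),
           "sama_max_harmonic", "sama_max_harmonic_freq",
           "sama_harmonic_distance", "sama_spectral_com",
           vapply(SAMA_BANDS_SKEW, function(b)
             sprintf("sama_bandskew_%g_%g", b[1], b[2]), character(1)),
           paste0("sama_pca", 1:3))
  data.frame(feature_id = ids,
             domain = c(rep("time", 13), rep("frequency", 15)),
             stringsAsFactors = FALSE)
}

# PSD of the summed back-acceleration signal restricted to the PCA band
samaSpectrum <- function(backAccel, fs) {
  s <- colSums(backAccel)
  spec <- psdEstimate(s, fs)
  sel <- spec$freq >= SAMA_PCA_BAND[1] - 1e-12 &
    spec$freq <= SAMA_PCA_BAND[2] + 1e-12
  list(full = spec, pcaVec = spec$psd[sel])
}

# indices of local PSD maxima (interior points); falls back to global max
spectralPeaks <- function(psd) {
  n <- length(psd)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1)
  i[psd[i] > psd[i - 1] & psd[i] >= psd[i + 1] & psd[i] > 0]
}

samaWindowVector <- function(backAccel, fs, pcaBasis) {
  V <- backAccel["V", ]; AP <- backAccel["AP", ]; ML <- backAccel["ML", ]
  vals <- c(
    sama_meandiff_AP_V = mean(AP) - mean(V),
    sama_meandiff_V_ML = mean(V) - mean(ML),
    sama_meandiff_AP_ML = mean(AP) - mean(ML),
    sama_sd_AP = stats::sd(AP), sama_sd_V = stats::sd(V),
    sama_sd_ML = stats::sd(ML),
    sama_corr_V_AP = safeCor(V, AP), sama_corr_AP_ML = safeCor(AP, ML),
    sama_corr_V_ML = safeCor(V, ML),
    sama_skew_AP = sampleSkewness(AP), sama_skew_V = sampleSkewness(V),
    sama_skew_ML = sampleSkewness(ML),
    sama_skew_rms = sampleSkewness(sqrt(V^2 + AP^2 + ML^2)))
  sp <- samaSpectrum(backAccel, fs)
  spec <- sp$full
  for (b in SAMA_BANDS_SD) {
    sel <- spec$freq >= b[1] - 1e-12 & spec$freq <= b[2] + 1e-12
    vals[sprintf("sama_bandsd_%g_%g", b[1], b[2])] <-
      if (sum(sel) > 1L) stats::sd(spec$psd[sel]) else 0
  }
  pk <- spectralPeaks(spec$psd)
  if (!length(pk)) {
    vals["sama_max_harmonic"] <- 0
    vals["sama_max_harmonic_freq"] <- 0
    vals["sama_harmonic_distance"] <- 0
  } else {
    ord <- pk[order(spec$psd[pk], decreasing = TRUE)]
    vals["sama_max_harmonic"] <- spec$psd[ord[1]]
    vals["sama_max_harmonic_freq"] <- spec$freq[ord[1]]
    vals["sama_harmonic_distance"] <-
      if (length(ord) >= 2L) abs(spec$freq[ord[1]] - spec$freq[ord[2]]) else 0
  }
  tot <- sum(spec$psd)
  vals["sama_spectral_com"] <-
    if (tot > 0) sum(spec$freq * spec$psd) / tot else 0
  for (b in SAMA_BANDS_SKEW) {
    vals[sprintf("sama_bandskew_%g_%g", b[1], b[2])] <-
      spectralSkewness(spec, b)
  }
  proj <- drop(crossprod(pcaBasis$rotation, sp$pcaVec - pcaBasis$center))
  vals[paste0("sama_pca", 1:3)] <- proj[1:3]
  vals
}

#' Fit the PCA basis of the comparator set on training windows
#'
#' Principal components of the 0.04-8 Hz back-acceleration spectra of all
#' supplied training windows (global fit across subjects).
#'
#' @param trials list of filtered \linkS4class{TrialRecording}s
#' @param windowSets matching list of \linkS4class{WindowSet}s
#' @return list(center, rotation) projecting a spectrum onto 3 components
#' @export
fitSamaBasis <- function(trials, windowSets) {
  specs <- list()
  for (k in seq_along(trials)) {
    fs <- samplingRate(trials[[k]])
    w <- windowInfo(windowSets[[k]])
    for (i in seq_len(nrow(w))) {
      sigs <- windowSigs(trials[[k]], w$start_s[i], windowSets[[k]]@lengthS)
      specs[[length(specs) + 1L]] <- samaSpectrum(sigs$back$accel, fs)$pcaVec
    }
  }
  X <- do.call(rbind, specs)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 3)
  rot <- pc$rotation
  if (ncol(rot) < 3L)  # degenerate training spectra: pad with zero loadings
    rot <- cbind(rot, matrix(0, nrow(rot), 3L - ncol(rot)))
  list(center = pc$center, rotation = rot[, 1:3, drop = FALSE])
}

#' Compute the comparator feature matrix for a window set
#'
#' @param trial a filtered \linkS4class{TrialRecording}
#' @param windows a \linkS4class{WindowSet}
#' @param pcaBasis basis from \code{\link{fitSamaBasis}} (required; the
#'   projections are part of the feature set)
#' @return a \linkS4class{FeatureMatrix} with the 28 comparator features
#' @export
computeSamaFeatures <- function(trial, windows, pcaBasis) {
  if (missing(pcaBasis) || is.null(pcaBasis))
    stop("PCA basis is required (fit it on training windows with fitSamaBasis)")
  fs <- samplingRate(trial)
  man <- samaManifest()
  w <- windowInfo(windows)
  vals <- matrix(NA_real_, nrow(w), nrow(man),
                 dimnames = list(NULL, man$feature_id))
  for (i in seq_len(nrow(w))) {
    sigs <- windowSigs(trial, w$start_s[i], windows@lengthS)
    vals[i, ] <- samaWindowVector(sigs$back$accel, fs, pcaBasis)
  }
  info <- cbind(data.frame(subject = trial@subjectId,
                           stringsAsFactors = FALSE), w)
  FeatureMatrix(vals, man, info)
}
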