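# The 86-feature window library. Features are organised in four channel
# groups -- back accelerometer, back gyroscope, leg accelerometers and leg
# gyroscopes -- with leg-sourced features computed per leg and aggregated
# (max over legs unless the manifest says min). Frequency features use the
# Hann periodogram of spectral.R with the walk (0.5-3 Hz) and freeze
# (3-8 Hz) bands.

GROUPS <- c("backacc", "backgyr", "legsacc", "legsgyr")
TIME_STATS <- c("mean", "sd", "skew", "rcs")
FREQ_FAMS <- c("fi", "bp_walk", "bp_freeze", "pf_walk", "pf_freeze",
               "ent_walk", "ent_freeze")

# axis on which each frequency family is evaluated, per group
freqAxisFor <- function(group, fam) {
  if (fam %in% c("fi", "bp_walk", "bp_freeze")) return("AP")
  if (fam %in% c("pf_walk", "pf_freeze")) return("V")
  if (group == "backacc") "AP" else "V"  # entropies
}

#' The canonical 86-entry feature manifest
#'
#' One row per feature: id, channel group, axis specification, domain,
#' frequency band (when spectral) and the leg-aggregation rule for
#' leg-sourced features. The manifest spans per-axis time statistics (mean,
#' SD, skewness, range of cumulative sum), tri-axial RMS per group,
#' per-group spectral features (freezing index, band powers, peak
#' frequencies and spectral entropies in the walk and freeze bands),
#' inter-leg coordination features on the gyroscope ML axis, two
#' walk-band spectral skewnesses, and the two cross-sensor RMS ratios that
#' capture trunk-leg dissociation during freezing.
#'
#' @return data.frame with columns feature_id, group, channel, axis, stat,
#'   domain, band, leg_agg
#' @export
featureManifest <- function() {
  rows <- list()
  addRow <- function(id, group, axis, stat, domain, band = NA_character_,
                     legAgg = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature_id = id, group = group,
      channel = c(backacc = "accel", backgyr = "gyro", legsacc = "accel",
                  legsgyr = "gyro", cross = "both")[[group]],
      axis = axis, stat = stat, domain = domain, band = band,
      leg_agg = legAgg, stringsAsFactors = FALSE)
  }
  for (grp in GROUPS) {
    legAgg <- if (startsWith(grp, "legs")) "max" else NA_character_
    for (ax in AXES) for (st in TIME_STATS) {
      agg <- legAgg
      # Table-3 rows that use the minimum over legs
      if ((grp == "legsacc" && ax == "V" && st == "rcs") ||
          (grp == "legsgyr" && ax == "ML" && st == "rcs")) agg <- "min"
      addRow(paste(grp, ax, st, sep = "_"), grp, ax, st, "time",
             legAgg = agg)
    }
  }
  for (grp in GROUPS)
    addRow(paste0(grp, "_rms3d"), grp, "VAPML", "rms3d", "time",
           legAgg = if (startsWith(grp, "legs")) "max" else NA_character_)
  for (grp in GROUPS) for (fam in FREQ_FAMS) {
    band <- if (fam == "fi") "0.5-3,3-8"
    else if (grepl("walk", fam)) "0.5-3" else "3-8"
    addRow(paste(grp, fam, sep = "_"), grp, freqAxisFor(grp, fam), fam,
           "frequency", band = band,
           legAgg = if (startsWith(grp, "legs")) "max" else NA_character_)
  }
  addRow("legsgyr_ML_interleg_corr", "legsgyr", "ML", "interleg_corr",
         "time", legAgg = "pair")
  addRow("legsgyr_ML_meanmag_ratio", "legsgyr", "ML", "meanmag_ratio",
         "time", legAgg = "pair")
  addRow("backacc_AP_specskew_walk", "backacc", "AP", "specskew",
         "frequency", band = "0.5-3")
  addRow("backgyr_ML_specskew_walk", "backgyr", "ML", "specskew",
         "frequency", band = "0.5-3")
  addRow("ratio_legsgyr_backacc_rms", "cross", "VAPML", "rms_ratio", "time",
         legAgg = "max")
  addRow("ratio_legsgyr_backgyr_rms", "cross", "VAPML", "rms_ratio", "time",
         legAgg = "max")
  do.call(rbind, rows)
}

#' Feature ids of the final 14-feature model
#'
#' The subset retained by the commonness-based selection for the final
#' classifier, in descending order of significance to the model: the
#' legs-gyroscope to back RMS ratios, the freezing index, peak frequencies
#' and spectral entropies in the walk/freeze bands, range-of-cumulative-sum
#' features, inter-leg mean-magnitude ratio and correlation, walk-band
#' spectral skewness, and the leg gyroscope tri-axial RMS.
#'
#' @return character vector of 14 feature ids (a subset of
#'   \code{featureManifest()$feature_id})
#' @export
finalModelFeatureIds <- function() {
  c("ratio_legsgyr_backacc_rms",
    "legsacc_fi",
    "legsacc_pf_freeze",
    "backgyr_ent_walk",
    "legsgyr_pf_walk",
    "backgyr_ML_rcs",
    "backacc_ent_walk",
    "legsacc_V_rcs",
    "legsgyr_ML_meanmag_ratio",
    "backgyr_ML_specskew_walk",
    "legsgyr_ML_interleg_corr",
    "ratio_legsgyr_backgyr_rms",
    "legsgyr_ML_rcs",
    "legsgyr_rms3d")
}

# ---- degenerate-input conventions -----------------------------------------

safeRatio <- function(num, den) if (den <= 0) 0 else num / den

safeCor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

rangeCumsum <- function(x) {
  cs <- cumsum(x)
  max(cs) - min(cs)
}

triaxRms <- function(m) sqrt(mean(m^2))

timeStat <- function(x, stat) {
  switch(stat,
         mean = mean(x),
         sd = stats::sd(x),
         skew = sampleSkewness(x),
         rcs = rangeCumsum(x))
}

freqStat <- function(spec, fam) {
  switch(fam,
         fi = {
           fz <- bandPower(spec, FREEZE_BAND)
           wk <- bandPower(spec, WALK_BAND)
           if (wk <= 0) { if (fz <= 0) 0 else Inf } else fz / wk
         },
         bp_walk = bandPower(spec, WALK_BAND),
         bp_freeze = bandPower(spec, FREEZE_BAND),
         pf_walk = peakFrequency(spec, WALK_BAND),
         pf_freeze = peakFrequency(spec, FREEZE_BAND),
         ent_walk = spectralEntropy(spec, WALK_BAND),
         ent_freeze = spectralEntropy(spec, FREEZE_BAND))
}

# ---- per-window computation -----------------------------------------------

# sigs: list(back = list(accel = 3 x n, gyro = 3 x n),
#            left = ..., right = ...) for one window
computeWindowFeatureVector <- function(sigs, fs, manifest) {
  specCache <- new.env(parent = emptyenv())
  getSpec <- function(m, axis, key) {
    if (is.null(specCache[[key]]))
      specCache[[key]] <- psdEstimate(m[axis, ], fs)
    specCache[[key]]
  }
  groupMats <- function(group) {
    ch <- if (grepl("acc$", group)) "accel" else "gyro"
    if (startsWith(group, "back")) list(back = sigs$back[[ch]])
    else list(left = sigs$left[[ch]], right = sigs$right[[ch]])
  }
  vals <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- manifest[i, ]
    if (f$group == "cross") {
      legRms <- max(triaxRms(sigs$left$gyro), triaxRms(sigs$right$gyro))
      den <- if (f$feature_id == "ratio_legsgyr_backacc_rms")
        triaxRms(sigs$back$accel) else triaxRms(sigs$back$gyro)
      vals[i] <- safeRatio(legRms, den)
      next
    }
    mats <- groupMats(f$group)
    v <- switch(f$stat,
      interleg_corr = safeCor(mats$left[f$axis, ], mats$right[f$axis, ]),
      meanmag_ratio = {
        a <- abs(mean(mats$left[f$axis, ]))
        b <- abs(mean(mats$right[f$axis, ]))
        safeRatio(min(a, b), max(a, b))
      },
      rms3d = {
        per <- vapply(mats, triaxRms, numeric(1))
        if (length(per) == 1L) per else max(per)
      },
      specskew = {
        per <- vapply(names(mats), function(nm)
          spectralSkewness(getSpec(mats[[nm]], f$axis,
                                   paste(f$group, nm, f$axis)),
                           WALK_BAND), numeric(1))
        if (length(per) == 1L) per else max(per)
      },
      {
        # per-leg (or single back) evaluation + aggregation
        per <- vapply(names(mats), function(nm) {
          if (f$domain == "frequency")
            freqStat(getSpec(mats[[nm]], f$axis,
                             paste(f$group, nm, f$axis)), f$stat)
          else timeStat(mats[[nm]][f$axis, ], f$stat)
        }, numeric(1))
        if (length(per) == 1L) per
        else if (identical(f$leg_agg, "min")) min(per) else max(per)
      })
    vals[i] <- v
  }
  if (any(!is.finite(vals)))
    stop("non-finite feature value(s): ",
         paste(manifest$feature_id[!is.finite(vals)], collapse = ", "))
  names(vals) <- manifest$feature_id
  vals
}

windowSigs <- function(trial, startS, lengthS) {
  fs <- samplingRate(trial)
  cut <- function(site) {
    rec <- getRecording(trial, site)
    i0 <- round(startS * fs); n <- round(lengthS * fs)
    list(accel = rec@accel[, (i0 + 1L):(i0 + n), drop = FALSE],
         gyro = rec@gyro[, (i0 + 1L):(i0 + n), drop = FALSE])
  }
  list(back = cut("lower_back"), left = cut("left_ankle"),
       right = cut("right_ankle"))
}

#' Compute the 86-feature matrix for a window set
#'
#' @param trial a filtered \linkS4class{TrialRecording}
#' @param windows a \linkS4class{WindowSet} cut from the same trial
#' @param manifest feature manifest (defaults to the full 86-entry one); a
#'   subset of rows computes just those features
#' @return a \linkS4class{FeatureMatrix} (windows x features)
#' @export
computeFeatures <- function(trial, windows, manifest = featureManifest()) {
  fs <- samplingRate(trial)
  w <- windowInfo(windows)
  vals <- matrix(NA_real_, nrow(w), nrow(manifest),
                 dimnames = list(NULL, manifest$feature_id))
  for (i in seq_len(nrow(w))) {
    sigs <- windowSigs(trial, w$start_s[i], windows@lengthS)
    vals[i, ] <- computeWindowFeatureVector(sigs, fs, manifest)
  }
  info <- cbind(data.frame(subject = trial@subjectId,
                           stringsAsFactors = FALSE), w)
  FeatureMatrix(vals, manifest, info)
}
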