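# Trial CSV dialect: one file per site named <prefix>_<site>.csv with comment
# headers  #fs=<Hz>  #units=m/s2,deg/s  #site=<site>, then columns
# t,accV,accAP,accML,gyrV,gyrAP,gyrML (any column order; mapped by name).
# Metadata sidecar <prefix>_meta.json; annotations <prefix>_annotations.json.

ACC_COLS <- paste0("acc", AXES)
GYR_COLS <- paste0("gyr", AXES)

parseHeaderComments <- function(path) {
  lines <- readLines(path, n = 10L)
  lines <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", lines), "=", fixed = TRUE)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  vals
}

readSiteFile <- function(path) {
  hdr <- parseHeaderComments(path)
  if (!"fs" %in% names(hdr)) stop("missing #fs header in ", path)
  if (!"units" %in% names(hdr) ||
      !identical(hdr[["units"]], "m/s2,deg/s"))
    stop("missing or unsupported #units header in ", path,
         " (expected m/s2,deg/s)")
  fs <- as.numeric(hdr[["fs"]])
  df <- utils::read.csv(path, comment.char = "#")
  df[] <- lapply(df, as.numeric)
  magCols <- grep("^mag", names(df), value = TRUE)
  if (length(magCols)) {
    message("ignoring magnetometer column(s): ",
            paste(magCols, collapse = ", "))
    df <- df[, setdiff(names(df), magCols), drop = FALSE]
  }
  unknown <- setdiff(names(df), c("t", ACC_COLS, GYR_COLS))
  if (length(unknown))
    stop("unknown axis label(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(c(ACC_COLS, GYR_COLS), names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  accel <- t(as.matrix(df[, ACC_COLS])); rownames(accel) <- AXES
  gyro <- t(as.matrix(df[, GYR_COLS])); rownames(gyro) <- AXES
  list(fs = fs, accel = accel, gyro = gyro, site = hdr[["site"]])
}

#' Read one trial from the CSV dialect
#'
#' Expects files \code{<prefix>_lower_back.csv}, \code{<prefix>_left_ankle.csv},
#' \code{<prefix>_right_ankle.csv} and the metadata sidecar
#' \code{<prefix>_meta.json}. Axes are mapped to (V, AP, ML) by column name;
#' magnetometer columns, if present, are ignored with a message.
#'
#' @param prefix path prefix common to the per-site files
#' @return a validated \linkS4class{TrialRecording}
#' @export
readTrial <- function(prefix) {
  recs <- list()
  for (site in SITES) {
    f <- paste0(prefix, "_", site, ".csv")
    if (!file.exists(f)) stop("missing site file for '", site, "': ", f)
    parsed <- readSiteFile(f)
    if (!is.null(parsed$site) && nzchar(parsed$site) &&
        !identical(parsed$site, site))
      stop("site header '", parsed$site, "' does not match file name ", f)
    recs[[site]] <- SensorRecording(site, parsed$accel, parsed$gyro,
                                    parsed$fs)
  }
  ns <- vapply(recs, nSamples, numeric(1))
  if (length(unique(ns)) > 1L)
    stop("mismatched sample counts across sites: ",
         paste(sprintf("%s=%d", names(ns), ns), collapse = ", "))
  metaFile <- paste0(prefix, "_meta.json")
  meta <- if (file.exists(metaFile))
    jsonlite::read_json(metaFile, simplifyVector = TRUE)
  else list(subject_id = "anonymous", med_state = "OFF", difficulty = 1L)
  TrialRecording(recs, subjectId = as.character(meta$subject_id),
                 medState = as.character(meta$med_state),
                 difficulty = as.integer(meta$difficulty))
}

#' Write one trial in the CSV dialect
#'
#' @param trial a \linkS4class{TrialRecording}
#' @param prefix output path prefix
#' @return \code{prefix}, invisibly
#' @export
writeTrial <- function(trial, prefix) {
  fs <- samplingRate(trial)
  n <- nSamples(trial)
  t <- seq_len(n) / fs - 1 / fs
  for (site in SITES) {
    rec <- getRecording(trial, site)
    df <- data.frame(t = t,
                     t(rec@accel), t(rec@gyro))
    names(df) <- c("t", ACC_COLS, GYR_COLS)
    # full double precision so write-then-read is exact
    df[] <- lapply(df, function(x) sprintf("%.17g", x))
    f <- paste0(prefix, "_", site, ".csv")
    con <- file(f, "w")
    writeLines(c(sprintf("#fs=%g", fs), "#units=m/s2,deg/s",
                 sprintf("#site=%s", site)), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  jsonlite::write_json(
    list(subject_id = trial@subjectId, med_state = trial@medState,
         difficulty = trial@difficulty),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read FOG annotations
#'
#' @param path JSON file holding an array of \code{{"start_s": ..., "end_s": ...}}
#'   objects
#' @param durationS optional trial duration used for bounds validation
#' @return an \linkS4class{AnnotationTrack} with sorted intervals
#' @export
readAnnotations <- function(path, durationS = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0L) return(AnnotationTrack())
  AnnotationTrack(cbind(raw$start_s, raw$end_s), durationS = durationS)
}

#' Write FOG annotations
#'
#' @param track an \linkS4class{AnnotationTrack}
#' @param path output JSON path
#' @export
writeAnnotations <- function(track, path) {
  iv <- intervals(track)
  df <- data.frame(start_s = iv[, 1], end_s = iv[, 2])
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}
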