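# End-to-end experiment: simulate (or load) a cohort, split by subject,
# extract windows and features, run LOPO with per-fold selection on the
# training subjects, build the final model on the commonness ranking, and
# evaluate on held-out subjects together with the freezing-index and
# back-sensor comparator methods.

#' Assemble windows and the 86-feature matrix for a set of trials
#'
#' Filters each trial, cleans its annotations, cuts windows in the given
#' role and stacks the per-window feature vectors of all trials.
#'
#' @param cohort list of subjects as from \code{\link{simulateCohort}}
#'   (each trial a list with \code{trial} and \code{annotations})
#' @param role "train" or "test" windowing
#' @param manifest feature manifest; NULL windows the cohort without
#'   computing features (used by the threshold-only detector path)
#' @return list(X, info, trials): feature matrix, per-window metadata
#'   (subject, trial, start_s, label, fog_overlap_s) and per-trial data
#'   (filtered trial, cleaned track, window set) keyed by subject/trial
#' @export
cohortFeatures <- function(cohort, role, manifest = featureManifest()) {
  Xs <- list(); infos <- list(); trials <- list()
  for (sid in names(cohort)) {
    for (j in seq_along(cohort[[sid]])) {
      entry <- cohort[[sid]][[j]]
      filt <- lowpassTrial(entry$trial)
      track <- cleanAnnotations(entry$annotations)
      ws <- makeWindows(filt, track, role = role)
      key <- sprintf("%s/%02d", sid, j)
      trials[[key]] <- list(subject = sid, trialIndex = j, filtered = filt,
                            track = track, windows = ws,
                            durationS = durationS(filt))
      if (nrow(windowInfo(ws)) == 0L) next
      if (is.null(manifest)) {
        info <- windowInfo(ws)
        info <- cbind(data.frame(subject = sid, stringsAsFactors = FALSE),
                      info)
      } else {
        fm <- computeFeatures(filt, ws, manifest)
        info <- windowInfo(fm)
        Xs[[key]] <- featureValues(fm)
      }
      info$trial <- key
      infos[[key]] <- info
    }
  }
  list(X = if (length(Xs)) do.call(rbind, Xs) else NULL,
       info = do.call(rbind, infos), trials = trials)
}

#' Default experiment configuration
#'
#' @param sim simulation configuration (\code{\link{simConfig}})
#' @param testFraction fraction of subjects held out as the test set
#'   (split by subject, never by window)
#' @param featureSet "full" (86-feature pipeline), "sama" (back-sensor
#'   comparator) or "fi" (freezing-index threshold only)
#' @param kMax cap on the feature-count search
#' @param nFolds inner folds for the feature-count choice
#' @param hyper list(cost, gamma) for the SVM
#' @param comparators character vector among "fi", "sama": comparator
#'   methods evaluated on the test set alongside the main pipeline
#' @param seed root seed; simulate/split/svm substreams are derived from it
#' @export
experimentConfig <- function(sim = simConfig(), testFraction = 0.2,
                             featureSet = c("full", "sama", "fi"),
                             kMax = 30L, nFolds = 5L,
                             hyper = list(cost = 1, gamma = NULL),
                             comparators = c("fi", "sama"), seed = 1L) {
  list(sim = sim, testFraction = testFraction,
       featureSet = match.arg(featureSet), kMax = kMax, nFolds = nFolds,
       hyper = hyper, comparators = comparators, seed = as.integer(seed))
}

# per-subject window metrics for a prediction on pooled test windows
perSubjectMetrics <- function(info, labels, predicted, scores = NULL) {
  do.call(rbind, lapply(split(seq_along(labels), info$subject), function(ix) {
    m <- windowMetrics(predicted[ix], labels[ix],
                       scores = if (is.null(scores)) NULL else scores[ix])
    data.frame(subject = info$subject[ix[1]], sensitivity = m$sensitivity,
               specificity = m$specificity, accuracy = m$accuracy,
               stringsAsFactors = FALSE)
  }))
}

# predicted/true percent time frozen per trial
trialOutcomes <- function(trials, info, predicted) {
  do.call(rbind, lapply(names(trials), function(key) {
    tr <- trials[[key]]
    ix <- which(info$trial == key)
    pred <- windowsToEpisodes(tr$windows, predicted[ix], tr$durationS)
    po <- deriveOutcomes(pred, tr$durationS)
    to <- deriveOutcomes(tr$track, tr$durationS)
    data.frame(trial = key, subject = tr$subject,
               pred_percent = po$percent_time_frozen,
               true_percent = to$percent_time_frozen,
               pred_episodes = po$n_episodes,
               true_episodes = to$n_episodes, stringsAsFactors = FALSE)
  }))
}

#' Run a full simulated FOG-detection experiment
#'
#' Simulates a cohort, splits it by subject into training and test sets,
#' runs leave-one-patient-out validation with per-fold feature selection
#' on the training subjects, builds the final model from the commonness
#' ranking, evaluates it on the test subjects (window metrics, ROC/AUC,
#' episode-derived outcomes), and evaluates the configured comparator
#' methods on the same test windows. Deterministic given the seed.
#'
#' @param config an \code{\link{experimentConfig}}
#' @return a nested report list (see Details in the vignette)
#' @export
runExperiment <- function(config = experimentConfig()) {
  seed <- config$seed
  cohort <- simulateCohort(config$sim, seed = seed)
  subjects <- names(cohort)
  nTest <- max(1L, round(config$testFraction * length(subjects)))
  testSubj <- withSeed(seed + 1L, sample(subjects, nTest))
  trainSubj <- setdiff(subjects, testSubj)
  if (length(intersect(trainSubj, testSubj)))
    stop("subject split integrity violated")

  report <- list(config = config,
                 split = list(train = trainSubj, test = testSubj))

  if (config$featureSet == "fi") {
    test <- cohortFeatures(cohort[testSubj], role = "test",
                           manifest = NULL)
    report$fi_baseline <- evalFiDetector(test)
    return(report)
  }

  if (config$featureSet == "full") {
    test <- cohortFeatures(cohort[testSubj], role = "test")
    testLabels <- test$info$label
    train <- cohortFeatures(cohort[trainSubj], role = "train")
    lopo <- lopoValidate(train$X, train$info$label, train$info$subject,
                         selection = TRUE, hyper = config$hyper,
                         nFolds = config$nFolds, kMax = config$kMax,
                         seed = seed + 2L)
    final <- buildFinalModel(train$X, train$info$label, train$info$subject,
                             lopo, hyper = config$hyper,
                             nFolds = config$nFolds, kMax = config$kMax,
                             seed = seed + 2L)
    model <- final$model
    report$lopo <- list(mean_metrics = lopo$mean_metrics, auc = lopo$auc,
                        oop = lopo$oop,
                        selections = lopo$selections,
                        rankings = lopo$rankings)
    report$final <- list(chosen_ids = final$chosen_ids,
                         chosen_k = final$chosen_k,
                         commonness = final$commonness)
  } else {  # sama comparator as the main method
    train <- cohortSamaFeatures(cohort[trainSubj])
    model <- trainFogModel(train$X, train$info$label, hyper = config$hyper,
                           seed = seed + 2L)
    test <- cohortSamaFeaturesFromBasis(cohort[testSubj], train$basis)
    testLabels <- test$info$label
  }

  pred <- predictFog(model, test$X)
  pooled <- windowMetrics(pred$label, testLabels, scores = pred$score)
  report$test <- list(
    metrics = pooled[c("sensitivity", "specificity", "accuracy", "auc")],
    oop = pooled$oop,
    per_subject = perSubjectMetrics(test$info, testLabels, pred$label,
                                    pred$score),
    outcomes = trialOutcomes(test$trials, test$info, pred$label))
  oc <- report$test$outcomes
  report$test$spearman_percent_frozen <-
    if (nrow(oc) >= 3L && stats::sd(oc$true_percent) > 0 &&
        stats::sd(oc$pred_percent) > 0)
      stats::cor(oc$pred_percent, oc$true_percent, method = "spearman")
    else NA_real_

  if ("fi" %in% config$comparators)
    report$fi_baseline <- evalFiDetector(test)
  if ("sama" %in% config$comparators && config$featureSet == "full")
    report$sama <- evalSamaComparator(cohort[trainSubj], cohort[testSubj],
                                      config, seed + 3L)

  # three-method comparison on the training cohort (the larger set), every
  # method patient-independent over the same windows
  if (config$featureSet == "full" && length(config$comparators)) {
    tabs <- list(proposed = lopoPerSubject(lopo))
    if ("fi" %in% config$comparators)
      tabs$freezing_index <- fiPerSubjectOnCohort(train)
    if ("sama" %in% config$comparators)
      tabs$sama <- samaLopoPerSubject(cohort[trainSubj], config, seed + 4L)
    report$comparison <- list(per_subject = tabs,
                              table = compareMethods(tabs))
  }
  report
}

lopoPerSubject <- function(lopo) {
  do.call(rbind, lapply(lopo$folds, function(f)
    data.frame(subject = f$subject, sensitivity = f$metrics$sensitivity,
               specificity = f$metrics$specificity,
               accuracy = f$metrics$accuracy, stringsAsFactors = FALSE)))
}

fiPerSubjectOnCohort <- function(data) {
  preds <- character(0)
  for (key in names(data$trials)) {
    tr <- data$trials[[key]]
    if (nrow(windowInfo(tr$windows)) == 0L) next
    preds <- c(preds, freezingIndexDetector(tr$filtered, tr$windows)$label)
  }
  perSubjectMetrics(data$info, data$info$label, preds)
}

# LOPO over the back-sensor comparator set with the PCA basis refit on
# each fold's training subjects (spectra computed once, projections per
# fold)
samaLopoPerSubject <- function(cohort, config, seed) {
  parts <- samaParts(cohort)
  subj <- unique(parts$info$subject)
  out <- list()
  for (s in subj) {
    tr <- parts$info$subject != s
    pc <- stats::prcomp(parts$spectra[tr, , drop = FALSE], center = TRUE,
                        scale. = FALSE, rank. = 3)
    proj <- scale(parts$spectra, center = pc$center, scale = FALSE) %*%
      pc$rotation
    X <- parts$X
    X[, paste0("sama_pca", 1:3)] <-
      proj[, seq_len(min(3, ncol(proj))), drop = FALSE]
    model <- trainFogModel(X[tr, , drop = FALSE], parts$info$label[tr],
                           hyper = config$hyper, seed = seed)
    p <- predictFog(model, X[!tr, , drop = FALSE])
    m <- windowMetrics(p$label, parts$info$label[!tr])
    out[[s]] <- data.frame(subject = s, sensitivity = m$sensitivity,
                           specificity = m$specificity,
                           accuracy = m$accuracy, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# comparator features over train-role windows with the PCA projections
# left as zeros, plus the per-window band spectra for per-fold bases
samaParts <- function(cohort) {
  zeroBasis <- NULL
  Xs <- list(); infos <- list(); specs <- list()
  for (sid in names(cohort)) for (j in seq_along(cohort[[sid]])) {
    entry <- cohort[[sid]][[j]]
    filt <- lowpassTrial(entry$trial)
    ws <- makeWindows(filt, cleanAnnotations(entry$annotations),
                      role = "train")
    w <- windowInfo(ws)
    if (!nrow(w)) next
    fs <- samplingRate(filt)
    sp <- t(vapply(w$start_s, function(s)
      samaSpectrum(windowSigs(filt, s, ws@lengthS)$back$accel, fs)$pcaVec,
      samaSpectrum(windowSigs(filt, w$start_s[1], ws@lengthS)$back$accel,
                   fs)$pcaVec))
    if (is.null(zeroBasis))
      zeroBasis <- list(center = rep(0, ncol(sp)),
                        rotation = matrix(0, ncol(sp), 3))
    fm <- computeSamaFeatures(filt, ws, zeroBasis)
    Xs[[length(Xs) + 1L]] <- featureValues(fm)
    infos[[length(infos) + 1L]] <- windowInfo(fm)
    specs[[length(specs) + 1L]] <- sp
  }
  list(X = do.call(rbind, Xs), info = do.call(rbind, infos),
       spectra = do.call(rbind, specs))
}

# freezing-index threshold detector over pooled test windows
evalFiDetector <- function(test) {
  preds <- character(0); scores <- numeric(0)
  for (key in names(test$trials)) {
    tr <- test$trials[[key]]
    if (nrow(windowInfo(tr$windows)) == 0L) next
    d <- freezingIndexDetector(tr$filtered, tr$windows)
    preds <- c(preds, d$label); scores <- c(scores, d$score)
  }
  labels <- test$info$label
  m <- windowMetrics(preds, labels, scores = scores)
  list(metrics = m[c("sensitivity", "specificity", "accuracy", "auc")],
       per_subject = perSubjectMetrics(test$info, labels, preds, scores),
       predictions = preds)
}

cohortSamaFeatures <- function(cohort) {
  trials <- list(); wsets <- list()
  for (sid in names(cohort)) for (j in seq_along(cohort[[sid]])) {
    entry <- cohort[[sid]][[j]]
    filt <- lowpassTrial(entry$trial)
    ws <- makeWindows(filt, cleanAnnotations(entry$annotations),
                      role = "train")
    trials[[length(trials) + 1L]] <- filt
    wsets[[length(wsets) + 1L]] <- ws
  }
  basis <- fitSamaBasis(trials, wsets)
  Xs <- list(); infos <- list()
  for (k in seq_along(trials)) {
    if (nrow(windowInfo(wsets[[k]])) == 0L) next
    fm <- computeSamaFeatures(trials[[k]], wsets[[k]], basis)
    Xs[[k]] <- featureValues(fm); infos[[k]] <- windowInfo(fm)
  }
  list(X = do.call(rbind, Xs), info = do.call(rbind, infos), basis = basis)
}

cohortSamaFeaturesFromBasis <- function(cohort, basis) {
  Xs <- list(); infos <- list(); trials <- list()
  for (sid in names(cohort)) for (j in seq_along(cohort[[sid]])) {
    entry <- cohort[[sid]][[j]]
    filt <- lowpassTrial(entry$trial)
    track <- cleanAnnotations(entry$annotations)
    ws <- makeWindows(filt, track, role = "test")
    key <- sprintf("%s/%02d", sid, j)
    trials[[key]] <- list(subject = sid, filtered = filt, track = track,
                          windows = ws, durationS = durationS(filt))
    if (nrow(windowInfo(ws)) == 0L) next
    fm <- computeSamaFeatures(filt, ws, basis)
    info <- windowInfo(fm); info$trial <- key
    Xs[[key]] <- featureValues(fm); infos[[key]] <- info
  }
  list(X = do.call(rbind, Xs), info = do.call(rbind, infos),
       trials = trials)
}

# back-sensor comparator trained on all its features, evaluated per test
# subject
evalSamaComparator <- function(trainCohort, testCohort, config, seed) {
  train <- cohortSamaFeatures(trainCohort)
  model <- trainFogModel(train$X, train$info$label, hyper = config$hyper,
                         seed = seed)
  test <- cohortSamaFeaturesFromBasis(testCohort, train$basis)
  pred <- predictFog(model, test$X)
  m <- windowMetrics(pred$label, test$info$label, scores = pred$score)
  list(metrics = m[c("sensitivity", "specificity", "accuracy", "auc")],
       per_subject = perSubjectMetrics(test$info, test$info$label,
                                       pred$label, pred$score))
}

#' Compare methods with paired per-subject Wilcoxon tests
#'
#' Pairs the per-subject sensitivity/specificity/accuracy of two or more
#' methods evaluated on the same subjects and reports median differences
#' and exact Wilcoxon signed-rank p-values of every method against the
#' first.
#'
#' @param perSubject named list of data.frames (subject, sensitivity,
#'   specificity, accuracy), one per method, same subjects in each
#' @return data.frame of method, metric, median, median_diff, p_value
#' @export
compareMethods <- function(perSubject) {
  stopifnot(length(perSubject) >= 2L)
  ref <- perSubject[[1]]
  ref <- ref[order(ref$subject), ]
  out <- list()
  for (nm in names(perSubject)) {
    tab <- perSubject[[nm]]
    tab <- tab[order(tab$subject), ]
    if (!identical(tab$subject, ref$subject))
      stop("subject mismatch between method reports: ", nm)
    for (metric in c("sensitivity", "specificity", "accuracy")) {
      d <- ref[[metric]] - tab[[metric]]
      p <- if (nm == names(perSubject)[1]) 1 else signedRankP(d)
      out[[length(out) + 1L]] <- data.frame(
        method = nm, metric = metric, median = stats::median(tab[[metric]]),
        median_diff_vs_first = stats::median(d), p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# two-sided Wilcoxon signed-rank p on paired differences, zeros dropped,
# exact when untied
signedRankP <- function(d) {
  d <- d[d != 0]
  if (!length(d)) return(1)
  exact <- !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact)$p.value)
}
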