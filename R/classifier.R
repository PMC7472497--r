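# SVM-RBF window classifier with leave-one-patient-out (LOPO) validation.
# Features are z-scored with training-set statistics (RBF kernels need
# comparable scales); the continuous score is the signed distance to the
# decision boundary, oriented so that larger means more FOG-like.

#' Train the window-level SVM-RBF classifier
#'
#' @param X windows x features matrix with named columns
#' @param labels "FOG"/"nonFOG" per row (both classes required)
#' @param ids feature ids to use (default: all columns)
#' @param hyper list(cost, gamma); \code{gamma = NULL} uses the
#'   1/(d * mean variance) heuristic on the standardized features
#' @param seed integer recorded in the model (training itself is
#'   deterministic)
#' @return a \linkS4class{FogModel}
#' @export
trainFogModel <- function(X, labels, ids = colnames(X),
                          hyper = list(cost = 1, gamma = NULL), seed = 1L) {
  if (length(unique(labels)) < 2L) stop("both classes required for training")
  M <- X[, ids, drop = FALSE]
  ctr <- colMeans(M)
  scl <- apply(M, 2L, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(M, center = ctr, scale = scl)
  y <- factor(labels, levels = c("nonFOG", "FOG"))
  gamma <- hyper$gamma
  if (is.null(gamma)) gamma <- 1 / (ncol(Z) * max(mean(apply(Z, 2, stats::var)),
                                                  1e-12))
  fit <- withSeed(seed,
    e1071::svm(Z, y, kernel = "radial", cost = hyper$cost, gamma = gamma,
               scale = FALSE))
  # orient decision values so larger = more FOG-like
  dv <- drop(attr(stats::predict(fit, Z, decision.values = TRUE),
                  "decision.values"))
  orient <- if (mean(dv[y == "FOG"]) >= mean(dv[y == "nonFOG"])) 1 else -1
  new("FogModel", featureIds = ids, center = ctr, scale = scl, fit = fit,
      orientation = orient, hyper = list(cost = hyper$cost, gamma = gamma),
      subjects = as.character(unique(rownames(X))), seed = as.integer(seed))
}

#' Predict window labels and scores
#'
#' @param model a \linkS4class{FogModel}
#' @param X windows x features matrix containing the model's feature ids
#'   (any column order; matched by name)
#' @return list(label, score): predicted labels and oriented continuous
#'   scores
#' @export
predictFog <- function(model, X) {
  Z <- scale(X[, model@featureIds, drop = FALSE], center = model@center,
             scale = model@scale)
  pred <- stats::predict(model@fit, Z, decision.values = TRUE)
  score <- model@orientation * drop(attr(pred, "decision.values"))
  list(label = as.character(pred), score = unname(score))
}

# ---- ROC utilities --------------------------------------------------------

#' Empirical ROC curve from scores
#'
#' @param scores continuous scores, larger = more FOG-like
#' @param truth "FOG"/"nonFOG" truth per score
#' @return data.frame(fpr, tpr) stepping through every threshold
#' @export
rocCurve <- function(scores, truth) {
  pos <- truth == "FOG"
  nP <- sum(pos); nN <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # collapse tied scores to one point
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tpr <- c(0, tp[keep] / max(nP, 1L))
  fpr <- c(0, fp[keep] / max(nN, 1L))
  data.frame(fpr = fpr, tpr = tpr)
}

#' Area under an ROC curve (trapezoid)
#'
#' @param roc data.frame(fpr, tpr) as from \code{\link{rocCurve}}
#' @export
aucTrapezoid <- function(roc) {
  pracma::trapz(roc$fpr, roc$tpr)
}

#' Vertically average ROC curves over a fixed specificity grid
#'
#' Sensitivity is interpolated at each grid false-positive rate in every
#' fold and averaged across folds.
#'
#' @param rocs list of per-fold ROC data.frames
#' @param grid false-positive-rate grid
#' @return data.frame(fpr, tpr) of the mean curve
#' @export
meanRoc <- function(rocs, grid = seq(0, 1, by = 0.01)) {
  tprAt <- vapply(rocs, function(r) {
    stats::approx(r$fpr, r$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(as.matrix(tprAt)))
}

#' Optimal operating point of an ROC curve
#'
#' The point minimizing the Euclidean distance to the ideal corner (0, 1).
#'
#' @param roc data.frame(fpr, tpr)
#' @return named numeric c(fpr, tpr)
#' @export
rocOptimalPoint <- function(roc) {
  d <- sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
  i <- which.min(d)
  c(fpr = roc$fpr[i], tpr = roc$tpr[i])
}

# ---- LOPO -----------------------------------------------------------------

#' Leave-one-patient-out validation with per-fold feature selection
#'
#' For each subject: run screening, MRMR ranking and feature-count choice
#' on all other subjects' windows, train the SVM, and evaluate the
#' held-out subject's windows. A held-out subject with no FOG windows gets
#' sensitivity 100% by convention.
#'
#' @param X windows x features matrix (named columns)
#' @param labels per-window labels
#' @param subjects per-window subject ids
#' @param selection TRUE to run per-fold feature selection, or a character
#'   vector of feature ids to use in every fold
#' @param hyper list(cost, gamma)
#' @param nFolds inner folds for the feature-count choice
#' @param kMax cap on the feature-count search
#' @param seed root seed (per-fold seeds derived from it)
#' @return list with per-fold metrics, selections, rankings, mean metrics,
#'   mean ROC and AUC
#' @export
lopoValidate <- function(X, labels, subjects, selection = TRUE,
                         hyper = list(cost = 1, gamma = NULL), nFolds = 5L,
                         kMax = Inf, seed = 1L) {
  subj <- unique(subjects)
  if (length(subj) < 3L) stop("need at least 3 subjects for LOPO")
  folds <- list()
  for (s in subj) {
    heldOut <- subjects == s
    if (!any(heldOut)) next
    Xtr <- X[!heldOut, , drop = FALSE]
    ytr <- labels[!heldOut]
    str <- subjects[!heldOut]
    if (isTRUE(selection)) {
      sel <- selectFeatures(Xtr, ytr, str, nFolds = nFolds, kMax = kMax,
                            hyper = hyper, seed = seed + match(s, subj))
      ids <- sel$chosen_ids
      ranking <- sel$mrmr_ranking
    } else {
      ids <- selection
      ranking <- selection
    }
    if (!length(ids)) {
      warning("fold ", s, ": empty selection, using all features")
      ids <- colnames(X)
      ranking <- ids
    }
    model <- trainFogModel(Xtr, ytr, ids, hyper = hyper, seed = seed)
    pred <- predictFog(model, X[heldOut, , drop = FALSE])
    m <- windowMetrics(pred$label, labels[heldOut], scores = pred$score)
    folds[[s]] <- list(subject = s, metrics = m, chosen_ids = ids,
                       ranking = ranking, n_windows = sum(heldOut))
  }
  sens <- vapply(folds, function(f) f$metrics$sensitivity, numeric(1))
  spec <- vapply(folds, function(f) f$metrics$specificity, numeric(1))
  acc <- vapply(folds, function(f) f$metrics$accuracy, numeric(1))
  rocs <- lapply(folds, function(f) f$metrics$roc)
  rocs <- rocs[!vapply(rocs, is.null, logical(1))]
  mroc <- if (length(rocs)) meanRoc(rocs) else NULL
  list(folds = folds,
       selections = lapply(folds, `[[`, "chosen_ids"),
       rankings = lapply(folds, `[[`, "ranking"),
       mean_metrics = list(
         sensitivity = mean(sens), sensitivity_sd = stats::sd(sens),
         specificity = mean(spec), specificity_sd = stats::sd(spec),
         accuracy = mean(acc), accuracy_sd = stats::sd(acc)),
       mean_roc = mroc,
       auc = if (!is.null(mroc)) aucTrapezoid(mroc) else NA_real_,
       oop = if (!is.null(mroc)) rocOptimalPoint(mroc) else NULL)
}

#' Build the final model from LOPO fold selections
#'
#' Ranks features by their commonness across the LOPO folds, chooses the
#' count minimizing misclassification error on inner subject-wise folds of
#' the whole training cohort, and trains on all training subjects.
#'
#' @param X training windows x features matrix
#' @param labels,subjects per-window labels and subject ids
#' @param lopo result of \code{\link{lopoValidate}} (its per-fold
#'   selections and rankings)
#' @param hyper,nFolds,kMax,seed as in \code{\link{lopoValidate}}
#' @return list(model, commonness, error_curve, chosen_k, chosen_ids)
#' @export
buildFinalModel <- function(X, labels, subjects, lopo,
                            hyper = list(cost = 1, gamma = NULL),
                            nFolds = 5L, kMax = Inf, seed = 1L) {
  ranking <- commonnessRank(lopo$selections, lopo$rankings)
  if (!length(ranking)) stop("empty commonness ranking")
  cc <- chooseFeatureCount(X, labels, subjects, ranking, nFolds = nFolds,
                           kMax = kMax, hyper = hyper, seed = seed)
  model <- trainFogModel(X, labels, cc$chosen_ids, hyper = hyper,
                         seed = seed)
  list(model = model, commonness = ranking, error_curve = cc$error_curve,
       chosen_k = cc$chosen_k, chosen_ids = cc$chosen_ids)
}
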