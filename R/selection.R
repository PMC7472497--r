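# Three-stage feature selection: Bonferroni-corrected Welch t-test
# screening, greedy MRMR ranking (MID scheme with discretized mutual
# information), and misclassification-error-minimizing choice of the
# feature count on inner subject-wise folds. The commonness ranking
# aggregates per-fold selections for the final model.

welchP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(if (m1 == m2) 1 else 0)
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(tstat), df)
}

#' Screen features by Welch t-test with Bonferroni correction
#'
#' Retains features whose two-sample Welch t-test separates FOG from
#' non-FOG windows at \code{alpha / bonferroniN}. The Bonferroni
#' denominator stays fixed at the full manifest size (86) regardless of how
#' many features are tested. Features that are constant overall are
#' excluded (undefined t statistic).
#'
#' @param X numeric matrix, windows x features, columns named by feature id
#' @param labels character/factor vector, "FOG"/"nonFOG" per row
#' @param alpha family-wise level
#' @param bonferroniN Bonferroni denominator
#' @return character vector of retained feature ids (input column order)
#' @export
screenTTest <- function(X, labels, alpha = 0.05, bonferroniN = 86) {
  isFog <- labels == "FOG"
  if (sum(isFog) < 2L || sum(!isFog) < 2L)
    stop("need at least two windows per class")
  p <- apply(X, 2L, function(col) welchP(col[isFog], col[!isFog]))
  colnames(X)[p <= alpha / bonferroniN]
}

# equal-frequency discretization into at most nBins bins
discretize <- function(x, nBins = 10L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1)))
  if (length(br) < 2L) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

mutualInfo <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
}

#' Greedy MRMR feature ranking (MID scheme)
#'
#' Ranks features by mutual information with the label minus the mean
#' mutual information with already-selected features, using equal-frequency
#' 10-bin discretization. The first feature is the most relevant one; ties
#' keep input order.
#'
#' @param X numeric matrix, windows x features, named columns
#' @param labels class labels per row
#' @param ids feature ids to rank (default: all columns)
#' @param nBins discretization bins
#' @return character vector: permutation of \code{ids} in MRMR order
#' @export
mrmrRank <- function(X, labels, ids = colnames(X), nBins = 10L) {
  if (!length(ids)) return(character(0))
  D <- lapply(ids, function(id) discretize(X[, id], nBins))
  names(D) <- ids
  y <- as.integer(factor(labels))
  rel <- vapply(D, mutualInfo, numeric(1), b = y)
  nId <- length(ids)
  selected <- character(0)
  remaining <- ids
  redSum <- stats::setNames(numeric(nId), ids)  # sum of MI with selected
  while (length(remaining)) {
    score <- if (!length(selected)) rel[remaining]
    else rel[remaining] - redSum[remaining] / length(selected)
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      redSum[remaining] <- redSum[remaining] +
        vapply(remaining, function(id) mutualInfo(D[[id]], D[[pick]]),
               numeric(1))
  }
  selected
}

#' Choose the feature count by minimum misclassification error
#'
#' For k = 1..length(ranking), trains an SVM-RBF on the first k ranked
#' features and measures mean window misclassification error on inner
#' subject-wise folds; the k with minimum mean error wins, ties going to
#' the smallest k.
#'
#' @param X windows x features matrix (named columns)
#' @param labels per-window labels ("FOG"/"nonFOG")
#' @param subjects per-window subject ids (folds never split a subject)
#' @param ranking ordered feature ids (from \code{\link{mrmrRank}})
#' @param nFolds inner fold count (capped at the number of subjects)
#' @param kMax optional cap on the largest k examined
#' @param hyper list(cost, gamma) passed to the SVM (gamma NULL for the
#'   1/(d * var) default)
#' @param seed integer controlling the fold assignment
#' @return list(error_curve, chosen_k, chosen_ids)
#' @export
chooseFeatureCount <- function(X, labels, subjects, ranking, nFolds = 5L,
                               kMax = Inf, hyper = list(cost = 1, gamma = NULL),
                               seed = 1L) {
  if (!length(ranking)) stop("empty ranking")
  subj <- unique(subjects)
  if (length(subj) < 2L) stop("need at least 2 subjects for inner folds")
  nFolds <- min(nFolds, length(subj))
  rs <- withSeed(seed, sample(length(subj)))
  foldOf <- stats::setNames(rep(seq_len(nFolds), length.out = length(subj))[rs],
                            subj)
  ks <- seq_len(min(length(ranking), kMax))
  err <- rep(NA_real_, length(ks))
  for (ki in seq_along(ks)) {
    ids <- ranking[seq_len(ks[ki])]
    foldErr <- rep(NA_real_, nFolds)
    for (f in seq_len(nFolds)) {
      testIdx <- foldOf[subjects] == f
      if (!any(testIdx) || length(unique(labels[!testIdx])) < 2L) next
      model <- trainFogModel(X[!testIdx, , drop = FALSE], labels[!testIdx],
                             ids, hyper = hyper, seed = seed)
      pred <- predictFog(model, X[testIdx, , drop = FALSE])$label
      foldErr[f] <- mean(pred != labels[testIdx])
    }
    err[ki] <- mean(foldErr, na.rm = TRUE)
  }
  chosen <- ks[which.min(err)]  # which.min takes the first (smallest k) tie
  list(error_curve = stats::setNames(err, ks), chosen_k = chosen,
       chosen_ids = ranking[seq_len(chosen)])
}

#' Run the full three-stage selection
#'
#' Screen by Bonferroni t-tests, rank the survivors by MRMR, then choose
#' the count minimizing inner-fold misclassification error.
#'
#' @inheritParams chooseFeatureCount
#' @param bonferroniN Bonferroni denominator for the screen
#' @return list(screened_ids, mrmr_ranking, error_curve, chosen_k,
#'   chosen_ids)
#' @export
selectFeatures <- function(X, labels, subjects, bonferroniN = 86,
                           nFolds = 5L, kMax = Inf,
                           hyper = list(cost = 1, gamma = NULL), seed = 1L) {
  screened <- screenTTest(X, labels, bonferroniN = bonferroniN)
  if (!length(screened))
    return(list(screened_ids = character(0), mrmr_ranking = character(0),
                error_curve = numeric(0), chosen_k = 0L,
                chosen_ids = character(0)))
  ranking <- mrmrRank(X, labels, screened)
  cc <- chooseFeatureCount(X, labels, subjects, ranking, nFolds = nFolds,
                           kMax = kMax, hyper = hyper, seed = seed)
  c(list(screened_ids = screened, mrmr_ranking = ranking), cc)
}

#' Rank features by commonness across fold selections
#'
#' Orders ids by how often they were chosen across leave-one-patient-out
#' folds (descending); ties are broken by mean MRMR rank across the folds'
#' rankings, then lexicographically.
#'
#' @param selections list of character vectors (chosen ids per fold)
#' @param rankings optional list of full MRMR rankings per fold, for the
#'   tie-break
#' @return character vector of ids in commonness order
#' @export
commonnessRank <- function(selections, rankings = NULL) {
  ids <- unique(unlist(selections))
  if (!length(ids)) return(character(0))
  freq <- vapply(ids, function(id)
    sum(vapply(selections, function(s) id %in% s, logical(1))), numeric(1))
  meanRank <- vapply(ids, function(id) {
    if (is.null(rankings)) return(NA_real_)
    r <- vapply(rankings, function(rk) {
      pos <- match(id, rk)
      if (is.na(pos)) length(rk) + 1 else pos
    }, numeric(1))
    mean(r)
  }, numeric(1))
  meanRank[is.na(meanRank)] <- Inf
  ids[order(-freq, meanRank, ids)]
}

# evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
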