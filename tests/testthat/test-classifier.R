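test_that("the SVM fits separable and XOR data and is deterministic", {
  set.seed(20)
  n <- 200
  labels <- rep(c("FOG", "nonFOG"), each = n / 2)
  X <- cbind(f1 = (labels == "FOG") * 4 + rnorm(n, sd = 0.3),
             f2 = rnorm(n))
  m <- trainFogModel(X, labels)
  expect_equal(mean(predictFog(m, X)$label == labels), 1.0)
  m2 <- trainFogModel(X, labels)
  expect_identical(predictFog(m2, X)$score, predictFog(m, X)$score)

  # XOR: radial kernel fits what a linear boundary cannot
  xor <- expand.grid(a = c(0, 1), b = c(0, 1))[rep(1:4, 50), ]
  xorX <- as.matrix(xor) + rnorm(400, sd = 0.05)
  xorY <- ifelse(xor(xor$a > 0.5, xor$b > 0.5), "FOG", "nonFOG")
  mx <- trainFogModel(xorX, xorY)
  expect_gt(mean(predictFog(mx, xorX)$label == xorY), 0.9)

  expect_error(trainFogModel(X, rep("FOG", n)), "class")
})

test_that("predictions are invariant under feature-column permutation", {
  set.seed(21)
  d <- plantedFeatures()
  m <- trainFogModel(d$X, d$labels)
  perm <- d$X[, sample(ncol(d$X))]
  expect_identical(predictFog(m, d$X)$score, predictFog(m, perm)$score)
})

test_that("a JSON round-tripped model reproduces in-memory predictions", {
  set.seed(22)
  d <- plantedFeatures()
  m <- trainFogModel(d$X, d$labels, ids = c("signal1", "noise1", "noise2"))
  path <- file.path(withr::local_tempdir(), "model.json")
  writeModelJson(m, path)
  m2 <- readModelJson(path)
  p1 <- predictFog(m, d$X)
  p2 <- predictFogJson(m2, d$X)
  expect_equal(p2$score, p1$score, tolerance = 1e-10)
  expect_equal(p2$label, p1$label)
})

test_that("ROC utilities match a reference AUC and find the ideal corner", {
  scores <- c(0.9, 0.8, 0.4, 0.35, 0.2)
  truth <- c("FOG", "FOG", "nonFOG", "FOG", "nonFOG")
  roc <- rocCurve(scores, truth)
  expect_equal(aucTrapezoid(roc),
               as.numeric(pROC::auc(pROC::roc(
                 response = truth, predictor = scores, levels = c("nonFOG", "FOG"),
                 direction = "<", quiet = TRUE))))
  perfect <- rocCurve(c(3, 2, 1, -1, -2), c("FOG", "FOG", "FOG", "nonFOG", "nonFOG"))
  expect_equal(aucTrapezoid(perfect), 1.0)
  expect_equal(rocOptimalPoint(perfect), c(fpr = 0, tpr = 1))
})

test_that("LOPO never trains on the held-out subject and honors the sensitivity convention", {
  set.seed(23)
  d <- plantedFeatures(nPerSubject = 30, nSubjects = 5, sep = 4)
  # one subject with no FOG windows at all
  d$labels[d$subjects == "p5"] <- "nonFOG"
  d$X[d$subjects == "p5", "signal1"] <- rnorm(sum(d$subjects == "p5"))
  lopo <- lopoValidate(d$X, d$labels, d$subjects,
                       selection = c("signal1", "noise1"), seed = 5)
  expect_equal(lopo$folds[["p5"]]$metrics$sensitivity, 100)
  # no-leakage: refitting without the held-out subject reproduces the fold
  hold <- d$subjects == "p2"
  m <- trainFogModel(d$X[!hold, ], d$labels[!hold],
                     ids = c("signal1", "noise1"), seed = 5)
  p <- predictFog(m, d$X[hold, ])
  mFold <- windowMetrics(p$label, d$labels[hold], p$score)
  expect_equal(lopo$folds[["p2"]]$metrics$accuracy, mFold$accuracy)
  # reproducibility: same seed, same report
  lopo2 <- lopoValidate(d$X, d$labels, d$subjects,
                        selection = c("signal1", "noise1"), seed = 5)
  expect_identical(lopo2$mean_metrics, lopo$mean_metrics)
})

test_that("the final model reuses fold selections and searches k up to their union", {
  set.seed(24)
  d <- plantedFeatures(nPerSubject = 30, nSubjects = 5, sep = 4)
  lopo <- lopoValidate(d$X, d$labels, d$subjects, selection = TRUE,
                       kMax = 4, seed = 7)
  final <- buildFinalModel(d$X, d$labels, d$subjects, lopo, kMax = 4,
                           seed = 7)
  expect_true(all(final$chosen_ids %in% final$commonness))
  expect_equal(final$chosen_k, length(final$chosen_ids))
  expect_equal(featureIds(final$model), final$chosen_ids)
  # the planted feature dominates every fold, hence the commonness ranking
  expect_equal(final$commonness[1], "signal1")
})
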