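# JSON serialization of a trained model: standardization recipe, selected
# feature ids, and the RBF support-vector payload (support vectors in the
# standardized space, dual coefficients, offset). The loaded model
# evaluates the decision function directly, so a round-tripped model
# reproduces the in-memory predictions.

#' Serialize a trained model to JSON
#'
#' @param model a \linkS4class{FogModel}
#' @param path output path
#' @export
writeModelJson <- function(model, path) {
  fit <- model@fit
  payload <- list(
    feature_ids = model@featureIds,
    center = as.list(model@center),
    scale = as.list(model@scale),
    orientation = model@orientation,
    hyper = model@hyper,
    svm = list(sv = unname(as.matrix(fit$SV)),
               coefs = as.numeric(fit$coefs),
               rho = fit$rho,
               gamma = fit$gamma))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a JSON-serialized model
#'
#' @param path JSON file from \code{\link{writeModelJson}}
#' @return a list usable with \code{\link{predictFogJson}}
#' @export
readModelJson <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$center <- unlist(m$center)
  m$scale <- unlist(m$scale)
  m$svm$sv <- as.matrix(m$svm$sv)
  m
}

#' Predict with a JSON-loaded model
#'
#' Evaluates the RBF decision function from the serialized support-vector
#' payload; equivalent to \code{\link{predictFog}} on the original model.
#'
#' @param model list from \code{\link{readModelJson}}
#' @param X windows x features matrix containing the model's feature ids
#' @return list(label, score)
#' @export
predictFogJson <- function(model, X) {
  Z <- scale(X[, model$feature_ids, drop = FALSE], center = model$center,
             scale = model$scale)
  sv <- model$svm$sv
  gamma <- model$svm$gamma
  dv <- vapply(seq_len(nrow(Z)), function(i) {
    d2 <- rowSums((sv - matrix(Z[i, ], nrow(sv), ncol(sv),
                               byrow = TRUE))^2)
    sum(model$svm$coefs * exp(-gamma * d2)) - model$svm$rho
  }, numeric(1))
  score <- model$orientation * dv
  list(label = ifelse(score > 0, "FOG", "nonFOG"), score = score)
}

#' Serialize a window set to JSON
#'
#' @param windows a \linkS4class{WindowSet}
#' @param path output path
#' @export
writeWindowsJson <- function(windows, path) {
  jsonlite::write_json(
    list(role = windows@role, length_s = windows@lengthS,
         trial_duration_s = windows@trialDuration,
         windows = windowInfo(windows)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a window set from JSON
#'
#' @param path file from \code{\link{writeWindowsJson}}
#' @return a \linkS4class{WindowSet}
#' @export
readWindowsJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- as.data.frame(x$windows)
  if (!nrow(w))
    w <- data.frame(start_s = numeric(0), label = character(0),
                    fog_overlap_s = numeric(0))
  new("WindowSet", windows = w[, c("start_s", "label", "fog_overlap_s")],
      role = x$role, lengthS = x$length_s,
      trialDuration = x$trial_duration_s)
}
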