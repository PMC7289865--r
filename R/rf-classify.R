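#' @importFrom randomForest randomForest
NULL

# Regression-mode forest on a 0/1 target: the class-probability vote is
# the prediction and its squared error is the "MSE" that both leaf-size
# tuning and permutation importance are defined on.
fitForest <- function(X, y, ntree = 500, nodesize = 5, importance = FALSE) {
  # regression mode on a 0/1 target is intentional; randomForest warns
  suppressWarnings(randomForest::randomForest(
    x = as.data.frame(X), y = as.numeric(y),
    ntree = ntree, nodesize = nodesize, importance = importance,
    keep.forest = TRUE
  ))
}

#' Tune the minimum leaf size of the forest
#'
#' Fits one forest per candidate leaf size and returns the candidate with
#' the lowest out-of-bag MSE of the class-probability vote. Candidates
#' not smaller than the number of subjects are skipped as infeasible.
#'
#' @param X subjects x features matrix.
#' @param y binary labels (1 = ataxic).
#' @param candidates leaf sizes to try (default 5, 10, 20, 50, 100).
#' @param ntree ensemble size.
#' @param seed RNG seed.
#' @return the selected leaf size.
#' @export
tuneLeafSize <- function(X, y, candidates = c(5, 10, 20, 50, 100),
                         ntree = 500, seed = 1) {
  if (nrow(X) < 10) stop("need at least 10 subjects")
  feasible <- candidates[candidates < nrow(X)]
  if (!length(feasible)) stop("no feasible leaf-size candidate")
  oob <- vapply(feasible, function(ns) {
    withSubSeed(seed, ns, {
      rf <- fitForest(X, y, ntree = ntree, nodesize = ns)
      rf$mse[length(rf$mse)]
    })
  }, numeric(1))
  feasible[which.min(oob)]
}

#' Leave-one-out cross-validated forest predictions
#'
#' One fold per subject: a forest trained on the remaining n - 1 subjects
#' predicts the held-out subject's class-probability vote, thresholded at
#' 0.5. Subjects are processed in sorted-identifier order with per-fold
#' seed substreams, so the predictions do not depend on the row order of
#' the input.
#'
#' @param X subjects x features matrix with subject ids as row names.
#' @param y binary labels (1 = ataxic), aligned with \code{X} rows.
#' @param nodesize minimum leaf size.
#' @param ntree ensemble size.
#' @param seed RNG seed.
#' @return list with \code{pred} (0/1 per subject), \code{prob}
#'   (class-probability votes) and \code{y} (true labels), all in
#'   sorted-id order.
#' @export
looCrossValidate <- function(X, y, nodesize = 5, ntree = 500, seed = 1) {
  n <- nrow(X)
  if (n < 4) stop("need at least 4 subjects")
  if (length(unique(y)) < 2) stop("both classes must be present")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("row%04d", seq_len(n))
  ord <- order(ids)
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  ids <- ids[ord]
  prob <- numeric(n)
  for (i in seq_len(n)) {
    prob[i] <- withSubSeed(seed, 300 + i, {
      rf <- fitForest(X[-i, , drop = FALSE], y[-i], ntree = ntree,
                      nodesize = nodesize)
      as.numeric(stats::predict(rf, X[i, , drop = FALSE]))
    })
  }
  list(
    pred = stats::setNames(as.integer(prob >= 0.5), ids),
    prob = stats::setNames(prob, ids),
    y = stats::setNames(as.integer(y), ids)
  )
}

#' Binary classification metrics
#'
#' Precision, recall, F1, accuracy and the Matthews correlation
#' coefficient of a binary prediction, with the ataxic class (1) as the
#' positive class. Ratios with an empty denominator are reported as 0
#' with a warning; the F1 is the harmonic mean of precision and recall.
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return list with \code{precision}, \code{recall}, \code{f1},
#'   \code{accuracy}, \code{mcc} and the confusion counts \code{tp},
#'   \code{fp}, \code{fn}, \code{tn}.
#' @export
binaryMetrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (empty denominator); reported 0")
      0
    } else {
      num / den
    }
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  mccDen <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mccDen == 0) 0 else (tp * tn - fp * fn) / mccDen
  list(
    precision = precision, recall = recall, f1 = f1,
    accuracy = (tp + tn) / length(y_true), mcc = mcc,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

#' Out-of-bag permutation importance of the forest features
#'
#' For each feature, the out-of-bag MSE increase caused by permuting that
#' feature's values is averaged over the trees of the ensemble and
#' divided by its standard deviation over the trees. Negative values mean
#' the permutation worked as well or better, i.e. the feature plays no
#' role. A constant feature scores exactly 0.
#'
#' @param X subjects x features matrix.
#' @param y binary labels.
#' @param nodesize,ntree forest settings.
#' @param seed RNG seed.
#' @return data.frame with \code{feature}, \code{importance} and
#'   \code{rank} (1 = most important), sorted by rank.
#' @export
permutationImportance <- function(X, y, nodesize = 5, ntree = 500, seed = 1) {
  rf <- withSubSeed(seed, 77, {
    fitForest(X, y, ntree = ntree, nodesize = nodesize, importance = TRUE)
  })
  meanInc <- rf$importance[, "%IncMSE"] # per-tree mean MSE increase
  sdOverTrees <- rf$importanceSD * sqrt(ntree) # importanceSD is SE over trees
  imp <- ifelse(sdOverTrees > 0, meanInc / sdOverTrees, 0)
  out <- data.frame(
    feature = colnames(X), importance = as.numeric(imp),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$importance, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Retain only features with positive importance (Subset 1)
#'
#' @param importances data.frame from
#'   \code{\link{permutationImportance}}.
#' @return character vector of features with importance > 0, in rank
#'   order.
#' @export
subset1Filter <- function(importances) {
  importances$feature[importances$importance > 0]
}

#' Greedy forward subset over ranked features (Subset 2)
#'
#' Adds features one by one in decreasing importance order and evaluates
#' the leave-one-out accuracy of each prefix; stops at the first addition
#' that does not strictly improve the accuracy. Returns the optimal
#' prefix with its classification report.
#'
#' @param X subjects x features matrix.
#' @param y binary labels.
#' @param importances ranked importance table.
#' @param nodesize,ntree,seed forest settings.
#' @return list with \code{features}, \code{report} (the
#'   \code{\link{binaryMetrics}} of the selected prefix), and
#'   \code{accuracy_path}.
#' @export
greedySubset2 <- function(X, y, importances, nodesize = 5, ntree = 500,
                          seed = 1) {
  ranked <- importances$feature
  best <- NULL
  bestAcc <- -Inf
  path <- numeric(0)
  for (k in seq_along(ranked)) {
    cv <- looCrossValidate(X[, ranked[seq_len(k)], drop = FALSE], y,
                           nodesize = nodesize, ntree = ntree, seed = seed)
    rep <- binaryMetrics(cv$y, cv$pred)
    path <- c(path, rep$accuracy)
    if (rep$accuracy > bestAcc) {
      bestAcc <- rep$accuracy
      best <- list(features = ranked[seq_len(k)], report = rep)
    } else {
      break
    }
  }
  c(best, list(accuracy_path = path))
}
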