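#' Label-powerset encoding of a multilabel matrix
#'
#' Maps each row of a subjects x 5 binary domain-label matrix
#' (speech, upper limb, lower limb, gait, balance) to a single class id,
#' turning the multilabel problem into one multiclass problem over the
#' observed label combinations. \code{powersetDecode} inverts the
#' encoding; decoding an id that was never encoded is an error.
#'
#' @param labels binary matrix or data.frame with 5 columns.
#' @return \code{powersetEncode}: factor of class ids (the id string is
#'   the 0/1 pattern, e.g. \code{"10100"} for speech and lower limb
#'   affected). \code{powersetDecode}: the binary label matrix.
#' @export
powersetEncode <- function(labels) {
  labels <- as.matrix(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  factor(apply(labels, 1, paste0, collapse = ""))
}

#' @rdname powersetEncode
#' @param ids factor or character vector of class ids.
#' @export
powersetDecode <- function(ids) {
  ids <- as.character(ids)
  if (!all(grepl("^[01]{5}$", ids))) {
    stop("unseen or malformed powerset class id")
  }
  out <- t(vapply(strsplit(ids, ""), function(s) as.integer(s),
                  integer(5)))
  colnames(out) <- DOMAIN_IDS
  out
}

#' Iteratively stratified k-fold assignment for multilabel data
#'
#' Greedy fold assignment preserving per-label proportions: labels are
#' processed rarest first and each remaining subject carrying the label
#' goes to the fold with the largest remaining desire for that label
#' (ties: largest overall remaining capacity, then lowest fold index).
#' Subjects with no labels are dealt to the emptiest folds.
#'
#' @param labels subjects x 5 binary matrix.
#' @param k number of folds (k <= n).
#' @param seed RNG seed (order randomisation within ties).
#' @return integer fold id (1..k) per subject.
#' @export
iterativeStratifiedFolds <- function(labels, k, seed = 1) {
  labels <- as.matrix(labels)
  n <- nrow(labels)
  if (k > n) stop("k must not exceed the number of subjects")
  withSubSeed(seed, 5, {
    fold <- rep(NA_integer_, n)
    capacity <- rep(floor(n / k), k) + (seq_len(k) <= n %% k)
    # desired per-fold label counts proportional to fold sizes
    desire <- outer(capacity / n, colSums(labels))
    remaining <- function() which(is.na(fold))
    while (length(remaining())) {
      rem <- remaining()
      cnt <- colSums(labels[rem, , drop = FALSE])
      if (all(cnt == 0)) {
        # label-free leftovers: spread over folds with most capacity
        for (i in rem[sample.int(length(rem))]) {
          f <- which.max(capacity)
          fold[i] <- f
          capacity[f] <- capacity[f] - 1
        }
        break
      }
      l <- which(cnt == min(cnt[cnt > 0]) & cnt > 0)[1]
      subj <- rem[labels[rem, l] == 1]
      subj <- subj[sample.int(length(subj))]
      for (i in subj) {
        cand <- which(capacity > 0)
        if (!length(cand)) cand <- seq_len(k)
        f <- cand[order(-desire[cand, l], -capacity[cand], cand)][1]
        fold[i] <- f
        capacity[f] <- capacity[f] - 1
        desire[f, ] <- desire[f, ] - labels[i, ]
      }
    }
    fold
  })
}

# fit/predict one base multiclass classifier on powerset classes
fitPredictMulticlass <- function(Xtr, ytr, Xte, algorithm, seed) {
  ytr <- droplevels(ytr)
  if (nlevels(ytr) == 1L) {
    return(factor(rep(levels(ytr), nrow(Xte)), levels = levels(ytr)))
  }
  withSubSeed(seed, 11, switch(algorithm,
    random_forest = {
      rf <- randomForest::randomForest(x = as.data.frame(Xtr), y = ytr,
                                       ntree = 500)
      stats::predict(rf, as.data.frame(Xte))
    },
    decision_tree = {
      d <- as.data.frame(Xtr)
      d$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = d,
                          control = rpart::rpart.control(minsplit = 4))
      stats::predict(fit, as.data.frame(Xte), type = "class")
    },
    knn = {
      class::knn(Xtr, Xte, cl = ytr, k = min(5, nrow(Xtr)))
    },
    mlp = {
      capture.output(fit <- nnet::nnet(
        x = Xtr, y = stats::model.matrix(~ 0 + ytr),
        size = 32, maxit = 300, softmax = TRUE, trace = FALSE,
        MaxNWts = 100000
      ))
      lv <- levels(ytr)
      factor(lv[apply(stats::predict(fit, Xte), 1, which.max)], levels = lv)
    },
    stop("unknown algorithm id: ", algorithm)
  ))
}

#' Cross-validated multilabel classification via the label powerset
#'
#' Encodes the domain-label matrix into powerset classes, fits the chosen
#' base multiclass classifier per fold of an iteratively stratified
#' cross-validation, decodes the predictions back into domain labels and
#' reports per-domain precision/recall/F1/accuracy plus their
#' arithmetic-mean "general" aggregates.
#'
#' @param X subjects x features matrix.
#' @param labels subjects x 5 binary domain-label matrix.
#' @param algorithm \code{"random_forest"}, \code{"decision_tree"},
#'   \code{"knn"} or \code{"mlp"}.
#' @param k number of folds (default n, i.e. leave-one-out).
#' @param seed RNG seed.
#' @return list with \code{per_domain} (data.frame), the Eq-style
#'   aggregates \code{general_precision}, \code{general_recall},
#'   \code{general_f1}, \code{general_accuracy}, and
#'   \code{predicted_labels}.
#' @export
multilabelCV <- function(X, labels,
                         algorithm = c("random_forest", "decision_tree",
                                       "knn", "mlp"),
                         k = nrow(X), seed = 1) {
  algorithm <- match.arg(algorithm)
  labels <- as.matrix(labels)
  classes <- powersetEncode(labels)
  if (nlevels(classes) < 2) stop("need at least 2 observed powerset classes")
  fold <- iterativeStratifiedFolds(labels, k, seed = seed)
  predClass <- factor(rep(NA_character_, nrow(X)), levels = levels(classes))
  for (f in sort(unique(fold))) {
    te <- fold == f
    predClass[te] <- fitPredictMulticlass(
      X[!te, , drop = FALSE], classes[!te], X[te, , drop = FALSE],
      algorithm, subSeed(seed, 900 + f)
    )
  }
  predLabels <- powersetDecode(predClass)
  per <- do.call(rbind, lapply(seq_along(DOMAIN_IDS), function(j) {
    m <- suppressWarnings(binaryMetrics(labels[, j], predLabels[, j]))
    data.frame(
      domain = DOMAIN_IDS[j], precision = m$precision, recall = m$recall,
      f1 = m$f1, accuracy = m$accuracy
    )
  }))
  list(
    per_domain = per,
    general_precision = mean(per$precision),
    general_recall = mean(per$recall),
    general_f1 = mean(per$f1),
    general_accuracy = mean(per$accuracy),
    predicted_labels = predLabels,
    algorithm = algorithm
  )
}

#' Forest importance of PC features in the powerset model
#'
#' Out-of-bag permutation importance (mean accuracy decrease over trees
#' divided by its SD over trees) of a random forest fitted to the
#' powerset classes.
#'
#' @inheritParams multilabelCV
#' @param ntree ensemble size.
#' @return ranked importance data.frame as in
#'   \code{\link{permutationImportance}}.
#' @export
multilabelImportance <- function(X, labels, ntree = 500, seed = 1) {
  classes <- powersetEncode(as.matrix(labels))
  rf <- withSubSeed(seed, 78, {
    randomForest::randomForest(
      x = as.data.frame(X), y = classes,
      ntree = ntree, importance = TRUE
    )
  })
  meanDec <- rf$importance[, "MeanDecreaseAccuracy"]
  sdOverTrees <- rf$importanceSD[, "MeanDecreaseAccuracy"] * sqrt(ntree)
  imp <- ifelse(sdOverTrees > 0, meanDec / sdOverTrees, 0)
  out <- data.frame(
    feature = colnames(X), importance = as.numeric(imp),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$importance, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Parsimonious multilabel feature subset
#'
#' Evaluates importance-ranked feature prefixes and returns the smallest
#' prefix whose general F1 is within \code{tolerance} of the full-set
#' general F1.
#'
#' @inheritParams multilabelCV
#' @param importances ranked importance table over the features of
#'   \code{X}.
#' @param tolerance allowed general-F1 shortfall (default 0.005, i.e.
#'   half a percentage point).
#' @return list with \code{features}, \code{report} (the prefix's
#'   \code{\link{multilabelCV}} result) and \code{full_f1}.
#' @export
multilabelSubset <- function(X, labels, importances,
                             algorithm = "random_forest", k = nrow(X),
                             tolerance = 0.005, seed = 1) {
  full <- multilabelCV(X, labels, algorithm = algorithm, k = k, seed = seed)
  ranked <- importances$feature
  for (m in seq_along(ranked)) {
    rep <- multilabelCV(X[, ranked[seq_len(m)], drop = FALSE], labels,
                        algorithm = algorithm, k = k, seed = seed)
    if (rep$general_f1 >= full$general_f1 - tolerance) {
      return(list(features = ranked[seq_len(m)], report = rep,
                  full_f1 = full$general_f1))
    }
  }
  list(features = ranked, report = full, full_f1 = full$general_f1)
}
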