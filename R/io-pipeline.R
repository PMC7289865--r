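#' Read and write the cohort feature table
#'
#' The feature table is a CSV with a mandatory \code{subject_id} key
#' column followed by the 172 feature columns of the shipped taxonomy.
#' Reading validates the column set against the taxonomy and reports the
#' missing/extra column names on mismatch.
#'
#' @param path CSV path.
#' @param truth optional subject truth table (joined into the returned
#'   container's column data when supplied).
#' @return \code{readFeatureTable}: a \linkS4class{CoaFeatureSet}.
#' @export
readFeatureTable <- function(path, truth = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (nrow(tab) == 0 || !("subject_id" %in% colnames(tab))) {
    stop("validation error: feature table needs a subject_id column and rows")
  }
  meta <- featureTaxonomy()
  have <- setdiff(colnames(tab), "subject_id")
  missing <- setdiff(meta$feature_id, have)
  extra <- setdiff(have, meta$feature_id)
  if (length(missing) || length(extra)) {
    stop(
      "validation error: feature columns do not match the taxonomy.\n",
      if (length(missing)) {
        paste0("  missing (", length(missing), "): ",
               paste(missing, collapse = ", "), "\n")
      } else "",
      if (length(extra)) {
        paste0("  extra (", length(extra), "): ",
               paste(extra, collapse = ", "))
      } else ""
    )
  }
  M <- t(as.matrix(tab[, meta$feature_id]))
  colnames(M) <- tab$subject_id
  if (is.null(truth)) {
    truth <- data.frame(subject_id = tab$subject_id,
                        row.names = tab$subject_id)
  }
  newCoaFeatureSet(M, meta, truth[colnames(M), , drop = FALSE])
}

#' @rdname readFeatureTable
#' @param fset a \linkS4class{CoaFeatureSet}.
#' @export
writeFeatureTable <- function(fset, path) {
  M <- featureMatrix(fset)
  out <- data.frame(subject_id = rownames(M), M, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a signal recording as delimited text
#'
#' One file per subject x test x condition; header comment lines carry
#' the subject id, test, sampling rate and condition flags, followed by a
#' CSV block of the channels.
#'
#' @param rec a \linkS4class{SignalRecord}.
#' @param path output path.
#' @export
writeSignalRecord <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject_id: %s", rec@subject),
    sprintf("# test: %s", rec@test),
    sprintf("# fs: %g", rec@fs),
    sprintf("# condition: %s",
            paste(names(rec@condition), rec@condition, sep = "=",
                  collapse = ";"))
  ), con)
  utils::write.csv(as.data.frame(rec@channels), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignalRecord
#' @export
readSignalRecord <- function(path) {
  hdr <- readLines(path, n = 4)
  val <- function(key) sub(sprintf("^# %s: ", key), "", hdr[grepl(key, hdr)])
  condStr <- val("condition")
  condition <- character(0)
  if (nzchar(condStr)) {
    kv <- strsplit(strsplit(condStr, ";")[[1]], "=")
    condition <- stats::setNames(
      vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1)
    )
    condition <- condition[!is.na(condition)]
  }
  ch <- as.matrix(utils::read.csv(path, skip = 4))
  makeRecord(val("subject_id"), val("test"), as.numeric(val("fs")),
             ch, condition)
}

#' Run the full assessment pipeline
#'
#' End-to-end driver: simulate (or accept) a cohort, extract features if
#' raw recordings were produced, compress to the 27 PC scores, compute
#' the PC-by-domain p-value matrix, build the test and SARA dependency
#' trees with centralities, run the binary forest with leave-one-out
#' validation including Subset 1/Subset 2 selection, decompose the
#' discriminative weight into STAR/test/domain percentages, and run the
#' multilabel powerset classification with its parsimonious subset.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param cohort optionally a pre-simulated cohort (the result of
#'   \code{\link{simulateCohort}}); simulated from \code{config} when
#'   omitted.
#' @param ntree forest ensemble size.
#' @param out_dir optional directory; when given, the feature table,
#'   p-value matrix, classification reports and STAR distribution are
#'   written there as CSV/JSON.
#' @param verbose log each stage.
#' @return list with elements \code{features}, \code{pca},
#'   \code{pvalues}, \code{graph}, \code{sara}, \code{binary},
#'   \code{star}, \code{multilabel}.
#' @export
runPipeline <- function(config = cohortConfig(), cohort = NULL, ntree = 500,
                        out_dir = NULL, verbose = FALSE) {
  log <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  seed <- config$seed
  log("simulate: seed %d, %d + %d subjects (%s mode)", seed,
      config$n_controls, config$n_ataxic, config$mode)
  if (is.null(cohort)) cohort <- stage("simulate", simulateCohort(config))
  fset <- stage("extract", {
    if (!is.null(cohort$features)) cohort$features else extractAllFeatures(cohort)
  })
  truth <- cohort$truth

  log("reduce: per-test PCA to 27 PCs")
  pca <- stage("reduce", reduceFeatures(fset))
  pv <- stage("reduce", pvalueMatrix(pca$scores, truth))

  log("graph: dependency MST and centralities")
  graph <- stage("graph", {
    dg <- testCorrelation(pca$scores)
    tree <- minimumSpanningTree(dg)
    list(graph = dg, tree = tree, centralities = treeCentralities(tree))
  })
  sara <- stage("graph", saraGraph(truth))

  log("classify: binary forest with LOO validation")
  y <- as.integer(truth$group == "ataxic")
  X <- pca$scores
  rownames(X) <- truth$subject_id
  binary <- stage("classify", {
    leaf <- tuneLeafSize(X, y, ntree = ntree, seed = seed)
    cv <- looCrossValidate(X, y, nodesize = leaf, ntree = ntree, seed = seed)
    imp <- permutationImportance(X, y, nodesize = leaf, ntree = ntree,
                                 seed = seed)
    s1 <- subset1Filter(imp)
    cv1 <- if (length(s1) >= 1) {
      looCrossValidate(X[, s1, drop = FALSE], y, nodesize = leaf,
                       ntree = ntree, seed = seed)
    } else {
      cv
    }
    s2 <- greedySubset2(X, y, imp, nodesize = leaf, ntree = ntree,
                        seed = seed)
    list(
      leaf_size = leaf,
      full = binaryMetrics(cv$y, cv$pred),
      importances = imp,
      subset1 = list(features = s1,
                     report = binaryMetrics(cv1$y, cv1$pred)),
      subset2 = s2
    )
  })

  log("star: back-projection onto %d subset-2 PCs",
      length(binary$subset2$features))
  star <- stage("star", {
    w <- featureWeights(pca$blocks, binary$importances,
                        included = binary$subset2$features)
    starDistribution(w, featureMeta(fset))
  })

  log("multilabel: label-powerset forest")
  labels <- as.matrix(truth[, DOMAIN_IDS])
  multilabel <- stage("multilabel", {
    if (sum(labels) == 0 || nlevels(powersetEncode(labels)) < 2) {
      NULL
    } else {
      rep <- multilabelCV(X, labels, algorithm = "random_forest",
                          seed = seed)
      mimp <- multilabelImportance(X, labels, ntree = ntree, seed = seed)
      sub <- multilabelSubset(X, labels, mimp, seed = seed)
      list(report = rep, importances = mimp, subset = sub)
    }
  })

  result <- list(
    features = fset, pca = pca, pvalues = pv, graph = graph, sara = sara,
    binary = binary, star = star, multilabel = multilabel,
    config = config, truth = truth
  )
  if (!is.null(out_dir)) writeReportBundle(result, out_dir)
  result
}

#' Write the pipeline report bundle
#'
#' @param result a \code{\link{runPipeline}} result.
#' @param out_dir output directory (created if absent).
#' @export
writeReportBundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeFeatureTable(result$features, file.path(out_dir, "feature_table.csv"))
  utils::write.csv(result$pvalues$p, file.path(out_dir, "pvalue_matrix.csv"))
  utils::write.csv(result$graph$centralities,
                   file.path(out_dir, "test_centralities.csv"),
                   row.names = FALSE)
  rep <- list(
    binary = result$binary[c("leaf_size", "full")],
    subset1 = result$binary$subset1$report,
    subset2 = result$binary$subset2$report,
    subset2_features = result$binary$subset2$features,
    star = result$star,
    multilabel = if (!is.null(result$multilabel)) {
      list(
        general_f1 = result$multilabel$report$general_f1,
        general_accuracy = result$multilabel$report$general_accuracy,
        subset_size = length(result$multilabel$subset$features)
      )
    }
  )
  jsonlite::write_json(rep, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
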