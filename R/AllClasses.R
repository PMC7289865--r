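#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

TEST_IDS <- c("DDK", "FNT", "FIN", "BAL", "FOO", "HST", "ROM", "WAL", "SPE")
DOMAIN_IDS <- c("speech", "upper_limb", "lower_limb", "balance", "gait")
STAR_IDS <- c("S", "T", "A", "R")

#' SignalRecord: one raw recording of one subject performing one test
#'
#' Holds a block of uniformly sampled channels (tri-axial accelerometer /
#' gyroscope traces, 2-D tracking trajectories, or an audio amplitude
#' envelope) together with the sampling rate and the recording condition
#' (side, sensor placement, eye state, walking speed).
#'
#' @slot subject subject identifier.
#' @slot test one of DDK, FNT, FIN, BAL, FOO, HST, ROM, WAL, SPE.
#' @slot fs sampling rate in Hz.
#' @slot channels numeric matrix, one column per named channel; all
#'   channels share length and sampling rate.
#' @slot condition named character vector of condition flags, e.g.
#'   \code{c(side = "L")}, \code{c(sensor = "front", eyes = "closed")},
#'   \code{c(speed = "preferred")}.
#' @exportClass SignalRecord
setClass("SignalRecord",
  representation(
    subject = "character",
    test = "character",
    fs = "numeric",
    channels = "matrix",
    condition = "character"
  )
)

setValidity("SignalRecord", function(object) {
  msg <- NULL
  if (!(object@test %in% TEST_IDS)) {
    msg <- c(msg, sprintf("unknown test id '%s'", object@test))
  }
  if (length(object@fs) != 1L || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (is.null(colnames(object@channels))) {
    msg <- c(msg, "channels must have column names")
  }
  if (is.null(msg)) TRUE else msg
})

#' CoaFeatureSet: subjects x 172 extracted features with taxonomy
#'
#' A \linkS4class{SummarizedExperiment} whose single assay holds the
#' feature matrix (features in rows, subjects in columns), whose
#' \code{rowData} carries the feature taxonomy (test, domain, STAR tag,
#' axis, side, condition) and whose \code{colData} carries subject-level
#' truth: group, severity, per-domain affectedness and SARA item scores.
#'
#' @exportClass CoaFeatureSet
setClass("CoaFeatureSet", contains = "SummarizedExperiment")

setValidity("CoaFeatureSet", function(object) {
  msg <- NULL
  rd <- rowData(object)
  need <- c("test", "domain", "star")
  if (!all(need %in% colnames(rd))) {
    msg <- c(msg, "rowData must carry columns test, domain, star")
  } else {
    if (!all(rd$test %in% TEST_IDS)) msg <- c(msg, "unknown test ids in rowData")
    if (!all(rd$star %in% STAR_IDS)) msg <- c(msg, "unknown STAR tags in rowData")
  }
  if (is.null(msg)) TRUE else msg
})

#' PCBlock: per-test principal-component block
#'
#' Loadings, subject scores and explained-variance fractions of the three
#' retained principal components of one test's feature block.
#'
#' @slot test test id.
#' @slot loadings features x k orthonormal loading matrix.
#' @slot scores subjects x k score matrix, columns named TEST_PCk.
#' @slot explainedVariance length-k nonincreasing variance fractions.
#' @slot center,scale the standardisation applied before rotation.
#' @exportClass PCBlock
setClass("PCBlock",
  representation(
    test = "character",
    loadings = "matrix",
    scores = "matrix",
    explainedVariance = "numeric",
    center = "numeric",
    scale = "numeric"
  )
)

setValidity("PCBlock", function(object) {
  k <- ncol(object@loadings)
  msg <- NULL
  if (ncol(object@scores) != k) msg <- c(msg, "scores/loadings width mismatch")
  if (length(object@explainedVariance) != k) {
    msg <- c(msg, "explainedVariance length mismatch")
  }
  if (k > 1 && any(diff(object@explainedVariance) > 1e-10)) {
    msg <- c(msg, "explainedVariance must be nonincreasing")
  }
  crossp <- crossprod(object@loadings)
  if (max(abs(crossp - diag(k))) > 1e-8) {
    msg <- c(msg, "loading columns must be orthonormal")
  }
  if (is.null(msg)) TRUE else msg
})

#' DependencyGraph: Spearman correlation network over tests or SARA items
#'
#' @slot nodes node labels.
#' @slot rho symmetric Spearman correlation matrix, unit diagonal.
#' @slot dist symmetric distance matrix from the selected rho-to-distance
#'   mapping, zero diagonal.
#' @slot mode the mapping used, \code{"linear"} (1 - rho) or \code{"sqrt"}
#'   (sqrt(2 (1 - rho))).
#' @exportClass DependencyGraph
setClass("DependencyGraph",
  representation(
    nodes = "character",
    rho = "matrix",
    dist = "matrix",
    mode = "character"
  )
)

setValidity("DependencyGraph", function(object) {
  msg <- NULL
  n <- length(object@nodes)
  if (!all(dim(object@rho) == n) || !all(dim(object@dist) == n)) {
    msg <- c(msg, "rho/dist must be square matrices over the nodes")
  } else {
    if (max(abs(object@rho - t(object@rho))) > 1e-10) {
      msg <- c(msg, "rho must be symmetric")
    }
    if (max(abs(diag(object@rho) - 1)) > 1e-10) {
      msg <- c(msg, "rho diagonal must be 1")
    }
    if (max(abs(diag(object@dist))) > 1e-10) {
      msg <- c(msg, "dist diagonal must be 0")
    }
    if (min(object@rho) < -1 - 1e-10 || max(object@rho) > 1 + 1e-10) {
      msg <- c(msg, "rho out of [-1, 1]")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' MSTree: minimum spanning tree of a dependency graph
#'
#' @slot nodes node labels.
#' @slot edges data.frame with columns from, to, length.
#' @slot totalLength sum of edge lengths.
#' @exportClass MSTree
setClass("MSTree",
  representation(
    nodes = "character",
    edges = "data.frame",
    totalLength = "numeric"
  )
)

setValidity("MSTree", function(object) {
  msg <- NULL
  if (nrow(object@edges) != length(object@nodes) - 1L) {
    msg <- c(msg, "a spanning tree on n nodes must have n - 1 edges")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SignalRecord", function(object) {
  cat(sprintf(
    "SignalRecord %s / %s  (%d samples @ %g Hz, %d channels%s)\n",
    object@subject, object@test, nrow(object@channels), object@fs,
    ncol(object@channels),
    if (length(object@condition)) {
      paste0("; ", paste(names(object@condition), object@condition,
        sep = "=", collapse = ", "
      ))
    } else ""
  ))
})

setMethod("show", "PCBlock", function(object) {
  cat(sprintf(
    "PCBlock %s: %d features -> %d PCs (explained %s)\n",
    object@test, nrow(object@loadings), ncol(object@loadings),
    paste(sprintf("%.1f%%", 100 * object@explainedVariance), collapse = "/")
  ))
})

setMethod("show", "DependencyGraph", function(object) {
  cat(sprintf(
    "DependencyGraph: %d nodes (%s mapping), mean |rho| = %.3f\n",
    length(object@nodes), object@mode,
    mean(abs(object@rho[upper.tri(object@rho)]))
  ))
})

setMethod("show", "MSTree", function(object) {
  cat(sprintf(
    "MSTree: %d nodes, %d edges, total length %.4f\n",
    length(object@nodes), nrow(object@edges), object@totalLength
  ))
})

#' Accessors for SignalRecord and PCBlock slots
#'
#' @param x the object.
#' @return \code{signalChannels}: the channel matrix; \code{samplingRate}:
#'   Hz; \code{recordCondition}: named condition flags; \code{pcScores},
#'   \code{pcLoadings}, \code{explainedVariance}: the corresponding PC
#'   block slots.
#' @rdname accessors
#' @export
signalChannels <- function(x) x@channels

#' @rdname accessors
#' @export
samplingRate <- function(x) x@fs

#' @rdname accessors
#' @export
recordCondition <- function(x) x@condition

#' @rdname accessors
#' @export
pcScores <- function(x) x@scores

#' @rdname accessors
#' @export
pcLoadings <- function(x) x@loadings

#' @rdname accessors
#' @export
explainedVariance <- function(x) x@explainedVariance

#' @rdname accessors
#' @export
mstEdges <- function(x) x@edges

#' @rdname accessors
#' @export
mstTotalLength <- function(x) x@totalLength

#' Feature matrix and metadata of a CoaFeatureSet
#'
#' @param x a \linkS4class{CoaFeatureSet}.
#' @return \code{featureMatrix}: subjects x features numeric matrix;
#'   \code{featureMeta}: the taxonomy data.frame; \code{subjectInfo}: the
#'   subject truth table.
#' @export
featureMatrix <- function(x) t(assay(x))

#' @rdname featureMatrix
#' @export
featureMeta <- function(x) as.data.frame(rowData(x))

#' @rdname featureMatrix
#' @export
subjectInfo <- function(x) as.data.frame(colData(x))
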