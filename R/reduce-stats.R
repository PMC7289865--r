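#' Per-test principal-component compression
#'
#' Compresses one test's feature block to its top principal components:
#' features are mean-imputed within group, optionally z-scored, and
#' rotated; the component sign is fixed by making the largest-magnitude
#' loading entry positive so reports are reproducible.
#'
#' @param fset a \linkS4class{CoaFeatureSet}.
#' @param test test id.
#' @param k number of components to retain (default 3).
#' @param standardize z-score features before rotation (default TRUE).
#' @return a \linkS4class{PCBlock}.
#' @export
perTestPCA <- function(fset, test, k = 3, standardize = TRUE) {
  meta <- featureMeta(fset)
  X <- featureMatrix(fset)[, meta$feature_id[meta$test == test], drop = FALSE]
  if (nrow(X) < 4) stop("need at least 4 subjects for PCA")
  X <- imputeWithinGroup(X, subjectInfo(fset)$group)
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize, rank. = k)
  k <- ncol(pc$rotation)
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- sprintf("%s_PC%d", test, seq_len(k))
  scl <- pc$scale
  if (isFALSE(scl)) scl <- rep(1, ncol(X))
  methods::new("PCBlock",
    test = test, loadings = pc$rotation[, seq_len(k), drop = FALSE],
    scores = scores, explainedVariance = ev[seq_len(k)],
    center = pc$center, scale = as.numeric(scl)
  )
}

# mean imputation of missing feature values, within group
imputeWithinGroup <- function(X, group) {
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) {
      for (g in unique(group)) {
        sel <- group == g & bad
        if (any(sel)) {
          m <- mean(X[group == g & !bad, j])
          if (!is.finite(m)) m <- mean(X[!bad, j])
          X[sel, j] <- m
        }
      }
    }
  }
  X
}

#' Compress a feature set to the cohort-wide PC score matrix
#'
#' Runs \code{\link{perTestPCA}} for each of the nine tests and binds the
#' per-test scores into the 27-column cohort score matrix.
#'
#' @inheritParams perTestPCA
#' @return list with \code{blocks} (named list of \linkS4class{PCBlock})
#'   and \code{scores} (subjects x 27 matrix, columns \code{TEST_PCk}).
#' @export
reduceFeatures <- function(fset, k = 3, standardize = TRUE) {
  blocks <- lapply(TEST_IDS, function(tt) {
    perTestPCA(fset, tt, k = k, standardize = standardize)
  })
  names(blocks) <- TEST_IDS
  scores <- do.call(cbind, lapply(blocks, pcScores))
  list(blocks = blocks, scores = scores)
}

#' Per-domain normal/ataxic grouping from SARA item scores
#'
#' A subject counts as ataxic in a domain when any of the SARA items
#' mapped to that domain is greater than zero (gait: gait item; balance:
#' stance and sitting; speech: speech disturbance; upper limb: finger
#' chase, nose-finger and alternating hand movements; lower limb:
#' heel-shin). Controls score zero everywhere and are normal in all
#' domains.
#'
#' @param truth subject truth table carrying the SARA item columns.
#' @param domain one of the five domain ids.
#' @return integer vector (1 = ataxic in that domain, 0 = normal).
#' @export
domainGroupSplit <- function(truth, domain) {
  sara <- saraItemTable()
  if (!(domain %in% DOMAIN_IDS)) stop("unknown domain: ", domain)
  items <- sara$item[sara$domain == domain]
  as.integer(rowSums(truth[, items, drop = FALSE] > 0) > 0)
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' @param x,y numeric samples (each of size >= 2).
#' @return two-sided p-value (exact for small samples without ties,
#'   normal approximation with continuity correction otherwise); all-tied
#'   data yields p = 1 with a warning.
#' @export
mwwTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("both samples need size >= 2")
  if (stats::sd(c(x, y)) == 0) {
    warning("all observations tied; p = 1")
    return(1)
  }
  suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                      correct = TRUE)$p.value)
}

#' PC-by-domain nonparametric group-difference matrix
#'
#' For every PC score column and every domain, tests the per-domain
#' normal/ataxic split with the two-sided MWW rank-sum test; a
#' Kolmogorov-Smirnov normality p-value per PC is reported alongside.
#'
#' @param scores subjects x 27 PC score matrix.
#' @param truth subject truth table (SARA items).
#' @param alpha significance level for the mask (default 0.05).
#' @param adjust optional p-adjustment method (\code{"none"} default,
#'   \code{"BH"} available).
#' @return list with \code{p} (27 x 5 matrix), \code{significant}
#'   (logical mask at \code{alpha}), \code{ks_normality} (per-PC p),
#'   and \code{flagged_domains} (domains with fewer than 2 ataxic
#'   subjects).
#' @export
pvalueMatrix <- function(scores, truth, alpha = 0.05, adjust = "none") {
  P <- matrix(NA_real_, nrow = ncol(scores), ncol = length(DOMAIN_IDS),
              dimnames = list(colnames(scores), DOMAIN_IDS))
  flagged <- character(0)
  for (d in DOMAIN_IDS) {
    lab <- domainGroupSplit(truth, d)
    if (sum(lab == 1) < 2 || sum(lab == 0) < 2) {
      flagged <- c(flagged, d)
      next
    }
    for (j in seq_len(ncol(scores))) {
      P[j, d] <- mwwTest(scores[lab == 1, j], scores[lab == 0, j])
    }
  }
  if (adjust != "none") {
    P[] <- stats::p.adjust(P, method = adjust)
  }
  ks <- apply(scores, 2, function(z) {
    z <- (z - mean(z)) / stats::sd(z)
    suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
  })
  list(
    p = P, significant = !is.na(P) & P < alpha,
    ks_normality = ks, flagged_domains = flagged
  )
}
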