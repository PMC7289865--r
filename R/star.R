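#' Back-project PC importances onto the original features
#'
#' The weight of an original feature accumulates, over its test's
#' included principal components, the absolute PCA loading of the feature
#' in that component times the component's forest importance (clipped at
#' zero: components with negative importance play no role). Loadings use
#' the absolute value because the component sign is arbitrary; the
#' importance enters as its value rather than an ordinal rank (an
#' ordinal-rank variant is available).
#'
#' @param blocks named list of \linkS4class{PCBlock}s (per test).
#' @param importances importance table over PC features
#'   (\code{TEST_PCk}).
#' @param included PC feature names to include (defaults to all in the
#'   importance table).
#' @param use_ordinal_rank replace the importance values by reverse
#'   ordinal ranks (most important = number of included PCs).
#' @return named nonnegative weight per original feature.
#' @export
featureWeights <- function(blocks, importances, included = NULL,
                           use_ordinal_rank = FALSE) {
  if (is.null(included)) included <- importances$feature
  imp <- stats::setNames(pmax(importances$importance, 0),
                         importances$feature)
  if (use_ordinal_rank) {
    inc <- importances[importances$feature %in% included, ]
    imp[inc$feature] <- rev(seq_len(nrow(inc)))[rank(inc$rank)]
  }
  weights <- numeric(0)
  for (b in blocks) {
    pcs <- colnames(pcScores(b))
    use <- intersect(pcs, included)
    L <- pcLoadings(b)
    w <- rep(0, nrow(L))
    names(w) <- rownames(L)
    for (pc in use) {
      k <- match(pc, pcs)
      if (!(pc %in% names(imp))) stop("feature absent from importances: ", pc)
      w <- w + abs(L[, k]) * imp[[pc]]
    }
    weights <- c(weights, w)
  }
  weights
}

#' STAR, test and domain contribution percentages
#'
#' Aggregates back-projected feature weights into percentage
#' contributions of the four Holmesian dimensions (Stability, Timing,
#' Accuracy, Rhythmicity), of the nine tests and of the five domains;
#' each block sums to 100.
#'
#' @param weights named feature weights from
#'   \code{\link{featureWeights}}.
#' @param meta feature taxonomy (default \code{\link{featureTaxonomy}}).
#' @return list with \code{star_pct} (named S/T/A/R), \code{test_pct}
#'   and \code{domain_pct}.
#' @export
starDistribution <- function(weights, meta = featureTaxonomy()) {
  meta <- meta[match(names(weights), meta$feature_id), ]
  if (anyNA(meta$feature_id)) stop("weights contain unknown feature ids")
  total <- sum(weights)
  if (total <= 0) stop("total feature weight is zero; distribution undefined")
  pct <- function(groups, levels) {
    v <- vapply(levels, function(g) {
      100 * sum(weights[groups == g]) / total
    }, numeric(1))
    v[!is.na(v)]
  }
  star <- pct(meta$star, STAR_IDS)
  tests <- pct(meta$test, intersect(TEST_IDS, unique(meta$test)))
  doms <- pct(meta$domain, intersect(DOMAIN_IDS, unique(meta$domain)))
  list(star_pct = star, test_pct = tests, domain_pct = doms)
}
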