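# The eleven non-specific filters: eight single ranking statistics
# (SD-b, SD-m, MAD, DIP, Precision, BQ-GOF, TM-GOF, TQ-GOF), three rank
# combinations (BR, AR, WAR), plus selection utilities and the hybrid selector.
#
# Every statistic is stored "larger = more interesting" so that rank
# combination is uniform: variability filters rank high-variance features
# first, goodness-of-fit filters rank worst-fitting features first.

.SINGLE_FILTERS <- c("SD-b", "SD-m", "MAD", "DIP", "Precision",
                     "BQ-GOF", "TM-GOF", "TQ-GOF")

# Accept a plain features x samples matrix or a SummarizedExperiment with a
# 'beta' assay; always returns a named numeric matrix strictly inside (0,1).
.asBetaMatrix <- function(x, clip = TRUE) {
  if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::assay(x, "beta")
  if (!is.matrix(x) || !is.numeric(x)) stop("expected a numeric matrix of proportions")
  if (is.null(rownames(x))) rownames(x) <- sprintf("f%04d", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate feature IDs")
  if (clip) x[] <- clipBoundary(x)
  x
}

.newScores <- function(name, stat, flag = NULL) {
  if (is.null(flag)) flag <- rep(FALSE, length(stat))
  names(flag) <- names(stat)
  rk <- rank(stat, ties.method = "average")
  names(rk) <- names(stat)
  new("FilterScores", filterName = name, statistic = stat,
      rankValue = rk, flagged = flag)
}

# Sentinel policy for features with no valid single-Beta fit: maximal evidence
# of a mixture, so they get the largest observed score + 1 and are flagged.
.worstFill <- function(stat, ok) {
  if (all(ok)) return(stat)
  top <- if (any(ok)) max(stat[ok]) else 0
  stat[!ok] <- top + 1
  stat
}

#' @rdname FilterScores-class
#' @export
setMethod("filterName", "FilterScores", function(x) x@filterName)
#' @rdname FilterScores-class
#' @export
setMethod("statistic", "FilterScores", function(x) x@statistic)
#' @rdname FilterScores-class
#' @export
setMethod("rankValue", "FilterScores", function(x) x@rankValue)
#' @rdname FilterScores-class
#' @export
setMethod("flagged", "FilterScores", function(x) x@flagged)

setMethod("show", "FilterScores", function(object) {
  p <- length(object@statistic)
  cat("FilterScores:", object@filterName, "over", p, "features\n")
  top <- names(sort(object@rankValue, decreasing = TRUE))[seq_len(min(5L, p))]
  cat("  top features:", paste(top, collapse = ", "), "\n")
  if (any(object@flagged))
    cat("  flagged (no single-Beta fit):", sum(object@flagged), "\n")
})

#' Standard deviation filter (SD-b / SD-m)
#'
#' Per-feature standard deviation with the 1/N divisor, computed on the raw
#' proportions (`scale = "beta"`) or on M-values (`scale = "mvalue"`).  For
#' Beta-distributed proportions the variance depends on the mean, so SD-b
#' favours features with mean methylation near 0.5; the M-value scale weakens
#' (but does not remove) that association.
#'
#' @param x features x samples matrix in (0, 1), or a SummarizedExperiment
#'   with a `beta` assay.
#' @param scale `"beta"` or `"mvalue"`.
#' @return A \linkS4class{FilterScores} object (larger SD = more interesting).
#' @export
sdStatistic <- function(x, scale = c("beta", "mvalue")) {
  scale <- match.arg(scale)
  x <- .asBetaMatrix(x)
  if (ncol(x) < 2L) stop("at least 2 samples are required")
  if (scale == "mvalue") x[] <- mValues(x)
  mom <- .rowMoments(x)
  .newScores(if (scale == "beta") "SD-b" else "SD-m", sqrt(mom$var))
}

#' Median absolute deviation filter
#'
#' Per-feature `median(|x - median(x)|)` (no consistency constant).
#'
#' @inheritParams sdStatistic
#' @return A \linkS4class{FilterScores} object.
#' @export
madStatistic <- function(x) {
  x <- .asBetaMatrix(x)
  if (ncol(x) < 2L) stop("at least 2 samples are required")
  stat <- apply(x, 1L, function(v) median(abs(v - median(v))))
  .newScores("MAD", stat)
}

#' Dip (multimodality) filter
#'
#' Per-feature [hartiganDip()] statistic; features whose sample distribution is
#' far from any unimodal distribution rank first.  With fewer than 4 samples
#' the statistic is defined as its minimal value 1/(2n).
#'
#' @inheritParams sdStatistic
#' @return A \linkS4class{FilterScores} object.
#' @export
dipStatistic <- function(x) {
  x <- .asBetaMatrix(x)
  n <- ncol(x)
  stat <- if (n < 4L) rep(1 / (2 * n), nrow(x)) else apply(x, 1L, hartiganDip)
  names(stat) <- rownames(x)
  .newScores("DIP", stat)
}

#' Inverse precision filter
#'
#' Ranks features by \eqn{1/\hat\phi = 1/(\hat\alpha + \hat\beta)} from the
#' method-of-moments fit: low precision means high dispersion after adjusting
#' for the mean.  Features too dispersed for any single Beta are assigned the
#' worst-fit sentinel score and flagged.
#'
#' @inheritParams sdStatistic
#' @return A \linkS4class{FilterScores} object.
#' @export
inversePrecision <- function(x) {
  x <- .asBetaMatrix(x)
  if (ncol(x) < 2L) stop("at least 2 samples are required")
  mom <- .rowMoments(x)
  fit <- .momFit(mom$mean, mom$var)
  stat <- 1 / (fit$alpha + fit$beta)
  names(stat) <- rownames(x)
  stat <- .worstFill(stat, fit$ok)
  .newScores("Precision", stat, !fit$ok)
}

# Interior quantile grid p_k = k/(K+1), k = 1..K.
.quantileGrid <- function(nQuantiles) seq_len(nQuantiles) / (nQuantiles + 1)

#' Beta-quantile goodness-of-fit filter (BQ-GOF)
#'
#' For each feature, a method-of-moments Beta is fitted and its quantiles
#' \eqn{q_k} at the interior grid \eqn{p_k = k/(K+1)} are compared against the
#' empirical CDF: the statistic is \eqn{\sum_k |\hat F(q_k) - p_k|} (cumulative
#' probability differences at the fitted-Beta quantiles).  A perfectly fitting
#' feature scores 0; the statistic is bounded by the number of quantile points.
#'
#' @inheritParams sdStatistic
#' @param nQuantiles number of interior quantile points (default 25).
#' @return A \linkS4class{FilterScores} object.
#' @export
bqGof <- function(x, nQuantiles = 25L) {
  x <- .asBetaMatrix(x)
  if (ncol(x) < 2L) stop("at least 2 samples are required")
  p <- .quantileGrid(nQuantiles)
  mom <- .rowMoments(x)
  fit <- .momFit(mom$mean, mom$var)
  n <- ncol(x)
  stat <- rep(NA_real_, nrow(x)); names(stat) <- rownames(x)
  for (i in which(fit$ok)) {
    q <- qbeta(p, fit$alpha[i], fit$beta[i])
    Fhat <- findInterval(q, sort(x[i, ])) / n     # right-continuous ECDF
    stat[i] <- sum(abs(Fhat - p))
  }
  stat <- .worstFill(stat, fit$ok)
  .newScores("BQ-GOF", stat, !fit$ok)
}

#' Per-feature moments of the CDF-transformed data
#'
#' Step 1-3 of the TM-GOF procedure: fit a Beta to each feature by the method
#' of moments, map the feature through the fitted CDF, and record the mean and
#' standard deviation (1/N divisor) of the transformed values.  For a feature
#' truly following a single Beta these concentrate around (1/2, sqrt(1/12)).
#'
#' @inheritParams sdStatistic
#' @return data.frame with columns `yMean`, `ySD` and logical `ok` (FALSE for
#'   features with no valid Beta fit, which are excluded from the
#'   cross-feature scale estimation downstream).
#' @export
transformedSummary <- function(x) {
  x <- .asBetaMatrix(x)
  if (ncol(x) < 2L) stop("at least 2 samples are required")
  mom <- .rowMoments(x)
  fit <- .momFit(mom$mean, mom$var)
  ym <- ys <- rep(NA_real_, nrow(x))
  okIdx <- which(fit$ok)
  if (length(okIdx)) {
    y <- pbeta(x[okIdx, , drop = FALSE], fit$alpha[okIdx], fit$beta[okIdx])
    ym[okIdx] <- rowMeans(y)
    ys[okIdx] <- sqrt(pmax(rowMeans(y * y) - ym[okIdx]^2, 0))
  }
  data.frame(yMean = ym, ySD = ys, ok = fit$ok, row.names = rownames(x))
}

#' Transformed-moment goodness-of-fit filter (TM-GOF)
#'
#' Steps 4-5 of the procedure: from the per-feature transformed moments
#' (see [transformedSummary()]), compute the cross-feature standard deviations
#' \eqn{s_{\bar y}} and \eqn{s_{s_y}} and score each feature by its
#' standardized Euclidean distance from the single-Beta target
#' \eqn{(1/2, \sqrt{1/12})}:
#' \deqn{\sqrt{\left(\frac{\bar y - 1/2}{s_{\bar y}}\right)^2 +
#'             \left(\frac{s_y - \sqrt{1/12}}{s_{s_y}}\right)^2}.}
#' Features containing a mixture of Betas land far from the target and rank
#' first.  Features with no valid Beta fit are flagged, excluded from the
#' scale estimation and given the worst-fit sentinel.
#'
#' @param x features x samples matrix (or SummarizedExperiment), or the
#'   data.frame returned by [transformedSummary()].
#' @return A \linkS4class{FilterScores} object.
#' @export
tmGof <- function(x) {
  sm <- if (is.data.frame(x)) x else transformedSummary(x)
  if (sum(sm$ok) < 2L) stop("need at least 2 features with a valid Beta fit")
  sdev <- function(v) sqrt(mean((v - mean(v))^2))   # 1/N convention
  sY <- sdev(sm$yMean[sm$ok]); sS <- sdev(sm$ySD[sm$ok])
  dy <- (sm$yMean - 0.5); ds <- (sm$ySD - sqrt(1 / 12))
  t1 <- t2 <- rep(0, nrow(sm))
  if (sY > 0) t1 <- (dy / sY)^2 else
    warning("all features share the same transformed mean; dropping that coordinate")
  if (sS > 0) t2 <- (ds / sS)^2 else
    warning("all features share the same transformed SD; dropping that coordinate")
  stat <- sqrt(t1 + t2)
  names(stat) <- rownames(sm)
  stat <- .worstFill(stat, sm$ok)
  .newScores("TM-GOF", stat, !sm$ok)
}

#' Transformed-quantile goodness-of-fit filter (TQ-GOF)
#'
#' Each feature is CDF-transformed with its fitted Beta parameters; the
#' statistic is the sum of absolute differences between the empirical quantiles
#' of the transformed data and the Uniform(0, 1) theoretical quantiles over the
#' interior grid: \eqn{\sum_k |\hat Q_Y(p_k) - p_k|}, with the inverse-ECDF
#' (type-1) empirical quantile.
#'
#' @inheritParams bqGof
#' @return A \linkS4class{FilterScores} object.
#' @export
tqGof <- function(x, nQuantiles = 25L) {
  x <- .asBetaMatrix(x)
  if (ncol(x) < 2L) stop("at least 2 samples are required")
  p <- .quantileGrid(nQuantiles)
  n <- ncol(x)
  idx <- ceiling(p * n)                  # type-1 empirical quantile index
  mom <- .rowMoments(x)
  fit <- .momFit(mom$mean, mom$var)
  stat <- rep(NA_real_, nrow(x)); names(stat) <- rownames(x)
  for (i in which(fit$ok)) {
    y <- sort(pbeta(x[i, ], fit$alpha[i], fit$beta[i]))
    stat[i] <- sum(abs(y[idx] - p))
  }
  stat <- .worstFill(stat, fit$ok)
  .newScores("TQ-GOF", stat, !fit$ok)
}

#' Re-rank filter scores
#'
#' Assigns rank values ascending in the statistic so the largest statistic
#' receives rank P, with ties averaged.  All filter constructors already rank
#' their output; this is exposed for score vectors assembled by hand.
#'
#' @param scores a \linkS4class{FilterScores} object, or a named numeric vector
#'   of statistics ("larger = more interesting").
#' @param name filter name used when `scores` is a bare vector.
#' @return A \linkS4class{FilterScores} object.
#' @export
rankFeatures <- function(scores, name = "custom") {
  if (is(scores, "FilterScores"))
    return(.newScores(scores@filterName, scores@statistic, scores@flagged))
  if (length(scores) == 0L) stop("empty score set")
  if (is.null(names(scores))) stop("scores must be a named vector")
  .newScores(name, scores)
}

#' Combine the ranks of the eight single filters (BR / AR / WAR)
#'
#' Best Rank takes each feature's maximum rank value across the eight single
#' filters; Average Rank averages its best two; Weighted Average Rank averages
#' its best four with weights 4:3:2:1 (largest rank weighted 4), divided by 10.
#' The combined statistic is then re-ranked.
#'
#' @param scoresList list of exactly 8 \linkS4class{FilterScores} objects over
#'   the same feature set (the eight single filters).
#' @param method `"BR"`, `"AR"` or `"WAR"`.
#' @return A \linkS4class{FilterScores} object.
#' @export
combineRanks <- function(scoresList, method = c("BR", "AR", "WAR")) {
  method <- match.arg(method)
  if (length(scoresList) != 8L)
    stop("rank combination is defined over exactly 8 single filters, got ",
         length(scoresList))
  ids <- names(rankValue(scoresList[[1L]]))
  R <- vapply(scoresList, function(s) {
    rv <- rankValue(s)
    if (!setequal(names(rv), ids)) stop("filters cover different feature sets")
    rv[ids]
  }, numeric(length(ids)))
  stat <- apply(R, 1L, function(r) {
    r <- sort(r, decreasing = TRUE)
    switch(method,
      BR  = r[1L],
      AR  = mean(r[1:2]),
      WAR = sum(r[1:4] * c(4, 3, 2, 1)) / 10)
  })
  names(stat) <- ids
  .newScores(method, stat)
}

#' Select the top-k features of a filter
#'
#' Returns the k feature IDs with the largest rank value, best first; ties are
#' broken deterministically by lexicographic feature ID.
#'
#' @param scores a \linkS4class{FilterScores} object.
#' @param k number of features to keep, `1 <= k <= P`.
#' @return character vector of k feature IDs.
#' @export
selectTop <- function(scores, k) {
  rv <- rankValue(scores)
  if (k < 1L || k > length(rv))
    stop("k must lie between 1 and the number of features (", length(rv), ")")
  ids <- names(rv)
  ord <- order(-rv, ids)
  ids[ord][seq_len(k)]
}

#' Hybrid two-filter selection
#'
#' Pools the top `kEach` features of two filters (union, duplicates kept once).
#' Pairing a variability filter with a goodness-of-fit filter (SD-b + TM-GOF)
#' selects complementary feature sets.
#'
#' @param scoresA,scoresB \linkS4class{FilterScores} objects over the same
#'   features.
#' @param kEach number of features taken from each filter (default 500).
#' @return character vector of feature IDs (size between kEach and 2*kEach).
#' @export
hybridSelect <- function(scoresA, scoresB, kEach = 500L) {
  union(selectTop(scoresA, kEach), selectTop(scoresB, kEach))
}

#' Compute a single filter by name
#'
#' @inheritParams sdStatistic
#' @param method one of `"SD-b"`, `"SD-m"`, `"MAD"`, `"DIP"`, `"Precision"`,
#'   `"BQ-GOF"`, `"TM-GOF"`, `"TQ-GOF"`.
#' @param nQuantiles quantile grid size for the quantile-based filters.
#' @return A \linkS4class{FilterScores} object.
#' @export
computeFilter <- function(x, method, nQuantiles = 25L) {
  method <- match.arg(method, .SINGLE_FILTERS)
  switch(method,
    "SD-b"      = sdStatistic(x, "beta"),
    "SD-m"      = sdStatistic(x, "mvalue"),
    "MAD"       = madStatistic(x),
    "DIP"       = dipStatistic(x),
    "Precision" = inversePrecision(x),
    "BQ-GOF"    = bqGof(x, nQuantiles),
    "TM-GOF"    = tmGof(x),
    "TQ-GOF"    = tqGof(x, nQuantiles))
}

#' Compute all eleven filters
#'
#' The eight single filters plus, when `combine = TRUE`, the three rank
#' combinations computed from them.
#'
#' @inheritParams computeFilter
#' @param combine also compute BR, AR and WAR (default TRUE).
#' @return named list of \linkS4class{FilterScores}.
#' @export
computeAllFilters <- function(x, nQuantiles = 25L, combine = TRUE) {
  x <- .asBetaMatrix(x)
  out <- lapply(.SINGLE_FILTERS, function(m) computeFilter(x, m, nQuantiles))
  names(out) <- .SINGLE_FILTERS
  if (combine) {
    singles <- out[.SINGLE_FILTERS]
    for (m in c("BR", "AR", "WAR")) out[[m]] <- combineRanks(singles, m)
  }
  out
}
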