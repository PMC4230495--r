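# Evaluation of filter performance: ROC enrichment over the informative-feature
# truth, AUC with a normal-approximation CI across replicates, fixed-list
# sensitivity/specificity, misclassification of the top-level clustering, and
# the adjusted Rand index; plus the two replicate-study harnesses.

#' ROC curve of a filter ranking against the informative truth
#'
#' For every feature-list length k = 0..P, the top-k list (rank order, ties
#' broken by feature ID as in [selectTop()]) is scored against the truth:
#' true-positive fraction = informative features captured / total informative,
#' false-positive fraction = null features captured / total null.  AUC by the
#' trapezoid rule over the false-positive axis.
#'
#' @param scores a \linkS4class{FilterScores} object.
#' @param truth named logical vector (TRUE = informative) over the same
#'   features, or a \linkS4class{MethylSimulation}.
#' @return A \linkS4class{RocCurve}.
#' @export
rocPoints <- function(scores, truth) {
  if (is(truth, "MethylSimulation")) truth <- informativeFeatures(truth)
  rv <- rankValue(scores)
  ids <- names(rv)
  if (!setequal(ids, names(truth))) stop("scores and truth cover different features")
  truth <- truth[ids]
  nPos <- sum(truth); nNeg <- sum(!truth)
  if (nPos == 0L || nNeg == 0L)
    stop("truth must contain at least one informative and one null feature")
  ord <- order(-rv, ids)
  tp <- c(0, cumsum(truth[ord])) / nPos
  fp <- c(0, cumsum(!truth[ord])) / nNeg
  auc <- sum(diff(fp) * (head(tp, -1) + tail(tp, -1)) / 2)
  new("RocCurve", fpf = fp, tpf = tp, auc = auc)
}

#' @rdname RocCurve-class
#' @export
setMethod("aucValue", "RocCurve", function(x) x@auc)
#' @rdname RocCurve-class
#' @export
setMethod("curvePoints", "RocCurve",
          function(x) data.frame(fpf = x@fpf, tpf = x@tpf))

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve over %d list lengths, AUC = %.4f\n",
              length(object@fpf) - 1L, object@auc))
})

#' Pointwise average of ROC curves over replicates
#'
#' @param curves list of \linkS4class{RocCurve} objects sharing the same
#'   list-length grid.
#' @return A \linkS4class{RocCurve} (AUC recomputed on the averaged curve).
#' @export
averageRoc <- function(curves) {
  stopifnot(length(curves) >= 1L)
  len <- vapply(curves, function(cv) length(cv@fpf), 0L)
  if (length(unique(len)) != 1L) stop("curves have mismatched list-length grids")
  fp <- rowMeans(vapply(curves, function(cv) cv@fpf, numeric(len[1L])))
  tp <- rowMeans(vapply(curves, function(cv) cv@tpf, numeric(len[1L])))
  auc <- sum(diff(fp) * (head(tp, -1) + tail(tp, -1)) / 2)
  new("RocCurve", fpf = fp, tpf = tp, auc = auc)
}

#' Normal-approximation confidence interval for replicate AUCs
#'
#' Mean +/- z * SE over replicate AUC values, clipped to `[0, 1]`.  A filter is
#' non-informative when this interval contains 0.5.
#'
#' @param replicateAucs numeric vector of per-replicate AUCs (length >= 2).
#' @param level confidence level (default 0.95).
#' @return named numeric: `mean`, `low`, `high`.
#' @export
aucCI <- function(replicateAucs, level = 0.95) {
  if (length(replicateAucs) < 2L) stop("need at least 2 replicate AUCs")
  m <- mean(replicateAucs)
  se <- stats::sd(replicateAucs) / sqrt(length(replicateAucs))
  z <- qnorm(1 - (1 - level) / 2)
  c(mean = m, low = max(0, m - z * se), high = min(1, m + z * se))
}

#' Sensitivity and specificity of a fixed-length top list
#'
#' For the top-k list: sensitivity = captured informative / total informative,
#' specificity = 1 - captured null / total null.  With P features of which
#' P1 are informative, the top-100 point is bounded by the diagonal joining
#' (fpf = 0, tpf = min(k, P1)/P1) and (fpf = min(k, P - P1)/(P - P1), tpf = 0).
#'
#' @inheritParams rocPoints
#' @param k list length, `1 <= k <= P`.
#' @return named numeric: `sensitivity`, `specificity`.
#' @export
sensSpecAtK <- function(scores, truth, k) {
  if (is(truth, "MethylSimulation")) truth <- informativeFeatures(truth)
  nPos <- sum(truth); nNeg <- sum(!truth)
  if (nPos == 0L || nNeg == 0L)
    stop("truth must contain at least one informative and one null feature")
  top <- selectTop(scores, k)
  tp <- sum(truth[top])
  c(sensitivity = tp / nPos, specificity = 1 - (k - tp) / nNeg)
}

#' Misclassification rate of a top-level clustering
#'
#' Compares an at-most-2-cluster labelling against a 2-group truth: the
#' fraction of misassigned samples, minimized over the two possible
#' cluster-to-group assignments.  A single-cluster labelling therefore scores
#' `min(n1, n2)/n` -- the "one big cluster" ceiling (10% at a 20/180 split,
#' 50% at 100/100).  The result never exceeds 0.5.
#'
#' @param labels per-sample cluster labels with at most 2 distinct values
#'   (e.g. from [topLevelLabels()]).
#' @param truth per-sample labels with exactly 2 distinct values, or a
#'   \linkS4class{MethylSimulation}.
#' @return misclassification rate in `[0, 0.5]`.
#' @export
misclassificationRate <- function(labels, truth) {
  if (is(truth, "MethylSimulation")) truth <- groupLabels(truth)
  if (length(labels) != length(truth)) stop("labels and truth lengths differ")
  ul <- unique(labels)
  if (length(ul) > 2L)
    stop("labels must have at most 2 distinct values; pass depth-1 labels")
  ut <- unique(truth)
  if (length(ut) != 2L) stop("truth must have exactly 2 groups")
  n <- length(labels)
  if (length(ul) == 1L) return(min(sum(truth == ut[1L]), sum(truth == ut[2L])) / n)
  a <- labels == ul[1L]; b <- truth == ut[1L]
  min(sum(a != b), sum(a == b)) / n
}

#' Adjusted Rand index of two partitions
#'
#' Hubert-Arabie chance-corrected pair-counting agreement: 1 for identical
#' partitions (up to relabelling), about 0 for independent ones.
#'
#' @param labels,truth per-sample label vectors of equal length.
#' @return numeric index (at most 1).
#' @export
adjustedRand <- function(labels, truth) {
  if (length(labels) != length(truth)) stop("label vectors differ in length")
  tab <- table(labels, truth)
  n <- sum(tab)
  sumIJ <- sum(choose(tab, 2))
  sumI <- sum(choose(rowSums(tab), 2))
  sumJ <- sum(choose(colSums(tab), 2))
  expected <- sumI * sumJ / choose(n, 2)
  maxIndex <- (sumI + sumJ) / 2
  # degenerate only when both partitions are trivial (and hence identical)
  if (maxIndex == expected) return(1)
  (sumIJ - expected) / (maxIndex - expected)
}

#' Replicate study of ranked-list enrichment (ROC / AUC)
#'
#' Runs `nReplicates` simulated data sets under one design (null parameters
#' fixed, informative positions and pairs re-drawn per replicate), ranks the
#' features with each requested filter, and scores each ranking against the
#' informative truth.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param library a \linkS4class{ParameterLibrary}.
#' @param filters character vector of filter names (see [computeFilter()]).
#' @param nReplicates number of replicate data sets.
#' @param level confidence level for the AUC interval.
#' @return list with `aucs` (replicates x filters matrix), `summary`
#'   (data.frame: filter, meanAuc, low, high) and `curves` (per-filter
#'   averaged \linkS4class{RocCurve}).
#' @export
enrichmentStudy <- function(design, library, filters = c("SD-b", "SD-m",
                            "Precision", "BQ-GOF", "TM-GOF", "TQ-GOF"),
                            nReplicates = 50L, level = 0.95) {
  aucs <- matrix(NA_real_, nReplicates, length(filters),
                 dimnames = list(NULL, filters))
  curves <- lapply(filters, function(f) vector("list", nReplicates))
  names(curves) <- filters
  for (r in seq_len(nReplicates)) {
    sim <- simulateDataset(design, library, replicate = r)
    x <- betaValues(sim)
    truth <- informativeFeatures(sim)
    for (f in filters) {
      rc <- rocPoints(computeFilter(x, f), truth)
      aucs[r, f] <- aucValue(rc)
      curves[[f]][[r]] <- rc
    }
  }
  summ <- do.call(rbind, lapply(filters, function(f) {
    ci <- aucCI(aucs[, f], level)
    data.frame(filter = f, meanAuc = ci[["mean"]], low = ci[["low"]],
               high = ci[["high"]])
  }))
  list(aucs = aucs, summary = summ,
       curves = lapply(curves, averageRoc))
}

#' Replicate study of cluster recovery after filtering
#'
#' For each replicate data set, each filter's top `listLengths` features are
#' clustered with [recursivePartition()] (depth 1, since scoring compares the
#' top two clusters to the truth) and the misclassification rate recorded.
#'
#' @inheritParams enrichmentStudy
#' @param listLengths top-list sizes to cluster (default 100, 200, 400).
#' @param minNode minimum child size for the splitter.
#' @return list with `rates` (replicates x filters x lengths array) and
#'   `summary` (data.frame: filter, listLength, meanError).
#' @export
clusterRecoveryStudy <- function(design, library,
                                 filters = c("SD-b", "SD-m", "Precision",
                                             "TM-GOF", "TQ-GOF"),
                                 listLengths = c(100L, 200L, 400L),
                                 nReplicates = 50L, minNode = 5L) {
  rates <- array(NA_real_,
                 dim = c(nReplicates, length(filters), length(listLengths)),
                 dimnames = list(NULL, filters, paste0("k", listLengths)))
  for (r in seq_len(nReplicates)) {
    sim <- simulateDataset(design, library, replicate = r)
    x <- betaValues(sim)
    truth <- groupLabels(sim)
    for (f in filters) {
      sc <- computeFilter(x, f)
      for (li in seq_along(listLengths)) {
        top <- selectTop(sc, listLengths[li])
        cl <- recursivePartition(x[top, , drop = FALSE], minNode = minNode,
                                 maxDepth = 1L)
        rates[r, f, li] <- misclassificationRate(topLevelLabels(cl), truth)
      }
    }
  }
  summ <- expand.grid(filter = filters, listLength = listLengths,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  summ$meanError <- mapply(function(f, k)
    mean(rates[, f, paste0("k", k)]), summ$filter, summ$listLength)
  list(rates = rates, summary = summ)
}

#' @importFrom utils head tail
NULL
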