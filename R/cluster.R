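# Recursive two-component Beta-mixture partitioning of samples: an EM fit of a
# product-of-independent-Betas mixture at each node, with a BIC rule deciding
# whether to accept the binary split.  Used to score filters by how well
# clustering on their top features recovers the true sample groups.

.clampMoments <- function(m, v, eps = 1e-6, phiMax = 1e6) {
  m <- pmin(pmax(m, eps), 1 - eps)
  vmax <- m * (1 - m)
  v <- pmin(pmax(v, vmax / (phiMax + 1)), vmax * 0.9999)
  nu <- vmax / v - 1
  list(alpha = m * nu, beta = (1 - m) * nu)
}

# Sum of per-feature Beta log-densities for every sample, for one component:
# L_s = sum_j [(a_j-1) log x_js + (b_j-1) log(1-x_js) - lbeta(a_j, b_j)],
# computed as two crossproducts against precomputed log matrices.
.componentLogLik <- function(LX, L1X, a, b) {
  drop(crossprod(LX, a - 1) + crossprod(L1X, b - 1)) - sum(lbeta(a, b))
}

.lloyd1d <- function(v, maxIter = 50L) {
  c1 <- min(v); c2 <- max(v)
  for (i in seq_len(maxIter)) {
    g <- ifelse(abs(v - c1) <= abs(v - c2), 1L, 2L)
    n1 <- sum(g == 1L); n2 <- sum(g == 2L)
    if (n1 == 0L || n2 == 0L) break
    d1 <- mean(v[g == 1L]); d2 <- mean(v[g == 2L])
    if (d1 == c1 && d2 == c2) break
    c1 <- d1; c2 <- d2
  }
  ifelse(abs(v - c1) <= abs(v - c2), 1L, 2L)
}

#' Fit a two-component Beta mixture over samples
#'
#' EM on the product-of-independent-Betas likelihood: the E-step computes
#' per-sample component responsibilities from summed per-feature Beta
#' log-densities; the M-step re-estimates each component's per-feature
#' (alpha, beta) by responsibility-weighted method of moments and the mixing
#' weight by the mean responsibility.  The observed log-likelihood is
#' monitored and the iteration stops on convergence, on `maxIter`, or if a
#' moment-based M-step ever fails to improve it (the previous state is kept,
#' so the reported trajectory is nondecreasing).
#'
#' Initialization is deterministic: one start from a 2-means split of the
#' per-sample mean methylation and one from a 2-means split of the per-sample
#' standard deviation; the best final likelihood wins.  `seed` is only used
#' when `nRandomStarts > 0` adds extra randomly initialized runs.
#'
#' @param x features x samples matrix in (0, 1) (or SummarizedExperiment).
#' @param seed seed for optional random restarts.
#' @param maxIter maximum EM iterations per start (default 100).
#' @param tol relative log-likelihood improvement declaring convergence.
#' @param nRandomStarts extra random-responsibility starts (default 0).
#' @return list with `responsibilities` (samples x 2), `weights`, `params`
#'   (list of two \linkS4class{BetaParams}), `logLik` (trajectory of the best
#'   start), `assign` (hard labels), and `degenerate` (TRUE if a component
#'   weight collapsed below 2/n so no valid split exists).
#' @export
fitBetaMixture <- function(x, seed = 1L, maxIter = 100L, tol = 1e-6,
                           nRandomStarts = 0L) {
  x <- .asBetaMatrix(x)
  if (ncol(x) < 4L) stop("at least 4 samples are required")
  if (nrow(x) < 1L) stop("at least 1 feature is required")
  N <- ncol(x)
  LX <- log(x); L1X <- log1p(-x); X2 <- x * x

  runEM <- function(r) {
    llOld <- -Inf; traj <- numeric(0)
    state <- NULL
    for (it in seq_len(maxIter)) {
      sw <- colSums(r)
      if (min(sw) < 2) return(list(degenerate = TRUE, logLik = traj, state = state))
      w <- sw / N
      a <- b <- vector("list", 2L)
      for (cc in 1:2) {
        m <- drop(x %*% r[, cc]) / sw[cc]
        v <- drop(X2 %*% r[, cc]) / sw[cc] - m * m
        p <- .clampMoments(m, v)
        a[[cc]] <- p$alpha; b[[cc]] <- p$beta
      }
      L <- cbind(.componentLogLik(LX, L1X, a[[1L]], b[[1L]]) + log(w[1L]),
                 .componentLogLik(LX, L1X, a[[2L]], b[[2L]]) + log(w[2L]))
      mx <- pmax(L[, 1L], L[, 2L])
      lse <- mx + log(exp(L[, 1L] - mx) + exp(L[, 2L] - mx))
      ll <- sum(lse)
      if (ll < llOld - abs(llOld) * 1e-12) break   # MoM step failed to improve; keep previous
      traj <- c(traj, ll)
      rNew <- exp(L - lse)
      state <- list(r = rNew, weights = w, a = a, b = b, ll = ll)
      if (is.finite(llOld) && (ll - llOld) <= tol * abs(ll)) { r <- rNew; break }
      llOld <- ll; r <- rNew
    }
    if (is.null(state)) return(list(degenerate = TRUE, logLik = traj, state = NULL))
    c(state, list(degenerate = FALSE, logLik = traj))
  }

  softInit <- function(g) {
    r <- matrix(0.05, N, 2L)
    r[cbind(seq_len(N), g)] <- 0.95
    r
  }
  inits <- list(softInit(.lloyd1d(colMeans(x))),
                softInit(.lloyd1d(apply(x, 2L, stats::sd))))
  if (nRandomStarts > 0L) {
    set.seed(as.integer(seed))
    for (i in seq_len(nRandomStarts)) {
      u <- runif(N); inits <- c(inits, list(cbind(u, 1 - u)))
    }
  }
  best <- NULL
  for (ini in inits) {
    res <- runEM(ini)
    if (res$degenerate) next
    if (is.null(best) || res$ll > best$ll) best <- res
  }
  if (is.null(best))
    return(list(degenerate = TRUE, responsibilities = NULL, weights = NULL,
                params = NULL, logLik = numeric(0), assign = rep(1L, N)))
  list(degenerate = FALSE,
       responsibilities = best$r,
       weights = best$weights,
       params = list(BetaParams(best$a[[1L]], best$b[[1L]]),
                     BetaParams(best$a[[2L]], best$b[[2L]])),
       logLik = best$logLik,
       assign = max.col(best$r, ties.method = "first"))
}

# One-Beta-per-feature log-likelihood of a node (the no-split model).
.singleBetaLogLik <- function(x) {
  mom <- .rowMoments(x)
  p <- .clampMoments(mom$mean, mom$var)
  sum(.componentLogLik(log(x), log1p(-x), p$alpha, p$beta))
}

#' Recursive binary partitioning under a Beta mixture
#'
#' At each node a two-component Beta mixture is fitted ([fitBetaMixture()]);
#' the binary split is accepted iff the two-component BIC (parameter count
#' 2 x 2P + 1) beats the one-Beta-per-feature BIC (2P) and both children hold
#' at least `minNode` samples.  Accepted children are split recursively up to
#' `maxDepth`.  On data without cluster structure the BIC penalty rejects the
#' root split and a single leaf is returned.
#'
#' @param x features x samples matrix in (0, 1) (or SummarizedExperiment).
#' @param minNode minimum samples per child (default 5).
#' @param maxDepth maximum splitting depth (default `Inf`).
#' @param seed passed to [fitBetaMixture()] (only used with random restarts).
#' @param maxIter,tol EM controls, see [fitBetaMixture()].
#' @return A \linkS4class{ClusterResult}.
#' @export
recursivePartition <- function(x, minNode = 5L, maxDepth = Inf, seed = 1L,
                               maxIter = 100L, tol = 1e-6) {
  x <- .asBetaMatrix(x)
  N <- ncol(x); P <- nrow(x)
  paths <- rep("r", N)
  tree <- data.frame(node = character(0), depth = integer(0), n = integer(0),
                     accepted = logical(0), bicSingle = numeric(0),
                     bicSplit = numeric(0), stringsAsFactors = FALSE)
  maxdep <- 0L

  recurse <- function(idx, path, depth) {
    n <- length(idx)
    accepted <- FALSE; bic1 <- NA_real_; bic2 <- NA_real_
    if (depth <= maxDepth && n >= 2L * minNode && n >= 4L) {
      sub <- x[, idx, drop = FALSE]
      fit <- fitBetaMixture(sub, seed = seed, maxIter = maxIter, tol = tol)
      if (!fit$degenerate) {
        ll2 <- fit$logLik[length(fit$logLik)]
        ll1 <- .singleBetaLogLik(sub)
        bic1 <- -2 * ll1 + (2 * P) * log(n)
        bic2 <- -2 * ll2 + (4 * P + 1) * log(n)
        sizes <- tabulate(fit$assign, 2L)
        if (bic2 < bic1 && min(sizes) >= minNode) accepted <- TRUE
      }
    }
    tree[nrow(tree) + 1L, ] <<- list(path, depth, n, accepted, bic1, bic2)
    if (accepted) {
      maxdep <<- max(maxdep, depth)
      left <- idx[fit$assign == 1L]; right <- idx[fit$assign == 2L]
      paths[left] <<- paste0(paths[left], "1")
      paths[right] <<- paste0(paths[right], "2")
      recurse(left, paste0(path, "1"), depth + 1L)
      recurse(right, paste0(path, "2"), depth + 1L)
    }
  }
  recurse(seq_len(N), "r", 1L)

  D <- max(maxdep, 1L)
  labels <- matrix(0L, N, D, dimnames = list(colnames(x), paste0("depth", seq_len(D))))
  for (d in seq_len(D)) {
    pref <- substr(paths, 1L, 1L + d)
    labels[, d] <- as.integer(factor(pref, levels = unique(pref)))
  }
  new("ClusterResult", labels = labels, tree = tree,
      nLeaves = length(unique(paths)))
}

#' Cluster labels at a given tree depth
#'
#' Depth 1 gives the top-level (at most binary) partition used for
#' misclassification scoring; a depth beyond the tree returns the leaf labels.
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param depth requested depth (default 1).
#' @return named integer vector of per-sample labels.
#' @export
topLevelLabels <- function(result, depth = 1L) {
  stopifnot(is(result, "ClusterResult"), depth >= 1L)
  d <- min(depth, ncol(result@labels))
  out <- result@labels[, d]
  names(out) <- rownames(result@labels)
  out
}

#' @rdname ClusterResult-class
#' @export
setMethod("nLeaves", "ClusterResult", function(x) x@nLeaves)
#' @rdname ClusterResult-class
#' @export
setMethod("splitTree", "ClusterResult", function(x) x@tree)

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", nrow(object@labels), "samples,",
      object@nLeaves, "leaves, depth", ncol(object@labels), "\n")
  tl <- table(object@labels[, 1L])
  cat("  top-level sizes:", paste(tl, collapse = " / "), "\n")
})
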