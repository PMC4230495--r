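# Two-group Beta simulator: a parameter library emulating colon-cancer-style
# CIMP / non-CIMP parameter estimates, an effect-size cap, and replicate
# generation (null parameters fixed across replicates; informative positions
# and parameter pairs re-drawn each replicate).

#' Construct a simulation design
#'
#' @param nFeatures total features (default 2000).
#' @param fracInformative fraction of informative features (default 0.10).
#' @param nSamples total samples (default 200).
#' @param groupRatio integer pair: relative sizes of group 1 (CIMP-like) and
#'   group 2 (majority); `c(1, 9)` gives 20 vs 180 samples at `nSamples = 200`.
#' @param thetaCap optional cap on the absolute effect size of informative
#'   features (e.g. 1 or 0.5); `NA` (default) leaves the library uncapped.
#' @param seed base seed; replicate r of a study uses `seed + r`.
#' @return A \linkS4class{SimulationDesign}.
#' @export
SimulationDesign <- function(nFeatures = 2000L, fracInformative = 0.1,
                             nSamples = 200L, groupRatio = c(1L, 1L),
                             thetaCap = NA_real_, seed = 1L) {
  new("SimulationDesign", nFeatures = as.integer(nFeatures),
      fracInformative = fracInformative, nSamples = as.integer(nSamples),
      groupRatio = as.integer(groupRatio), thetaCap = as.numeric(thetaCap),
      seed = as.integer(seed))
}

setMethod("show", "SimulationDesign", function(object) {
  cat("SimulationDesign:", object@nFeatures, "features x", object@nSamples,
      "samples\n  informative fraction:", object@fracInformative,
      " group ratio:", paste(object@groupRatio, collapse = ":"),
      " theta cap:", object@thetaCap, " seed:", object@seed, "\n")
})

.nInformative <- function(design)
  as.integer(round(design@fracInformative * design@nFeatures))

.groupSizes <- function(design) {
  r <- design@groupRatio
  n1 <- as.integer(round(design@nSamples * r[1L] / sum(r)))
  c(n1, design@nSamples - n1)
}

#' Build a parameter library for the simulator
#'
#' Emulates the structure of Beta parameters estimated from a CIMP /
#' non-CIMP cancer cohort:
#' \itemize{
#' \item Null (non-informative) means are drawn from a methylation-like
#'   bimodal mixture: a low mode, a high mode, and a configurable mid-range
#'   fraction; precisions are log-uniform.
#' \item Informative candidates give the majority group 2 a low mean
#'   \eqn{\mu_2} (a normally unmethylated, CpG-island-like locus) and the
#'   CIMP-like group 1 a logit-shifted mean
#'   \eqn{\mu_1 = \mathrm{logistic}(\mathrm{logit}(\mu_2) + \delta)} with
#'   \eqn{\delta > 0} and \eqn{\phi_1 \le \phi_2}, so the minority group has
#'   both higher mean and higher variance.  The shift \eqn{\delta} is
#'   exponential (mean `deltaMean`, truncated at `deltaMax`): most informative
#'   loci shift modestly, a minority strongly.
#' }
#'
#' @param nNull number of null parameter sets (default 1800).
#' @param nCandidates number of candidate informative pairs (default 2400;
#'   studies sample their informative features per replicate from whatever
#'   survives the effect-size cap).
#' @param midFraction fraction of null means in the mid-range (default 0.25;
#'   the remainder splits 0.40 low / 0.35 high).
#' @param lowRange,highRange,midRange uniform ranges for the three null-mean
#'   modes; `lowRange` is also the range of informative \eqn{\mu_2}.
#' @param phiRange log-uniform precision range for null features.
#' @param informativePhiRange log-uniform range of the majority-group
#'   precision \eqn{\phi_2} for informative candidates.
#' @param phiShrink range of the multiplicative factor applied to \eqn{\phi_2}
#'   to obtain \eqn{\phi_1 \le \phi_2}; the default 0.1-1 span reflects both
#'   the genuinely higher variance of the hypermethylated minority and the
#'   spread that small-cohort per-group estimation adds to precision estimates.
#' @param deltaMean,deltaMax mean and truncation of the exponential logit
#'   shift \eqn{\delta}.
#' @param seed RNG seed; the same seed and settings reproduce the library.
#' @return A \linkS4class{ParameterLibrary}.
#' @export
buildParameterLibrary <- function(nNull = 1800L, nCandidates = 2400L,
                                  midFraction = 0.25,
                                  lowRange = c(0.02, 0.15),
                                  highRange = c(0.85, 0.98),
                                  midRange = c(0.20, 0.80),
                                  phiRange = c(5, 200),
                                  informativePhiRange = c(30, 300),
                                  phiShrink = c(0.1, 1),
                                  deltaMean = 0.8, deltaMax = 4,
                                  seed = 1L) {
  stopifnot(nNull >= 1L, nCandidates >= 1L,
            midFraction >= 0, midFraction < 1, deltaMean > 0)
  set.seed(as.integer(seed))
  lowFrac <- (1 - midFraction) * 0.40 / 0.75
  highFrac <- (1 - midFraction) * 0.35 / 0.75
  comp <- sample(c("low", "high", "mid"), nNull, replace = TRUE,
                 prob = c(lowFrac, highFrac, midFraction))
  mu <- numeric(nNull)
  mu[comp == "low"]  <- runif(sum(comp == "low"),  lowRange[1L],  lowRange[2L])
  mu[comp == "high"] <- runif(sum(comp == "high"), highRange[1L], highRange[2L])
  mu[comp == "mid"]  <- runif(sum(comp == "mid"),  midRange[1L],  midRange[2L])
  phi <- exp(runif(nNull, log(phiRange[1L]), log(phiRange[2L])))
  nulls <- data.frame(mu = mu, phi = phi)

  mu2 <- runif(nCandidates, lowRange[1L], lowRange[2L])
  delta <- pmin(rexp(nCandidates, rate = 1 / deltaMean), deltaMax)
  mu1 <- stats::plogis(stats::qlogis(mu2) + delta)
  phi2 <- exp(runif(nCandidates, log(informativePhiRange[1L]),
                    log(informativePhiRange[2L])))
  phi1 <- phi2 * runif(nCandidates, phiShrink[1L], phiShrink[2L])
  informative <- data.frame(mu1 = mu1, phi1 = phi1, mu2 = mu2, phi2 = phi2,
                            theta = effectSize(mu1, mu2))
  new("ParameterLibrary", informative = informative, nulls = nulls)
}

setMethod("show", "ParameterLibrary", function(object) {
  cat("ParameterLibrary:", nrow(object@informative), "informative candidate pairs,",
      nrow(object@nulls), "null parameter sets\n")
  cat(sprintf("  |theta| range of candidates: %.3f - %.3f\n",
              min(abs(object@informative$theta)), max(abs(object@informative$theta))))
})

#' Restrict informative candidates by effect size
#'
#' Removes candidate pairs with `|theta| > thetaMax`; null parameters are left
#' unchanged.  Capping the effect size weakens the cluster signal carried by
#' the informative features, which is what separates the performance of the
#' different filters.
#'
#' @param library a \linkS4class{ParameterLibrary}.
#' @param thetaMax positive cap on the absolute effect size.
#' @return A \linkS4class{ParameterLibrary} with the surviving candidates.
#' @export
filterByEffectSize <- function(library, thetaMax) {
  stopifnot(is(library, "ParameterLibrary"), thetaMax >= 0)
  keep <- abs(library@informative$theta) <= thetaMax
  if (!any(keep)) stop("effect-size cap ", thetaMax, " removes every candidate pair")
  new("ParameterLibrary", informative = library@informative[keep, , drop = FALSE],
      nulls = library@nulls)
}

#' Simulate one two-group methylation data set
#'
#' Draws each feature j and sample in group i iid from
#' Beta(\eqn{\mu_{ij}\phi_{ij}}, \eqn{(1-\mu_{ij})\phi_{ij}}).  A random
#' `fracInformative` subset of feature positions receives group-specific
#' parameter pairs sampled (without replacement) from the library's candidates
#' (after applying the design's effect-size cap); all remaining features use
#' one shared null parameter set per feature, identical for both groups.
#' Replicates of a study keep the null parameters fixed and re-draw the
#' informative positions and pairs: call with `replicate = 1, 2, ...`.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param library a \linkS4class{ParameterLibrary} whose `nulls` has exactly
#'   `nFeatures - round(fracInformative * nFeatures)` rows.
#' @param replicate replicate index; the RNG seed is `design@seed + replicate`.
#' @return A \linkS4class{MethylSimulation}.
#' @export
simulateDataset <- function(design, library, replicate = 1L) {
  stopifnot(is(design, "SimulationDesign"), is(library, "ParameterLibrary"))
  if (!is.na(design@thetaCap))
    library <- filterByEffectSize(library, design@thetaCap)
  nInf <- .nInformative(design)
  nNull <- design@nFeatures - nInf
  if (nrow(library@nulls) != nNull)
    stop("library holds ", nrow(library@nulls), " null parameter sets but the design needs ", nNull)
  if (nrow(library@informative) < nInf)
    stop("library holds only ", nrow(library@informative),
         " candidate pairs; the design needs ", nInf)
  set.seed(design@seed + as.integer(replicate))

  pos <- sort(sample.int(design@nFeatures, nInf))
  pick <- library@informative[sample.int(nrow(library@informative), nInf), ]
  mu1 <- mu2 <- phi1 <- phi2 <- numeric(design@nFeatures)
  mu1[-pos] <- mu2[-pos] <- library@nulls$mu
  phi1[-pos] <- phi2[-pos] <- library@nulls$phi
  mu1[pos] <- pick$mu1; phi1[pos] <- pick$phi1
  mu2[pos] <- pick$mu2; phi2[pos] <- pick$phi2

  gs <- .groupSizes(design)
  P <- design@nFeatures
  x1 <- matrix(rbeta(P * gs[1L], mu1 * phi1, (1 - mu1) * phi1), nrow = P)
  x2 <- matrix(rbeta(P * gs[2L], mu2 * phi2, (1 - mu2) * phi2), nrow = P)
  x <- clipBoundary(cbind(x1, x2))
  dimnames(x) <- list(sprintf("cg%05d", seq_len(P)),
                      sprintf("s%03d", seq_len(design@nSamples)))
  informative <- logical(P); informative[pos] <- TRUE

  se <- SummarizedExperiment(
    assays = list(beta = x),
    rowData = DataFrame(informative = informative,
                        mu1 = mu1, phi1 = phi1, mu2 = mu2, phi2 = phi2),
    colData = DataFrame(group = rep(c(1L, 2L), gs),
                        row.names = colnames(x)))
  new("MethylSimulation", se)
}

#' @rdname MethylSimulation-class
#' @export
setMethod("betaValues", "MethylSimulation",
          function(x) SummarizedExperiment::assay(x, "beta"))
#' @rdname MethylSimulation-class
#' @export
setMethod("groupLabels", "MethylSimulation",
          function(x) {
            g <- SummarizedExperiment::colData(x)$group
            names(g) <- colnames(x)
            g
          })
#' @rdname MethylSimulation-class
#' @export
setMethod("informativeFeatures", "MethylSimulation",
          function(x) {
            f <- SummarizedExperiment::rowData(x)$informative
            names(f) <- rownames(x)
            f
          })
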