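#' @import methods
#' @importFrom stats dbeta pbeta qbeta rbeta rexp runif quantile median qnorm
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Beta distribution parameters with mean/precision reparameterization
#'
#' Holds vectors of shape parameters (alpha, beta) together with the derived
#' mean \eqn{\mu = \alpha/(\alpha+\beta)} and precision
#' \eqn{\phi = \alpha+\beta}.  Under this parameterization the variance is
#' \eqn{\mu(1-\mu)/(\phi+1)}, so \eqn{\phi} measures dispersion independently
#' of the mean.
#'
#' @slot alpha numeric, first shape parameter(s), strictly positive.
#' @slot beta numeric, second shape parameter(s), strictly positive.
#' @slot mu numeric, distribution mean(s) in (0, 1).
#' @slot phi numeric, precision(s), strictly positive.
#' @export
setClass("BetaParams",
  representation(alpha = "numeric", beta = "numeric",
                 mu = "numeric", phi = "numeric"))

setValidity("BetaParams", function(object) {
  a <- object@alpha; b <- object@beta
  if (length(a) != length(b)) return("alpha and beta lengths differ")
  if (any(!is.finite(a)) || any(!is.finite(b))) return("non-finite shape parameter")
  if (any(a <= 0) || any(b <= 0)) return("shape parameters must be positive")
  if (any(abs(object@mu - a / (a + b)) > 1e-8)) return("mu inconsistent with alpha/(alpha+beta)")
  if (any(abs(object@phi - (a + b)) > 1e-8 * (a + b))) return("phi inconsistent with alpha+beta")
  TRUE
})

#' Per-feature filter statistics and rank values
#'
#' One non-specific filter's output over a set of features.  The statistic is
#' stored with the convention that larger values are more interesting (more
#' variable, or worse single-Beta fit); `rankValue` assigns rank P to the
#' largest statistic with ties averaged, so rank combination across filters is
#' uniform.
#'
#' @slot filterName character, one of the supported filter identifiers.
#' @slot statistic named numeric, per-feature statistic (larger = more interesting).
#' @slot rankValue named numeric, per-feature rank values (ties averaged).
#' @slot flagged named logical, features whose Beta fit failed and which were
#'   assigned a sentinel worst-fit score.
#' @export
setClass("FilterScores",
  representation(filterName = "character", statistic = "numeric",
                 rankValue = "numeric", flagged = "logical"))

setValidity("FilterScores", function(object) {
  p <- length(object@statistic)
  if (length(object@rankValue) != p || length(object@flagged) != p)
    return("statistic, rankValue and flagged lengths differ")
  ids <- names(object@statistic)
  if (is.null(ids) || anyDuplicated(ids)) return("statistic must carry unique feature names")
  if (!identical(ids, names(object@rankValue))) return("rankValue names differ from statistic names")
  if (p > 0) {
    if (abs(mean(object@rankValue) - (p + 1) / 2) > 1e-8)
      return("rank values are not a tie-averaged permutation of 1..P")
    if (!isTRUE(all.equal(rank(object@statistic, ties.method = "average"),
                          rank(object@rankValue, ties.method = "average"),
                          check.attributes = FALSE)))
      return("statistic and rankValue are not co-monotone")
  }
  TRUE
})

#' Design of a two-group Beta-mixture simulation
#'
#' @slot nFeatures integer, total number of features (default 2000).
#' @slot fracInformative numeric in (0,1), fraction of features carrying
#'   group-specific parameters (default 0.10).
#' @slot nSamples integer, total number of samples (default 200).
#' @slot groupRatio integer pair, relative sizes of group 1 (the CIMP-like,
#'   typically minority group) and group 2; e.g. `c(1, 9)`, `c(1, 1)`, `c(9, 1)`.
#' @slot thetaCap numeric, optional ceiling on the absolute effect size
#'   (log odds ratio of group means) of informative features; `NA` means no cap.
#' @slot seed integer, base seed; replicate r uses `seed + r`.
#' @export
setClass("SimulationDesign",
  representation(nFeatures = "integer", fracInformative = "numeric",
                 nSamples = "integer", groupRatio = "integer",
                 thetaCap = "numeric", seed = "integer"))

setValidity("SimulationDesign", function(object) {
  if (object@nFeatures < 2L) return("nFeatures must be >= 2")
  if (object@fracInformative <= 0 || object@fracInformative >= 1)
    return("fracInformative must lie in (0, 1)")
  if (object@nSamples < 4L) return("nSamples must be >= 4")
  if (length(object@groupRatio) != 2L || any(object@groupRatio < 1L))
    return("groupRatio must be two positive integers")
  if (!is.na(object@thetaCap) && object@thetaCap <= 0)
    return("thetaCap must be positive or NA")
  TRUE
})

#' Library of per-feature Beta parameters for the simulator
#'
#' `informative` holds candidate parameter pairs
#' \eqn{((\mu_1,\phi_1),(\mu_2,\phi_2))} for informative features (group 1 =
#' CIMP-like minority, group 2 = majority) together with the signed effect size
#' `theta`; `nulls` holds one `(mu, phi)` per non-informative feature, used for
#' both groups.
#'
#' @slot informative data.frame with columns mu1, phi1, mu2, phi2, theta.
#' @slot nulls data.frame with columns mu, phi.
#' @export
setClass("ParameterLibrary",
  representation(informative = "data.frame", nulls = "data.frame"))

setValidity("ParameterLibrary", function(object) {
  inf <- object@informative; nul <- object@nulls
  if (!all(c("mu1", "phi1", "mu2", "phi2", "theta") %in% names(inf)))
    return("informative must have columns mu1, phi1, mu2, phi2, theta")
  if (!all(c("mu", "phi") %in% names(nul)))
    return("nulls must have columns mu, phi")
  mus <- c(inf$mu1, inf$mu2, nul$mu)
  if (any(mus <= 0 | mus >= 1)) return("all mu must lie in (0, 1)")
  if (any(c(inf$phi1, inf$phi2, nul$phi) <= 0)) return("all phi must be positive")
  TRUE
})

#' Simulated two-group methylation data set
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single `beta` assay of
#' methylation proportions, per-sample group labels (`colData$group`, 1 =
#' CIMP-like group, 2 = majority group) and the per-feature informative truth
#' (`rowData$informative`).
#'
#' @export
setClass("MethylSimulation", contains = "SummarizedExperiment")

setValidity("MethylSimulation", function(object) {
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'beta' missing")
  b <- SummarizedExperiment::assay(object, "beta")
  if (any(!is.finite(b)) || any(b <= 0) || any(b >= 1))
    return("beta values must lie strictly in (0, 1)")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% names(cd) || !all(cd$group %in% c(1L, 2L)))
    return("colData$group must contain group labels 1/2")
  rd <- SummarizedExperiment::rowData(object)
  if (!"informative" %in% names(rd) || !is.logical(rd$informative))
    return("rowData$informative must be logical")
  TRUE
})

#' Result of recursive Beta-mixture partitioning
#'
#' @slot labels integer matrix, samples x depths; column d holds the hard
#'   cluster labels after d levels of splitting (a rejected split leaves the
#'   parent's membership intact).
#' @slot tree data.frame describing each visited node: node path, depth, size,
#'   whether its binary split was accepted, and the BIC values compared.
#' @slot nLeaves integer, number of leaves of the accepted tree.
#' @export
setClass("ClusterResult",
  representation(labels = "matrix", tree = "data.frame", nLeaves = "integer"))

setValidity("ClusterResult", function(object) {
  if (ncol(object@labels) < 1L) return("labels must have at least depth 1")
  if (length(unique(object@labels[, 1L])) > 2L)
    return("depth-1 labels must have at most 2 distinct values")
  TRUE
})

#' ROC curve over feature-list lengths
#'
#' Sensitivity (true-positive fraction) and false-positive fraction for ranked
#' feature lists of every length 0..P, with trapezoid-rule area under the curve.
#'
#' @slot fpf numeric, false-positive fractions (nondecreasing, 0 to 1).
#' @slot tpf numeric, true-positive fractions (nondecreasing, 0 to 1).
#' @slot auc numeric(1), area under the curve.
#' @export
setClass("RocCurve",
  representation(fpf = "numeric", tpf = "numeric", auc = "numeric"))

setValidity("RocCurve", function(object) {
  if (length(object@fpf) != length(object@tpf)) return("fpf and tpf lengths differ")
  if (is.unsorted(object@fpf) || is.unsorted(object@tpf))
    return("ROC coordinates must be nondecreasing")
  if (object@auc < -1e-12 || object@auc > 1 + 1e-12) return("auc outside [0, 1]")
  TRUE
})

#' Feature quality mask
#'
#' @slot keep named logical, per-feature keep flag.
#' @slot reason named character, reason for dropping (`"outlier"`, `"constant"`,
#'   `"invalid"`) or `NA` for kept features.
#' @export
setClass("FeatureMask",
  representation(keep = "logical", reason = "character"))

setValidity("FeatureMask", function(object) {
  if (length(object@keep) != length(object@reason)) return("keep/reason lengths differ")
  dropped <- !object@keep
  if (any(is.na(object@reason[dropped]))) return("every dropped feature needs a reason")
  TRUE
})
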