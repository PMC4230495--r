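#' @rdname FilterScores-class
#' @param x a \linkS4class{FilterScores} object.
#' @export
setGeneric("filterName", function(x) standardGeneric("filterName"))
#' @rdname FilterScores-class
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
#' @rdname FilterScores-class
#' @export
setGeneric("rankValue", function(x) standardGeneric("rankValue"))
#' @rdname FilterScores-class
#' @export
setGeneric("flagged", function(x) standardGeneric("flagged"))

#' @rdname BetaParams-class
#' @param x a \linkS4class{BetaParams} object.
#' @export
setGeneric("shape1", function(x) standardGeneric("shape1"))
#' @rdname BetaParams-class
#' @export
setGeneric("shape2", function(x) standardGeneric("shape2"))
#' @rdname BetaParams-class
#' @export
setGeneric("betaMean", function(x) standardGeneric("betaMean"))
#' @rdname BetaParams-class
#' @export
setGeneric("betaPrecision", function(x) standardGeneric("betaPrecision"))

#' @rdname MethylSimulation-class
#' @param x a \linkS4class{MethylSimulation} object.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))
#' @rdname MethylSimulation-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname MethylSimulation-class
#' @export
setGeneric("informativeFeatures", function(x) standardGeneric("informativeFeatures"))

#' @rdname ClusterResult-class
#' @param x a \linkS4class{ClusterResult} object.
#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))
#' @rdname ClusterResult-class
#' @export
setGeneric("splitTree", function(x) standardGeneric("splitTree"))

#' @rdname RocCurve-class
#' @param x a \linkS4class{RocCurve} object.
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
#' @rdname RocCurve-class
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))

#' @rdname FeatureMask-class
#' @param x a \linkS4class{FeatureMask} object.
#' @export
setGeneric("keptFeatures", function(x) standardGeneric("keptFeatures"))
#' @rdname FeatureMask-class
#' @export
setGeneric("dropReason", function(x) standardGeneric("dropReason"))
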