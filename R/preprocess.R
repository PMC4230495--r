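# Feature-level quality filters applied before ranking.

#' Outlier-feature mask (median +/- 3 IQR rule)
#'
#' A feature is dropped iff any of its values lies outside
#' `[median - multiplier * IQR, median + multiplier * IQR]`, with the median
#' and IQR (Q3 - Q1, linear-interpolation quantiles) computed per feature
#' across samples.  Constant features are kept (a constant is not an outlier);
#' zero-IQR features with any value off the median by more than 1e-9 are
#' dropped.  Note that coordinate outliers across many features are exactly
#' the signature of a rare hypermethylated subtype, so this pre-filter can
#' remove features informative for a CIMP-like minority -- apply it when
#' hunting tissue-level structure, not rare subtypes.
#'
#' @param x features x samples matrix (or SummarizedExperiment).
#' @param multiplier IQR multiplier (default 3).
#' @return A \linkS4class{FeatureMask}.
#' @export
outlierFeatureMask <- function(x, multiplier = 3) {
  x <- .asBetaMatrix(x, clip = FALSE)
  if (ncol(x) < 4L) stop("at least 4 samples are required for quartiles")
  keep <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    md <- median(v)
    iqr <- diff(quantile(v, c(0.25, 0.75), names = FALSE))
    keep[i] <- if (iqr == 0) all(abs(v - md) <= 1e-9)
               else all(v >= md - multiplier * iqr & v <= md + multiplier * iqr)
  }
  reason <- ifelse(keep, NA_character_, "outlier")
  names(keep) <- names(reason) <- rownames(x)
  new("FeatureMask", keep = keep, reason = reason)
}

#' Basic quality filter
#'
#' Drops features with any non-finite entry (`"invalid"`) or zero variance
#' (`"constant"`), then boundary-clips the survivors.
#'
#' @param x features x samples matrix (or SummarizedExperiment).
#' @return list with the reduced `matrix` and the \linkS4class{FeatureMask}.
#' @export
qcFilter <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::assay(x, "beta")
  if (!is.matrix(x) || !is.numeric(x)) stop("expected a numeric matrix")
  if (is.null(rownames(x))) rownames(x) <- sprintf("f%04d", seq_len(nrow(x)))
  bad <- apply(x, 1L, function(v) any(!is.finite(v)))
  const <- !bad & apply(x, 1L, function(v) max(v) - min(v) == 0)
  keep <- !bad & !const
  if (!any(keep)) stop("quality filter drops every feature")
  reason <- rep(NA_character_, nrow(x))
  reason[bad] <- "invalid"; reason[const] <- "constant"
  names(keep) <- names(reason) <- rownames(x)
  out <- x[keep, , drop = FALSE]
  out[] <- clipBoundary(out)
  list(matrix = out, mask = new("FeatureMask", keep = keep, reason = reason))
}

#' Apply a feature mask
#'
#' @param x features x samples matrix (or SummarizedExperiment).
#' @param mask a \linkS4class{FeatureMask}.
#' @return the matrix restricted to kept features.
#' @export
applyMask <- function(x, mask) {
  x <- .asBetaMatrix(x, clip = FALSE)
  stopifnot(is(mask, "FeatureMask"), identical(rownames(x), names(mask@keep)))
  x[mask@keep, , drop = FALSE]
}

#' @rdname FeatureMask-class
#' @export
setMethod("keptFeatures", "FeatureMask", function(x) x@keep)
#' @rdname FeatureMask-class
#' @export
setMethod("dropReason", "FeatureMask", function(x) x@reason)

setMethod("show", "FeatureMask", function(object) {
  cat("FeatureMask:", sum(object@keep), "of", length(object@keep), "features kept\n")
  if (any(!object@keep)) print(table(object@reason[!object@keep]))
})
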