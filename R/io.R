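# Delimited-text readers/writers for beta matrices, truth sidecars and filter
# scores (GEO series-matrix style: header row of sample IDs, first column of
# feature IDs).

#' Read a beta-value matrix from delimited text
#'
#' Expects a header row of sample IDs and a first column of feature IDs; every
#' body cell must be a number in `[0, 1]`.  Malformed cells, duplicated IDs and
#' out-of-range values raise errors naming the offending location.
#'
#' @param path file path.
#' @param sep field separator: `"tab"` (default) or `"comma"`.
#' @return numeric matrix, features in rows.
#' @export
readBetaMatrix <- function(path, sep = c("tab", "comma")) {
  sep <- switch(match.arg(sep), tab = "\t", comma = ",")
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("expected a feature-ID column plus at least one sample column")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature ID: ", ids[duplicated(ids)][1L])
  if (anyDuplicated(colnames(df)[-1L]))
    stop("duplicate sample ID: ", colnames(df)[-1L][duplicated(colnames(df)[-1L])][1L])
  x <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(ids, colnames(df)[-1L]))
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric cell at feature '", ids[bad[1L]], "', sample '",
           colnames(df)[j], "' (value '", df[[j]][bad[1L]], "')")
    x[, j - 1L] <- v
  }
  bad <- which(x < 0 | x > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop("value outside [0, 1] at feature '", rownames(x)[bad[1L, 1L]],
         "', sample '", colnames(x)[bad[1L, 2L]], "'")
  x
}

#' Write a beta-value matrix as delimited text
#'
#' Values are written with enough significant digits (default 12) that a
#' write/read round trip reproduces them to full precision.
#'
#' @param x features x samples matrix (or SummarizedExperiment).
#' @param path output file path.
#' @param sep `"tab"` or `"comma"`.
#' @param digits significant digits (>= 10 recommended).
#' @export
writeBetaMatrix <- function(x, path, sep = c("tab", "comma"), digits = 12L) {
  sep <- switch(match.arg(sep), tab = "\t", comma = ",")
  if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::assay(x, "beta")
  df <- cbind(feature_id = rownames(x),
              as.data.frame(signif(x, digits)))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the truth sidecar of a simulated data set
#'
#' Two blocks of tab-separated text: per-feature informative flags and
#' per-sample group labels, in separate files `<stem>_features.tsv` and
#' `<stem>_samples.tsv`.
#'
#' @param sim a \linkS4class{MethylSimulation}.
#' @param stem output path stem.
#' @export
writeSimulationTruth <- function(sim, stem) {
  stopifnot(is(sim, "MethylSimulation"))
  f <- data.frame(feature_id = rownames(sim),
                  informative = as.integer(informativeFeatures(sim)))
  s <- data.frame(sample_id = colnames(sim), group = groupLabels(sim))
  utils::write.table(f, paste0(stem, "_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(s, paste0(stem, "_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' Write filter scores as delimited text
#'
#' One row per feature with columns feature_id, statistic, rank_value,
#' filter_name, flag; multiple filters are stacked long-format.
#'
#' @param scores a \linkS4class{FilterScores} or a list of them.
#' @param path output file path.
#' @export
writeFilterScores <- function(scores, path) {
  if (is(scores, "FilterScores")) scores <- list(scores)
  tab <- do.call(rbind, lapply(scores, function(s)
    data.frame(feature_id = names(statistic(s)),
               statistic = signif(statistic(s), 12),
               rank_value = rankValue(s),
               filter_name = filterName(s),
               flag = as.integer(flagged(s)))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
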