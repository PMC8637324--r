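## Column filters on the call matrix: call-rate, variability, and
## gene-region subsetting (for the gene-restricted relationship matrix).

.subsetCols <- function(x, keep) {
  m <- x@calls[, keep, drop = FALSE]
  dimnames(m) <- list(rownames(x@calls), colnames(x@calls)[keep])
  new("WindowCallMatrix", calls = m, windowSize = x@windowSize)
}

#' Remove windows with insufficient call rate
#'
#' Keeps columns called (non-missing) in at least `minCallRate` of the
#' samples; the boundary is inclusive (a window called in exactly 80% of
#' samples survives the default). Row set and column order are unchanged.
#'
#' @param x a [WindowCallMatrix].
#' @param minCallRate minimum fraction of non-missing rows, in (0, 1].
#' @return the filtered [WindowCallMatrix].
#' @export
filterCallRate <- function(x, minCallRate = 0.8) {
  stopifnot(is(x, "WindowCallMatrix"))
  if (minCallRate <= 0 || minCallRate > 1)
    stop("minCallRate must lie in (0, 1]")
  if (nrow(x@calls) == 0) stop("matrix has no samples")
  rate <- colMeans(!is.na(x@calls))
  .subsetCols(x, rate >= minCallRate)
}

#' Remove non-variable windows
#'
#' Computes a per-column standard deviation of the 0/1 calls and removes
#' columns with SD strictly below `minSD` (an SD of exactly 0.5 is kept
#' under the default). Constant columns (SD 0) are always removed, as are
#' columns with fewer than two usable values (SD undefined; their count
#' is reported via `message()`).
#'
#' The SD definition is configurable because the binarized scale makes it
#' consequential: with the sample SD (n-1 denominator, the default) a
#' near-balanced 0/1 column can clear a 0.5 threshold, while the
#' population SD of a 0/1 column never exceeds 0.5 and would reach it
#' only at an exact 50/50 split, removing nearly everything. `sdRows`
#' chooses whether the SD is taken over the observed entries only
#' (default) or over all rows after column-mean imputation.
#'
#' @param x a [WindowCallMatrix] (apply [filterCallRate()] first).
#' @param minSD removal threshold: columns with SD < `minSD` are dropped.
#' @param sdDenominator `"sample"` (n-1) or `"population"` (n).
#' @param sdRows `"observed"` or `"imputed"`.
#' @return the filtered [WindowCallMatrix].
#' @export
filterVariability <- function(x, minSD = 0.5,
    sdDenominator = c("sample", "population"),
    sdRows = c("observed", "imputed")) {
  stopifnot(is(x, "WindowCallMatrix"))
  sdDenominator <- match.arg(sdDenominator)
  sdRows <- match.arg(sdRows)
  m <- x@calls
  if (ncol(m) == 0) return(x)
  colSD <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    if (sdRows == "imputed" && anyNA(v) && any(!is.na(v)))
      v[is.na(v)] <- mean(v, na.rm = TRUE)
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 2) return(NA_real_)
    s2 <- sum((v - mean(v))^2) /
      (if (sdDenominator == "sample") n - 1 else n)
    sqrt(s2)
  }, numeric(1))
  nUndef <- sum(is.na(colSD))
  if (nUndef > 0)
    message("removing ", nUndef,
      " column(s) with <2 usable values (SD undefined)")
  .subsetCols(x, !is.na(colSD) & colSD >= minSD)
}

#' Restrict the matrix to windows overlapping genes
#'
#' Keeps columns whose window interval overlaps at least one gene
#' interval by at least 1 bp. Windows are half-open `[i*w, (i+1)*w)` in
#' 0-based terms, so a gene starting exactly at the window end does not
#' overlap.
#'
#' @param x a [WindowCallMatrix].
#' @param genes a `GRanges` of gene intervals (e.g. from
#'   [readGeneAnnotation()]).
#' @return the subset [WindowCallMatrix].
#' @export
subsetToGenes <- function(x, genes) {
  stopifnot(is(x, "WindowCallMatrix"))
  if (length(genes) == 0) {
    warning("empty gene list: returning a matrix with no windows")
    return(.subsetCols(x, logical(ncol(x@calls))))
  }
  hits <- findOverlaps(windowRanges(x), genes, minoverlap = 1L,
    ignore.strand = TRUE)
  keep <- seq_len(ncol(x@calls)) %in% queryHits(hits)
  .subsetCols(x, keep)
}

#' Summary of a filtering step
#'
#' Convenience report comparing window counts before/after a filter
#' chain, as written by the pipeline stage.
#'
#' @param before,after [WindowCallMatrix] objects.
#' @param rule label of the rule applied.
#' @return one-row data.frame with columns `rule`, `windows_in`,
#'   `windows_out`, `windows_removed`.
#' @export
filterReport <- function(before, after, rule) {
  data.frame(rule = rule, windows_in = ncol(before@calls),
    windows_out = ncol(after@calls),
    windows_removed = ncol(before@calls) - ncol(after@calls),
    stringsAsFactors = FALSE)
}
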