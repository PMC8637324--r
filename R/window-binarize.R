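## Aggregation of per-site methylation frequencies into fixed windows and
## binarization into the 0/1/NA call matrix X.

#' Mean methylation per fixed window for one sample
#'
#' A site with 0-based start s maps to window index `floor(s / windowSize)`
#' on its chromosome (windows are anchored at coordinate 0). The window
#' value is the unweighted arithmetic mean of `methylated_frequency` over
#' the sites mapped to it — a mean over motif groups, not coverage-weighted,
#' and a multi-motif group still contributes a single value. Windows with
#' no sites are absent from the result.
#'
#' @param records site records of a single sample.
#' @param windowSize window width in bp (default 100).
#' @return data.frame with columns `chrom`, `window_index`,
#'   `mean_frequency`, sorted by (chrom, window_index).
#' @export
assignWindows <- function(records, windowSize = 100) {
  stopifnot(windowSize >= 1)
  if (length(unique(records$sample_id)) > 1)
    stop("assignWindows expects records from a single sample")
  if (nrow(records) == 0)
    return(data.frame(chrom = character(), window_index = integer(),
      mean_frequency = numeric(), stringsAsFactors = FALSE))
  if (any(records$methylated_frequency < 0 |
      records$methylated_frequency > 1))
    stop("methylated_frequency outside [0, 1]")
  idx <- records$start %/% as.integer(windowSize)
  key <- paste(records$chrom, idx, sep = "\r")
  agg <- tapply(records$methylated_frequency, key, mean)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    window_index = as.integer(vapply(parts, `[`, character(1), 2L)),
    mean_frequency = unname(as.numeric(agg)),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$window_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binarize window mean frequencies
#'
#' Applies the clock call rule: mean frequency > 0.5 is methylated (1),
#' < 0.5 unmethylated (0). A mean of exactly 0.5 satisfies neither
#' condition and carries no directional evidence, so it is returned as
#' NA, as is a missing input.
#'
#' @param meanFrequency numeric vector in [0, 1] (NA allowed).
#' @return integer vector of 0, 1 and NA.
#' @examples
#' binarizeCalls(c(0.7, 0.3, 0.5, NA))  # 1 0 NA NA
#' @export
binarizeCalls <- function(meanFrequency) {
  ok <- is.na(meanFrequency) |
    (meanFrequency >= 0 & meanFrequency <= 1)
  if (!all(ok)) stop("mean frequency outside [0, 1]")
  out <- rep(NA_integer_, length(meanFrequency))
  out[!is.na(meanFrequency) & meanFrequency > 0.5] <- 1L
  out[!is.na(meanFrequency) & meanFrequency < 0.5] <- 0L
  out
}

#' Assemble the samples-by-windows call matrix
#'
#' Takes per-sample window means (a named list of [assignWindows()]
#' results) and builds the binarized [WindowCallMatrix]: the column set is
#' the union of all windows observed in any sample; entries are NA where a
#' sample lacks the window.
#'
#' @param windowValues named list (names = sample ids, defining row
#'   order) of data.frames from [assignWindows()].
#' @param windowSize window width in bp recorded on the matrix.
#' @return a [WindowCallMatrix].
#' @export
buildCallMatrix <- function(windowValues, windowSize = 100) {
  sampleOrder <- names(windowValues)
  if (is.null(sampleOrder) || anyDuplicated(sampleOrder))
    stop("windowValues must be a named list with unique sample ids")
  all_df <- do.call(rbind, lapply(sampleOrder, function(sid) {
    df <- windowValues[[sid]]
    if (nrow(df) == 0) return(NULL)
    data.frame(sample_id = sid, chrom = df$chrom,
      window_index = df$window_index,
      mean_frequency = df$mean_frequency, stringsAsFactors = FALSE)
  }))
  if (is.null(all_df)) {
    calls <- matrix(NA_integer_, nrow = length(sampleOrder), ncol = 0,
      dimnames = list(sampleOrder, character()))
    return(new("WindowCallMatrix", calls = calls,
      windowSize = as.integer(windowSize)))
  }
  keyDf <- unique(all_df[, c("chrom", "window_index")])
  keyDf <- keyDf[order(keyDf$chrom, keyDf$window_index), , drop = FALSE]
  keys <- .windowKey(keyDf$chrom, keyDf$window_index)
  calls <- matrix(NA_integer_, nrow = length(sampleOrder),
    ncol = length(keys), dimnames = list(sampleOrder, keys))
  rIdx <- match(all_df$sample_id, sampleOrder)
  cIdx <- match(.windowKey(all_df$chrom, all_df$window_index), keys)
  calls[cbind(rIdx, cIdx)] <- binarizeCalls(all_df$mean_frequency)
  new("WindowCallMatrix", calls = calls,
    windowSize = as.integer(windowSize))
}

#' Call matrix straight from long-format site records
#'
#' Convenience wrapper: splits a multi-sample record table, windows each
#' sample with [assignWindows()] and assembles the matrix with
#' [buildCallMatrix()].
#'
#' @param records long data.frame of site records with a `sample_id`
#'   column.
#' @param windowSize window width in bp.
#' @param sampleOrder row order; defaults to order of first appearance.
#' @return a [WindowCallMatrix].
#' @export
windowCallMatrix <- function(records, windowSize = 100,
    sampleOrder = unique(records$sample_id)) {
  if (anyDuplicated(sampleOrder)) stop("duplicate sample_id in order")
  perSample <- lapply(setNames(sampleOrder, sampleOrder), function(sid)
    assignWindows(records[records$sample_id == sid, , drop = FALSE],
      windowSize))
  buildCallMatrix(perSample, windowSize)
}
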