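#' Samples-by-windows binary methylation call matrix
#'
#' Holds the matrix X of the clock analysis: rows are samples, columns are
#' fixed-width genomic windows, entries are 1 (window methylated: mean site
#' frequency > 0.5), 0 (unmethylated: mean < 0.5) or NA (no sequencing
#' coverage, or an exact 0.5 tie). Column names encode the window as
#' \code{"chrom:windowIndex"} with \code{windowIndex = floor(start0 / windowSize)}
#' over 0-based site starts, i.e. windows are anchored at coordinate 0 of
#' each chromosome.
#'
#' @slot calls integer matrix with entries in \{0, 1, NA\}; rownames are
#'   sample ids, colnames are window keys sorted by (chrom, windowIndex).
#' @slot windowSize window width in bp.
#'
#' @seealso [buildCallMatrix()], [windowRanges()], [filterCallRate()]
#' @exportClass WindowCallMatrix
setClass("WindowCallMatrix",
  representation(calls = "matrix", windowSize = "integer"))

setValidity("WindowCallMatrix", function(object) {
  m <- object@calls
  msg <- character()
  if (length(object@windowSize) != 1L || is.na(object@windowSize) ||
      object@windowSize < 1L)
    msg <- c(msg, "windowSize must be a single integer >= 1")
  if (nrow(m) > 0L && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
    msg <- c(msg, "rownames (sample ids) must be present and unique")
  if (ncol(m) > 0L && (is.null(colnames(m)) || anyDuplicated(colnames(m))))
    msg <- c(msg, "colnames (window keys) must be present and unique")
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msg <- c(msg, "entries must be 0, 1 or NA")
  if (ncol(m) > 1L) {
    k <- .parseWindowKeys(colnames(m))
    o <- order(k$chrom, k$index)
    if (!identical(o, seq_len(ncol(m))))
      msg <- c(msg, "columns must be sorted by (chrom, windowIndex)")
  }
  if (length(msg)) msg else TRUE
})

#' Methylation relationship matrix
#'
#' The sample-by-sample similarity matrix MRM = XX'/m computed from a
#' complete (imputed) call matrix X with m columns. Plays the role the
#' genomic relationship matrix plays in GBLUP. For the literal
#' \code{"as_stated"} variant on 0/1 calls all entries lie in [0, 1]; the
#' \code{"centered_standardized"} variant column-centers and scales X first
#' (the GCTA-style construction).
#'
#' @slot values symmetric positive semidefinite n-by-n numeric matrix with
#'   sample ids as dimnames.
#' @slot nSites number of columns m used in the denominator.
#' @slot variant \code{"as_stated"} or \code{"centered_standardized"}.
#'
#' @seealso [computeMRM()], [imputeMissing()]
#' @exportClass MethylationRelationshipMatrix
setClass("MethylationRelationshipMatrix",
  representation(values = "matrix", nSites = "integer", variant = "character"))

setValidity("MethylationRelationshipMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "dimnames must be identical sample ids on both margins")
  if (max(abs(v - t(v))) > 1e-10)
    msg <- c(msg, "matrix must be symmetric within 1e-10")
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (length(ev) && min(ev) < -1e-8 * max(abs(ev), 1))
    msg <- c(msg, "matrix must be positive semidefinite")
  if (!(object@variant %in% c("as_stated", "centered_standardized")))
    msg <- c(msg, "variant must be 'as_stated' or 'centered_standardized'")
  if (object@nSites < 1L) msg <- c(msg, "nSites must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Fitted methylation clock mixed model
#'
#' REML fit of age = mu + herd + animal + error where the per-sample
#' "animal" effects are random with covariance sigma2Animal * MRM and the
#' residuals are iid with variance sigma2Error.
#'
#' @slot sigma2Animal animal-effect variance (years^2).
#' @slot sigma2Error residual variance (years^2).
#' @slot h2 variance ratio sigma2Animal / (sigma2Animal + sigma2Error).
#' @slot fixedEffects named numeric: intercept and herd (and optionally
#'   season) effects, in years.
#' @slot blup named numeric: per-sample BLUP of the animal effect (years).
#' @slot logRestrictedLik restricted log-likelihood at the optimum.
#'
#' @seealso [fitREML()], [fitClockModel()]
#' @exportClass ClockModelFit
setClass("ClockModelFit",
  representation(sigma2Animal = "numeric", sigma2Error = "numeric",
    h2 = "numeric", fixedEffects = "numeric", blup = "numeric",
    logRestrictedLik = "numeric"))

setValidity("ClockModelFit", function(object) {
  msg <- character()
  if (object@sigma2Animal < 0) msg <- c(msg, "sigma2Animal must be >= 0")
  if (object@sigma2Error <= 0) msg <- c(msg, "sigma2Error must be > 0")
  if (is.null(names(object@blup))) msg <- c(msg, "blup must be named by sample")
  if (length(msg)) msg else TRUE
})

#' Cross-validated clock accuracy
#'
#' Result of leave-group-out cross-validation of the methylation clock:
#' each fold of samples has its ages masked, the model is refit on the
#' remainder, and ages are predicted through the MRM covariances.
#'
#' @slot folds list of character vectors of sample ids (a partition).
#' @slot predicted named numeric, pooled out-of-fold predicted ages (years).
#' @slot actual named numeric, actual ages (years).
#' @slot accuracy Pearson correlation of predicted vs actual (pooled).
#' @slot accuracySE SD of per-fold correlations / sqrt(number of folds).
#' @slot perFoldCor numeric, per-fold correlations (NA where undefined).
#' @slot madByClass named numeric, mean absolute deviation (years) by
#'   age class.
#'
#' @seealso [crossValidate()], [madByAgeClass()]
#' @exportClass CrossValidationResult
setClass("CrossValidationResult",
  representation(folds = "list", predicted = "numeric", actual = "numeric",
    accuracy = "numeric", accuracySE = "numeric", perFoldCor = "numeric",
    madByClass = "numeric"))

setValidity("CrossValidationResult", function(object) {
  ids <- sort(unlist(object@folds, use.names = FALSE))
  msg <- character()
  if (anyDuplicated(ids))
    msg <- c(msg, "every sample must appear in exactly one fold")
  if (!identical(ids, sort(names(object@predicted))))
    msg <- c(msg, "folds must partition the predicted samples")
  if (length(object@madByClass) && any(object@madByClass < 0))
    msg <- c(msg, "madByClass values must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "WindowCallMatrix", function(object) {
  m <- object@calls
  nNA <- sum(is.na(m))
  cat(sprintf(
    "WindowCallMatrix: %d samples x %d windows (%d bp), %.1f%% missing\n",
    nrow(m), ncol(m), object@windowSize,
    if (length(m)) 100 * nNA / length(m) else 0))
})

setMethod("show", "MethylationRelationshipMatrix", function(object) {
  cat(sprintf(
    "MethylationRelationshipMatrix (%s): %d samples, m = %d sites\n",
    object@variant, nrow(object@values), object@nSites))
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
    mean(diag(object@values)),
    mean(object@values[row(object@values) != col(object@values)])))
})

setMethod("show", "ClockModelFit", function(object) {
  cat("ClockModelFit (MeBLUP REML)\n")
  cat(sprintf("  sigma2_animal = %.4f, sigma2_error = %.4f (h = %.3f)\n",
    object@sigma2Animal, object@sigma2Error, object@h2))
  cat(sprintf("  logREML = %.4f; fixed effects: %s\n",
    object@logRestrictedLik,
    paste(sprintf("%s=%.3f", names(object@fixedEffects),
      object@fixedEffects), collapse = ", ")))
})

setMethod("show", "CrossValidationResult", function(object) {
  cat(sprintf(
    "CrossValidationResult: %d folds, %d samples\n  accuracy (pooled r) = %.3f +/- %.3f\n",
    length(object@folds), length(object@predicted), object@accuracy,
    object@accuracySE))
  if (length(object@madByClass)) {
    cat("  MAD by age class (years):",
      paste(sprintf("%s: %.2f", names(object@madByClass),
        object@madByClass), collapse = ", "), "\n")
  }
})

## ---- accessors ----

#' @rdname WindowCallMatrix-class
#' @param x a \code{WindowCallMatrix}.
#' @export
callMatrix <- function(x) {
  stopifnot(is(x, "WindowCallMatrix"))
  x@calls
}

#' @rdname WindowCallMatrix-class
#' @export
windowSize <- function(x) {
  stopifnot(is(x, "WindowCallMatrix"))
  x@windowSize
}

#' @rdname WindowCallMatrix-class
#' @export
sampleIds <- function(x) {
  if (is(x, "WindowCallMatrix")) return(rownames(x@calls))
  if (is(x, "MethylationRelationshipMatrix")) return(rownames(x@values))
  stop("no sample ids for this object")
}

#' @rdname WindowCallMatrix-class
#' @export
windowKeys <- function(x) {
  stopifnot(is(x, "WindowCallMatrix"))
  cn <- colnames(x@calls)
  if (is.null(cn)) character(0) else cn
}

#' Genomic intervals of the matrix windows
#'
#' Converts the window keys of a [WindowCallMatrix] into a
#' \code{GRanges} (1-based closed coordinates): window index i spans
#' 0-based half-open \code{[i*w, (i+1)*w)}, i.e. 1-based
#' \code{(i*w + 1):((i+1)*w)}.
#'
#' @param x a \code{WindowCallMatrix}.
#' @return a \code{GRanges} parallel to the matrix columns.
#' @export
windowRanges <- function(x) {
  stopifnot(is(x, "WindowCallMatrix"))
  k <- .parseWindowKeys(colnames(x@calls))
  w <- as.integer(x@windowSize)
  GRanges(k$chrom, IRanges(start = k$index * w + 1L, width = w))
}

#' @rdname MethylationRelationshipMatrix-class
#' @param x a \code{MethylationRelationshipMatrix}.
#' @export
mrmValues <- function(x) {
  stopifnot(is(x, "MethylationRelationshipMatrix"))
  x@values
}

#' @rdname MethylationRelationshipMatrix-class
#' @export
nSites <- function(x) {
  stopifnot(is(x, "MethylationRelationshipMatrix"))
  x@nSites
}

#' @rdname ClockModelFit-class
#' @param x a \code{ClockModelFit}.
#' @export
varianceComponents <- function(x) {
  stopifnot(is(x, "ClockModelFit"))
  c(sigma2_animal = x@sigma2Animal, sigma2_error = x@sigma2Error,
    h = x@h2)
}

#' @rdname ClockModelFit-class
#' @export
fixedEffects <- function(x) {
  stopifnot(is(x, "ClockModelFit"))
  x@fixedEffects
}

#' @rdname ClockModelFit-class
#' @export
blup <- function(x) {
  stopifnot(is(x, "ClockModelFit"))
  x@blup
}

#' @rdname CrossValidationResult-class
#' @param x a \code{CrossValidationResult}.
#' @export
accuracy <- function(x) {
  stopifnot(is(x, "CrossValidationResult"))
  x@accuracy
}

#' @rdname CrossValidationResult-class
#' @export
accuracySE <- function(x) {
  stopifnot(is(x, "CrossValidationResult"))
  x@accuracySE
}

#' @rdname CrossValidationResult-class
#' @export
predictedAges <- function(x) {
  stopifnot(is(x, "CrossValidationResult"))
  x@predicted
}

#' @rdname CrossValidationResult-class
#' @export
madByClass <- function(x) {
  stopifnot(is(x, "CrossValidationResult"))
  x@madByClass
}

## window keys "chrom:index" -> list(chrom, index); chrom may contain ':'
## only if it never ends in digits, so split on the last ':'
.parseWindowKeys <- function(keys) {
  pos <- regexpr(":[0-9]+$", keys)
  if (any(pos < 0)) stop("malformed window key(s): ",
    paste(head(keys[pos < 0], 3), collapse = ", "))
  list(chrom = substr(keys, 1L, pos - 1L),
       index = as.integer(substr(keys, pos + 1L, nchar(keys))))
}

.windowKey <- function(chrom, index) paste0(chrom, ":", index)
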