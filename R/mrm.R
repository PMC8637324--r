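## Column-mean imputation and the methylation relationship matrix
## MRM = XX'/m.

#' Impute missing calls by column means
#'
#' Replaces each missing entry by the mean of the non-missing entries of
#' its column, leaving observed calls untouched. This is the
#' minimal-assumption completion of the 0/1 matrix required by the MRM
#' formula and keeps the resulting Gram matrix positive semidefinite.
#'
#' @param x a [WindowCallMatrix] (post-filtering: every column must have
#'   at least one observed entry).
#' @return a numeric matrix with values in [0, 1] and the same dimnames.
#' @export
imputeMissing <- function(x) {
  stopifnot(is(x, "WindowCallMatrix"))
  m <- x@calls
  storage.mode(m) <- "double"
  if (ncol(m) == 0) return(m)
  nObs <- colSums(!is.na(m))
  if (any(nObs == 0))
    stop("all-missing column(s) present; apply filterCallRate() first: ",
      paste(head(colnames(m)[nObs == 0], 3), collapse = ", "))
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
  }
  m
}

#' Compute the methylation relationship matrix
#'
#' The literal construction (`variant = "as_stated"`) is MRM = XX'/m with
#' X the complete call matrix and m its number of columns; on 0/1 calls
#' every entry then lies in [0, 1] and the diagonal holds each sample's
#' methylated-window fraction. The `"centered_standardized"` variant
#' first centers each column by its mean and scales by its SD (columns
#' with zero SD are dropped), the construction GRM tools such as GCTA
#' use; it is provided for sensitivity analysis.
#'
#' @param X complete numeric matrix (samples x sites), e.g. from
#'   [imputeMissing()].
#' @param variant `"as_stated"` (default) or `"centered_standardized"`.
#' @return a [MethylationRelationshipMatrix].
#' @examples
#' X <- diag(2); dimnames(X) <- list(c("a", "b"), c("w1", "w2"))
#' mrmValues(computeMRM(X))  # 0.5 on the diagonal, 0 off it
#' @export
computeMRM <- function(X, variant = c("as_stated",
    "centered_standardized")) {
  variant <- match.arg(variant)
  if (is.null(rownames(X))) stop("X must carry sample ids as rownames")
  if (ncol(X) < 1) stop("X must have at least one column")
  if (anyNA(X)) stop("X must be complete; run imputeMissing() first")
  if (variant == "centered_standardized") {
    sds <- apply(X, 2, sd)
    keep <- sds > 0
    if (!any(keep)) stop("all columns have zero variance")
    X <- scale(X[, keep, drop = FALSE])
  }
  m <- ncol(X)
  V <- tcrossprod(X) / m
  V <- (V + t(V)) / 2
  dimnames(V) <- list(rownames(X), rownames(X))
  new("MethylationRelationshipMatrix", values = V, nSites = as.integer(m),
    variant = variant)
}

#' Write / read a relationship matrix as TSV
#'
#' @param mrm a [MethylationRelationshipMatrix].
#' @param path file path.
#' @export
writeMRM <- function(mrm, path) {
  writeMatrixTSV(mrm@values, path)
}

#' @rdname writeMRM
#' @param nSitesUsed m recorded on the re-read object.
#' @param variant construction variant recorded on the re-read object.
#' @export
readMRM <- function(path, nSitesUsed, variant = "as_stated") {
  v <- readMatrixTSV(path)
  colnames(v) <- rownames(v)
  new("MethylationRelationshipMatrix", values = (v + t(v)) / 2,
    nSites = as.integer(nSitesUsed), variant = variant)
}
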