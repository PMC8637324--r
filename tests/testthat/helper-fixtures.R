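## Shared fixtures and independent oracles used across test files.

## A minimal record data.frame in the internal layout.
makeRecords <- function(chrom, start, called, methylated, sampleId,
    end = start + 1L) {
  data.frame(chrom = chrom, start = as.integer(start),
    end = as.integer(end), num_motifs = 1L,
    called_sites = as.integer(called),
    called_sites_methylated = as.integer(methylated),
    methylated_frequency = methylated / called,
    sample_id = sampleId, stringsAsFactors = FALSE)
}

## Write a methylation-frequency TSV from raw columns.
writeFreqTSV <- function(path, rows,
    header = c("chromosome", "start", "end", "num_motifs_in_group",
      "called_sites", "called_sites_methylated", "methylated_frequency",
      "group_sequence")) {
  writeLines(c(paste(header, collapse = "\t"),
    vapply(rows, paste, character(1), collapse = "\t")), path)
}

## Random WindowCallMatrix with controlled missingness.
randomCallMatrix <- function(nSamples, nWindows, pMissing = 0.2,
    windowSize = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(c(0L, 1L), nSamples * nWindows, replace = TRUE),
    nSamples, nWindows)
  m[matrix(runif(length(m)) < pMissing, nSamples, nWindows)] <- NA
  dimnames(m) <- list(sprintf("S%03d", seq_len(nSamples)),
    paste0("chr1:", seq_len(nWindows) - 1L))
  new("WindowCallMatrix", calls = m, windowSize = as.integer(windowSize))
}

## Random PSD relationship matrix.
randomMRM <- function(n, m = 4 * n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rbinom(n * m, 1, 0.5), n, m,
    dimnames = list(sprintf("S%03d", seq_len(n)), NULL))
  computeMRM(X)
}

## Dense restricted log-likelihood oracle: explicit V, determinants.
denseREMLLogLik <- function(y, X, K, s2a, s2e) {
  n <- length(y); p <- ncol(X)
  V <- s2a * K + s2e * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
    determinant(XtViX, logarithm = TRUE)$modulus +
    t(r) %*% Vi %*% r + (n - p) * log(2 * pi)))
}

## Dense GLS fixed effects + BLUP oracle at given variance components.
denseGLSBlup <- function(y, X, K, s2a, s2e) {
  n <- length(y)
  V <- s2a * K + s2e * diag(n)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2a * K %*% Vi %*% (y - X %*% beta)
  list(beta = unname(drop(beta)), u = unname(drop(u)))
}

## The ridged kinship exactly as the solver builds it.
ridgedK <- function(K, ridge = 1e-6) K + diag(ridge * mean(diag(K)), nrow(K))
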