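## MeBLUP: REML variance components and BLUP for the model
##   age = mu + herd + animal + error,   animal ~ N(0, sigma2_a * MRM)
## fitted by a single eigendecomposition of the (ridge-stabilised) MRM
## and a profiled restricted likelihood over the variance ratio
## h = sigma2_a / (sigma2_a + sigma2_e).

## Core solver on raw matrices. Returns all internals; fitREML() wraps
## them into the S4 result. The restricted log-likelihood reported is
##   -0.5 * ( log|V| + log|X'V^-1 X| + r'V^-1 r + (n - p) log 2pi )
## with V = sigma2_a * K_ridged + sigma2_e * I, the same definition a
## dense-matrix evaluation uses.
.remlCore <- function(y, X, K, ridge = 1e-6, hGrid = 201L) {
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("fixed-effect design is singular; collinear column(s): ",
      paste(bad, collapse = ", "))
  }
  eps <- ridge * mean(diag(K))
  Kr <- K + diag(eps, n)
  eg <- eigen(Kr, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  profile <- function(h) {
    w <- h * d + (1 - h)
    Xw <- Xt / w
    XtWX <- crossprod(Xt, Xw)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(list(obj = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xw, yt)))
    r <- yt - Xt %*% beta
    rss <- sum(r^2 / w)
    sigma2 <- rss / (n - p)
    obj <- (n - p) * log(sigma2) + sum(log(w)) +
      2 * sum(log(diag(ch)))
    list(obj = obj, beta = drop(beta), sigma2 = sigma2, w = w, r = drop(r))
  }

  hs <- seq(0, 0.9999, length.out = hGrid)
  objs <- vapply(hs, function(h) profile(h)$obj, numeric(1))
  i <- which.min(objs)
  lo <- hs[max(1L, i - 1L)]
  hi <- hs[min(length(hs), i + 1L)]
  hHat <- if (lo < hi)
    optimize(function(h) profile(h)$obj, c(lo, hi), tol = 1e-7)$minimum
  else hs[i]
  if (profile(hs[i])$obj < profile(hHat)$obj) hHat <- hs[i]

  sol <- profile(hHat)
  sigma2 <- sol$sigma2
  sigma2A <- hHat * sigma2
  sigma2E <- (1 - hHat) * sigma2
  ## BLUP: u = sigma2_a K V^-1 (y - X beta) = U diag(h d / w) U' r
  u <- drop(U %*% (hHat * d / sol$w * sol$r))
  VinvR <- drop(U %*% (sol$r / (sigma2 * sol$w)))
  logREML <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2) +
    sum(log(sol$w)) + .logdet(crossprod(Xt, Xt / sol$w)) + (n - p))
  list(h = hHat, sigma2 = sigma2, sigma2A = sigma2A, sigma2E = sigma2E,
    beta = setNames(sol$beta, colnames(X)), u = u, VinvR = VinvR,
    logREML = logREML, eps = eps)
}

.logdet <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)

#' Fit the clock mixed model by REML
#'
#' Estimates the animal and residual variances of
#' `age = X beta + animal + error` with `animal ~ N(0, sigma2_a * MRM)`
#' and iid errors. The (ridge-stabilised) MRM is eigendecomposed once and
#' the restricted likelihood, with the total variance profiled out, is
#' minimised over the variance ratio `h = sigma2_a / (sigma2_a +
#' sigma2_e)` on a grid followed by golden-section polishing; fixed
#' effects and BLUPs come from the mixed-model equations at the optimum.
#'
#' A ridge of `ridge * mean(diag(MRM))` is added to the MRM diagonal
#' before factorisation for numerical stability (it is never stored on
#' the MRM object itself).
#'
#' @param ages named numeric vector of ages (years).
#' @param fixedDesign numeric design matrix (samples x effects, full
#'   column rank, rownames = sample ids) — typically an intercept plus
#'   herd indicator columns.
#' @param mrm a [MethylationRelationshipMatrix] over the same samples in
#'   the same order.
#' @param ridge relative ridge added to the MRM diagonal at solve time.
#' @return a [ClockModelFit].
#' @seealso [fitClockModel()] for the metadata-level interface,
#'   [predictMasked()], [crossValidate()].
#' @export
fitREML <- function(ages, fixedDesign, mrm, ridge = 1e-6) {
  stopifnot(is(mrm, "MethylationRelationshipMatrix"))
  ids <- sampleIds(mrm)
  if (!is.null(names(ages)) && !identical(names(ages), ids))
    stop("ages must be ordered as the MRM samples")
  if (!is.null(rownames(fixedDesign)) &&
      !identical(rownames(fixedDesign), ids))
    stop("fixedDesign rows must be ordered as the MRM samples")
  if (any(!is.finite(ages))) stop("ages must be finite")
  core <- .remlCore(as.numeric(ages), fixedDesign, mrm@values, ridge)
  new("ClockModelFit", sigma2Animal = core$sigma2A,
    sigma2Error = core$sigma2E, h2 = core$h,
    fixedEffects = core$beta, blup = setNames(core$u, ids),
    logRestrictedLik = core$logREML)
}

## Fixed-effect design from metadata: intercept + herd (reference =
## largest herd) + optionally season. Rownames are sample ids.
.clockDesign <- function(metadata, useHerd = TRUE, useSeason = FALSE) {
  n <- nrow(metadata)
  X <- matrix(1, n, 1, dimnames = list(metadata$sample_id, "(Intercept)"))
  addFactor <- function(X, values, prefix) {
    f <- factor(values)
    ref <- names(which.max(table(f)))
    f <- relevel(f, ref = ref)
    singles <- names(which(table(f) == 1L))
    if (length(singles))
      message(prefix, " level(s) with a single sample: ",
        paste(singles, collapse = ", "))
    if (nlevels(f) > 1) {
      D <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(D) <- paste0(prefix, levels(f)[-1])
      X <- cbind(X, D)
    }
    X
  }
  if (useHerd) X <- addFactor(X, metadata$herd, "herd")
  if (useSeason) {
    if (is.null(metadata$season))
      stop("useSeason = TRUE but metadata has no season column")
    X <- addFactor(X, metadata$season, "season")
  }
  rownames(X) <- metadata$sample_id
  X
}

#' Fit the clock model from sample metadata
#'
#' Builds the fixed-effect design (intercept, herd with the largest herd
#' as reference, optional season) from a metadata table and calls
#' [fitREML()]. Metadata rows are matched to the MRM samples by
#' `sample_id`.
#'
#' @param metadata data.frame from [readSampleMetadata()].
#' @param mrm a [MethylationRelationshipMatrix].
#' @param useHerd include the herd fixed effect (default TRUE; the model
#'   without it conflates herd-driven methylation differences with age).
#' @param useSeason include season as an additional fixed effect.
#' @param ridge see [fitREML()].
#' @return a [ClockModelFit].
#' @export
fitClockModel <- function(metadata, mrm, useHerd = TRUE,
    useSeason = FALSE, ridge = 1e-6) {
  ids <- sampleIds(mrm)
  idx <- match(ids, metadata$sample_id)
  if (anyNA(idx)) stop("metadata is missing MRM sample(s): ",
    paste(head(ids[is.na(idx)], 3), collapse = ", "))
  md <- metadata[idx, , drop = FALSE]
  X <- .clockDesign(md, useHerd, useSeason)
  fitREML(setNames(md$age_years, md$sample_id), X, mrm, ridge)
}

#' Predict ages for phenotype-masked samples
#'
#' Implements the clock validation scheme: the masked samples' ages are
#' removed, REML and fixed effects are re-estimated on the remaining
#' samples only, and the masked samples' animal effects are predicted
#' through their MRM covariances with the training samples,
#' `u_masked = sigma2_a K[masked, train] V_train^-1 (y - X beta)` —
#' the conditional expectation of the unobserved effects. Predicted age
#' is the estimable fixed-effect part plus the predicted effect; a
#' masked sample whose herd is absent from training falls back to the
#' intercept alone, with a warning.
#'
#' @param ages named numeric vector over all MRM samples (years); masked
#'   entries may be anything — they are not used.
#' @param fixedDesign design matrix over all MRM samples.
#' @param mrm a [MethylationRelationshipMatrix] over all samples.
#' @param maskedIds character vector, a non-empty strict subset of the
#'   MRM sample ids.
#' @param ridge see [fitREML()].
#' @return list with `predicted` (named numeric over `maskedIds`) and
#'   `fit` (the training [ClockModelFit]).
#' @export
predictMasked <- function(ages, fixedDesign, mrm, maskedIds,
    ridge = 1e-6) {
  stopifnot(is(mrm, "MethylationRelationshipMatrix"))
  ids <- sampleIds(mrm)
  if (!all(maskedIds %in% ids)) stop("maskedIds must be MRM samples")
  if (length(maskedIds) == 0 || length(maskedIds) >= length(ids))
    stop("maskedIds must be a non-empty strict subset of the samples")
  if (is.null(names(ages))) names(ages) <- ids
  if (is.null(rownames(fixedDesign))) rownames(fixedDesign) <- ids
  train <- setdiff(ids, maskedIds)
  K <- mrm@values
  Xall <- fixedDesign[ids, , drop = FALSE]
  Xt <- Xall[train, , drop = FALSE]
  keep <- colSums(abs(Xt)) > 0
  orphan <- rowSums(abs(Xall[maskedIds, !keep, drop = FALSE])) > 0
  if (any(orphan))
    warning("masked sample(s) from herd/level unseen in training; ",
      "prediction falls back to estimable effects only: ",
      paste(maskedIds[orphan], collapse = ", "))
  core <- .remlCore(as.numeric(ages[train]), Xt[, keep, drop = FALSE],
    K[train, train], ridge)
  uMasked <- drop(core$sigma2A *
    K[maskedIds, train, drop = FALSE] %*% core$VinvR)
  pred <- drop(Xall[maskedIds, keep, drop = FALSE] %*% core$beta) + uMasked
  fit <- new("ClockModelFit", sigma2Animal = core$sigma2A,
    sigma2Error = core$sigma2E, h2 = core$h, fixedEffects = core$beta,
    blup = setNames(core$u, train), logRestrictedLik = core$logREML)
  list(predicted = setNames(pred, maskedIds), fit = fit)
}

## Partition samples into ceiling(n / foldSize) folds under a seed,
## keeping all samples of one animal in the same fold (repeat samples
## would otherwise leak near-duplicate methylation profiles across the
## train/validation split).
.makeFolds <- function(sampleIds, animalIds, foldSize, seed) {
  if (foldSize <= 0) stop("foldSize must be positive")
  n <- length(sampleIds)
  nFolds <- ceiling(n / foldSize)
  set.seed(seed)
  animals <- sample(unique(animalIds))
  folds <- vector("list", nFolds)
  sizes <- integer(nFolds)
  for (a in animals) {
    s <- sampleIds[animalIds == a]
    j <- which.min(sizes)
    folds[[j]] <- c(folds[[j]], s)
    sizes[j] <- sizes[j] + length(s)
  }
  folds[lengths(folds) > 0]
}

#' Cross-validated clock accuracy
#'
#' Partitions the samples into `ceiling(n / foldSize)` folds under the
#' seed (samples sharing an `animal_id` stay in one fold), masks each
#' fold in turn with [predictMasked()] — variance components re-estimated
#' on each training set — and pools the out-of-fold predictions.
#' Accuracy is the Pearson correlation of pooled predicted vs actual
#' age; its standard error is the SD of the per-fold correlations
#' divided by the square root of the number of folds (folds where the
#' correlation is undefined are dropped from the SE). Mean absolute
#' deviations are summarised by age class via [madByAgeClass()].
#'
#' @param metadata data.frame with `sample_id`, `animal_id`, `herd`,
#'   `age_years` (and optionally `season`).
#' @param mrm a [MethylationRelationshipMatrix].
#' @param foldSize target samples per fold (default 5).
#' @param seed integer seed for the fold partition.
#' @param useHerd,useSeason,ridge passed to the model fit.
#' @param breaks age-class boundaries in years for the MAD summary.
#' @return a [CrossValidationResult].
#' @export
crossValidate <- function(metadata, mrm, foldSize = 5, seed = 1,
    useHerd = TRUE, useSeason = FALSE, ridge = 1e-6, breaks = c(3, 10)) {
  ids <- sampleIds(mrm)
  if (length(ids) < 2 * foldSize)
    stop("need at least 2 * foldSize samples")
  idx <- match(ids, metadata$sample_id)
  if (anyNA(idx)) stop("metadata is missing MRM sample(s)")
  md <- metadata[idx, , drop = FALSE]
  X <- .clockDesign(md, useHerd, useSeason)
  ages <- setNames(md$age_years, md$sample_id)
  folds <- .makeFolds(md$sample_id, md$animal_id, foldSize, seed)

  predicted <- setNames(rep(NA_real_, length(ids)), ids)
  perFold <- rep(NA_real_, length(folds))
  for (k in seq_along(folds)) {
    res <- predictMasked(ages, X, mrm, folds[[k]], ridge)
    predicted[folds[[k]]] <- res$predicted
    act <- ages[folds[[k]]]
    if (length(act) >= 2 && sd(act) > 0 && sd(res$predicted) > 0)
      perFold[k] <- cor(res$predicted, act)
  }
  acc <- cor(predicted, ages)
  accSE <- sd(perFold, na.rm = TRUE) / sqrt(length(folds))
  new("CrossValidationResult", folds = folds, predicted = predicted,
    actual = ages, accuracy = acc, accuracySE = accSE,
    perFoldCor = perFold,
    madByClass = madByAgeClass(predicted, ages, breaks))
}

#' Mean absolute deviation by age class
#'
#' Classes are assigned by actual age with half-open boundaries: with the
#' default breaks (3, 10) they are `<3`, `3-10` (3 inclusive, 10
#' exclusive) and `>=10` years. Empty classes are absent from the result.
#'
#' @param predicted,actual equal-length numeric vectors (years).
#' @param breaks increasing numeric vector of class boundaries (years).
#' @return named numeric vector of within-class means of
#'   `|predicted - actual|`.
#' @examples
#' madByAgeClass(c(2, 5, 12), c(1, 4, 14))  # 1, 1 and 2 years
#' @export
madByAgeClass <- function(predicted, actual, breaks = c(3, 10)) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  stopifnot(length(breaks) >= 1, !is.unsorted(breaks, strictly = TRUE))
  b <- c(-Inf, breaks, Inf)
  labels <- c(paste0("<", breaks[1]),
    if (length(breaks) > 1)
      paste0(breaks[-length(breaks)], "-", breaks[-1]),
    paste0(">=", breaks[length(breaks)]))
  cls <- cut(actual, b, right = FALSE, labels = labels)
  err <- abs(predicted - actual)
  out <- tapply(err, cls, mean)
  out <- out[!is.na(out)]
  setNames(as.numeric(out), names(out))
}
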