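test_that("REML optimum matches the dense-matrix restricted likelihood", {
  set.seed(42)
  n <- 8
  A <- matrix(rnorm(n * 20), n)
  K <- tcrossprod(A) / 20
  dimnames(K) <- list(paste0("s", 1:n), paste0("s", 1:n))
  herd <- rep(c("h1", "h2"), each = 4)
  X <- cbind(`(Intercept)` = 1, herdh2 = as.numeric(herd == "h2"))
  rownames(X) <- rownames(K)
  y <- 2 + (herd == "h2") + drop(chol(K + diag(1e-6, n)) %*% rnorm(n)) +
    rnorm(n)
  mrm <- new("MethylationRelationshipMatrix", values = K, nSites = 20L,
    variant = "as_stated")
  fit <- fitREML(setNames(y, rownames(K)), X, mrm)
  vc <- varianceComponents(fit)
  Kr <- ridgedK(K)

  llDense <- denseREMLLogLik(y, X, Kr, vc["sigma2_animal"],
    vc["sigma2_error"])
  expect_equal(fit@logRestrictedLik, llDense, tolerance = 1e-6)

  ## the optimum beats a grid of alternative variance ratios
  s2 <- vc["sigma2_animal"] + vc["sigma2_error"]
  gridLL <- vapply(seq(0.01, 0.99, by = 0.02), function(h)
    denseREMLLogLik(y, X, Kr, h * s2, (1 - h) * s2), numeric(1))
  expect_gte(fit@logRestrictedLik, max(gridLL) - 1e-9)

  ## fixed effects and BLUP match the dense GLS formulas
  o <- denseGLSBlup(y, X, Kr, vc["sigma2_animal"], vc["sigma2_error"])
  expect_equal(unname(fixedEffects(fit)), o$beta, tolerance = 1e-8)
  expect_equal(unname(blup(fit)), o$u, tolerance = 1e-8)
})

test_that("degenerate cases: vanishing kinship gives OLS, identity kinship shrinks residuals", {
  set.seed(7)
  n <- 20
  herd <- rep(c("h1", "h2"), each = 10)
  X <- cbind(`(Intercept)` = 1, herdh2 = as.numeric(herd == "h2"))
  ids <- sprintf("s%02d", 1:n)
  rownames(X) <- ids
  y <- setNames(3 + 2 * (herd == "h2") + rnorm(n), ids)

  ## K ~ 0: no usable similarity, u -> 0 and fixed effects -> OLS
  K0 <- diag(1e-10, n); dimnames(K0) <- list(ids, ids)
  mrm0 <- new("MethylationRelationshipMatrix", values = K0,
    nSites = 1L, variant = "as_stated")
  fit0 <- fitREML(y, X, mrm0)
  expect_lt(max(abs(blup(fit0))), 1e-6)
  ols <- coef(lm(y ~ 0 + X))
  expect_equal(unname(fixedEffects(fit0)), unname(ols),
    tolerance = 1e-6)

  ## K = I, intercept-only: u_i = h * (y_i - GLS mean)
  KI <- diag(n); dimnames(KI) <- list(ids, ids)
  mrmI <- new("MethylationRelationshipMatrix", values = KI,
    nSites = 1L, variant = "as_stated")
  XI <- X[, 1, drop = FALSE]
  fitI <- fitREML(y, XI, mrmI)
  h <- varianceComponents(fitI)[["h"]]
  expect_equal(unname(blup(fitI)),
    unname(h * (y - fixedEffects(fitI)[1])), tolerance = 1e-4)

  ## singular fixed design is reported with the collinear column
  Xbad <- cbind(X, dup = X[, 2])
  expect_error(fitREML(y, Xbad, mrmI), "dup")
})

test_that("masked prediction equals the joint-Gaussian conditioning oracle", {
  set.seed(11)
  n <- 10
  A <- matrix(rnorm(n * 30), n)
  K <- tcrossprod(A) / 30
  ids <- sprintf("s%02d", 1:n)
  dimnames(K) <- list(ids, ids)
  herd <- rep(c("h1", "h2"), each = 5)
  X <- cbind(`(Intercept)` = 1, herdh2 = as.numeric(herd == "h2"))
  rownames(X) <- ids
  y <- setNames(4 + (herd == "h2") +
    drop(chol(K + diag(1e-6, n)) %*% rnorm(n)) + 0.5 * rnorm(n), ids)
  mrm <- new("MethylationRelationshipMatrix", values = K,
    nSites = 30L, variant = "as_stated")

  masked <- c("s03", "s08")
  pm <- predictMasked(y, X, mrm, masked)
  tr <- setdiff(ids, masked)
  vc <- varianceComponents(pm$fit)
  KrT <- ridgedK(K[tr, tr])
  Vt <- vc[["sigma2_animal"]] * KrT +
    vc[["sigma2_error"]] * diag(length(tr))
  betaT <- fixedEffects(pm$fit)
  uO <- vc[["sigma2_animal"]] * K[masked, tr] %*%
    solve(Vt, y[tr] - X[tr, ] %*% betaT)
  predO <- drop(X[masked, ] %*% betaT + uO)
  expect_equal(unname(pm$predicted), unname(predO), tolerance = 1e-8)
})

test_that("masked samples with no covariance or duplicated covariance behave as expected", {
  set.seed(3)
  n <- 9
  ids <- sprintf("s%02d", 1:n)
  A <- matrix(rnorm((n - 1) * 25), n - 1)
  Kt <- tcrossprod(A) / 25
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  K[1:(n - 1), 1:(n - 1)] <- Kt
  K[n, n] <- mean(diag(Kt))  # isolated sample: zero off-diagonal
  X <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  y <- setNames(5 + drop(rbind(chol(Kt + diag(1e-6, n - 1)), 0) %*%
    c(rnorm(n - 1))), ids)
  y[n] <- 5
  mrm <- new("MethylationRelationshipMatrix", values = K,
    nSites = 25L, variant = "as_stated")
  pm <- predictMasked(y, X, mrm, ids[n])
  expect_equal(unname(pm$predicted), unname(fixedEffects(pm$fit)[1]),
    tolerance = 1e-10)

  ## a masked exact duplicate of a training sample gets the same BLUP
  K2 <- rbind(cbind(Kt, Kt[, 1]), c(Kt[1, ], Kt[1, 1]))
  ids2 <- c(sprintf("t%02d", 1:(n - 1)), "dup")
  dimnames(K2) <- list(ids2, ids2)
  X2 <- matrix(1, n, 1, dimnames = list(ids2, "(Intercept)"))
  y2 <- setNames(c(y[1:(n - 1)], 0), ids2)
  mrm2 <- new("MethylationRelationshipMatrix", values = K2,
    nSites = 25L, variant = "as_stated")
  pm2 <- predictMasked(y2, X2, mrm2, "dup")
  expect_equal(unname(pm2$predicted - fixedEffects(pm2$fit)[1]),
    unname(blup(pm2$fit)["t01"]), tolerance = 1e-5)
})

test_that("an unseen training herd falls back to the intercept with a warning", {
  set.seed(15)
  n <- 12
  ids <- sprintf("s%02d", 1:n)
  mrm <- randomMRM(n, seed = 15)
  herd <- c(rep("h1", 6), rep("h2", 5), "h3")
  X <- cbind(`(Intercept)` = 1, herdh2 = as.numeric(herd == "h2"),
    herdh3 = as.numeric(herd == "h3"))
  rownames(X) <- sampleIds(mrm)
  y <- setNames(rnorm(n, 6), sampleIds(mrm))
  expect_warning(pm <- predictMasked(y, X, mrm, sampleIds(mrm)[n]),
    "unseen")
  expect_false("herdh3" %in% names(fixedEffects(pm$fit)))
})

test_that("cross-validation partitions samples into ceiling(n/5) folds keeping animals together", {
  cfg <- simConfig(nAnimals = 48, nSites = 600, nRepeatAnimals = 18,
    clockSlope = 0.5, seed = 19)
  co <- generateCohort(cfg)           # 66 samples
  rec <- simulateMethylation(co, co$truth, cfg)
  wcm <- windowCallMatrix(rec, 100, sampleOrder = co$metadata$sample_id)
  f <- filterVariability(filterCallRate(wcm))
  mrm <- computeMRM(imputeMissing(f))
  cv <- crossValidate(co$metadata, mrm, foldSize = 5, seed = 101)

  expect_equal(length(cv@folds), ceiling(66 / 5))
  allIds <- unlist(cv@folds)
  expect_equal(sort(allIds), sort(co$metadata$sample_id))
  ## samples of one animal never straddle folds
  foldOf <- rep(seq_along(cv@folds), lengths(cv@folds))
  names(foldOf) <- allIds
  split_animals <- tapply(
    foldOf[co$metadata$sample_id], co$metadata$animal_id,
    function(z) length(unique(z)))
  expect_true(all(split_animals == 1))
  ## identical seed reproduces the partition
  cvB <- crossValidate(co$metadata, mrm, foldSize = 5, seed = 101)
  expect_identical(cv@folds, cvB@folds)
  expect_error(crossValidate(co$metadata, mrm, foldSize = 0), "foldSize")
})

test_that("adding a constant to all ages shifts only the intercept", {
  cfg <- simConfig(nAnimals = 40, nSites = 600, nRepeatAnimals = 0,
    clockSlope = 0.5, seed = 23)
  co <- generateCohort(cfg)
  rec <- simulateMethylation(co, co$truth, cfg)
  wcm <- windowCallMatrix(rec, 100, sampleOrder = co$metadata$sample_id)
  mrm <- computeMRM(imputeMissing(filterVariability(filterCallRate(wcm))))

  fitA <- fitClockModel(co$metadata, mrm)
  mdShift <- co$metadata
  mdShift$age_years <- mdShift$age_years + 7
  fitB <- fitClockModel(mdShift, mrm)
  expect_equal(fixedEffects(fitB)[["(Intercept)"]],
    fixedEffects(fitA)[["(Intercept)"]] + 7, tolerance = 1e-5)
  expect_equal(blup(fitB), blup(fitA), tolerance = 1e-5)
  expect_equal(varianceComponents(fitB), varianceComponents(fitA),
    tolerance = 1e-4)

  cvA <- crossValidate(co$metadata, mrm, seed = 31)
  cvB <- crossValidate(mdShift, mrm, seed = 31)
  expect_equal(accuracy(cvB), accuracy(cvA), tolerance = 1e-6)
  expect_equal(madByClass(cvB),
    madByAgeClass(predictedAges(cvB), cvB@actual),
    tolerance = 1e-12)
  expect_equal(mean(abs(predictedAges(cvB) - cvB@actual)),
    mean(abs(predictedAges(cvA) - cvA@actual)), tolerance = 1e-6)
})

test_that("predictions are invariant to the fixed-effect reference level", {
  set.seed(29)
  n <- 14
  mrm <- randomMRM(n, seed = 29)
  ids <- sampleIds(mrm)
  herd <- rep(c("h1", "h2"), each = 7)
  y <- setNames(rnorm(n, 8, 2), ids)
  X1 <- cbind(`(Intercept)` = 1, herdh2 = as.numeric(herd == "h2"))
  X2 <- cbind(`(Intercept)` = 1, herdh1 = as.numeric(herd == "h1"))
  rownames(X1) <- rownames(X2) <- ids
  f1 <- fitREML(y, X1, mrm)
  f2 <- fitREML(y, X2, mrm)
  expect_equal(drop(X1 %*% fixedEffects(f1)) + blup(f1),
    drop(X2 %*% fixedEffects(f2)) + blup(f2), tolerance = 1e-6)
  expect_equal(f1@logRestrictedLik, f2@logRestrictedLik,
    tolerance = 1e-6)
})

test_that("MAD by age class follows half-open class boundaries", {
  actual <- c(1, 2, 2.9, 3, 5, 9.9, 10, 12, 14)
  predicted <- actual + c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  mad <- madByAgeClass(predicted, actual, breaks = c(3, 10))
  expect_equal(mad, c("<3" = 1, "3-10" = 2, ">=10" = 3))

  expect_equal(madByAgeClass(c(2, 5, 12), c(2, 5, 12)),
    c("<3" = 0, "3-10" = 0, ">=10" = 0))
  ## empty classes are absent
  expect_equal(names(madByAgeClass(c(1), c(1))), "<3")
  expect_error(madByAgeClass(1:3, 1:2), "equal length")
})
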