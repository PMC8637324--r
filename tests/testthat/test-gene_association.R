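test_that("gene methylation percent sums read-level calls over overlapping sites", {
  gene <- GRanges("chr1", IRanges(101, 300))
  mcols(gene)$gene_id <- "g1"
  rec <- makeRecords("chr1", c(120L, 250L, 400L), c(10L, 6L, 8L),
    c(5L, 3L, 8L), "s1")
  prof <- geneMethylationPercent(rec, gene)
  expect_equal(prof$profiles$c_m, 8L)     # 5 + 3; site at 400 outside
  expect_equal(prof$profiles$c_total, 16L)
  expect_equal(prof$profiles$percent, 50)
  expect_equal(prof$coverage$n_covered_samples, 1L)

  ## a sample with no overlapping sites is excluded for the gene
  rec2 <- rbind(rec, makeRecords("chr1", 500L, 10L, 2L, "s2"))
  prof2 <- geneMethylationPercent(rec2, gene)
  expect_equal(prof2$profiles$sample_id, "s1")
  expect_equal(prof2$coverage$n_covered_samples, 1L)
})

test_that("multi-gene multi-sample profiles match a brute-force summation oracle", {
  set.seed(61)
  genes <- GRanges("chr1", IRanges(c(1, 301), c(250, 600)))
  mcols(genes)$gene_id <- c("gA", "gB")
  rec <- do.call(rbind, lapply(paste0("s", 1:4), function(s) {
    starts <- sort(sample(0:650, 5))
    called <- sample(0:12, 5, replace = TRUE)
    meth <- vapply(called, function(k) if (k == 0) 0L else
      sample(0:k, 1), integer(1))
    makeRecords("chr1", starts, pmax(called, 1L), meth, s)
  }))
  prof <- geneMethylationPercent(rec, genes)$profiles
  for (g in 1:2) for (s in paste0("s", 1:4)) {
    gs <- GenomicRanges::start(genes)[g]; ge <- GenomicRanges::end(genes)[g]
    sub <- rec[rec$sample_id == s & rec$start + 1 <= ge &
      rec$end + 1 >= gs, ]
    row <- prof[prof$gene_id == mcols(genes)$gene_id[g] &
      prof$sample_id == s, ]
    if (sum(sub$called_sites) == 0) {
      expect_equal(nrow(row), 0)
    } else {
      expect_equal(row$c_m, sum(sub$called_sites_methylated))
      expect_equal(row$c_total, sum(sub$called_sites))
      expect_equal(row$percent, 100 * row$c_m / row$c_total)
    }
  }
})

test_that("coverage filter requires strictly more than the threshold", {
  cov <- data.frame(gene_id = c("g10", "g11", "g30"),
    n_covered_samples = c(10L, 11L, 30L))
  prof <- data.frame(gene_id = rep(cov$gene_id, cov$n_covered_samples),
    sample_id = "x", c_m = 1L, c_total = 2L, percent = 50)
  kept <- filterGeneCoverage(list(profiles = prof, coverage = cov), 10)
  expect_equal(kept$coverage$gene_id, c("g11", "g30"))
})

test_that("single-herd gene model reduces to closed-form simple regression", {
  set.seed(71)
  n <- 25
  pct <- rnorm(n, 50, 8)
  age <- 1 + 0.15 * pct + rnorm(n, sd = 1.2)
  expect_message(res <- fitGeneLMM(age, pct, rep("h1", n)),
    "single herd")
  ## textbook OLS closed forms
  bHat <- cov(age, pct) / var(pct)
  aHat <- mean(age) - bHat * mean(pct)
  resid <- age - aHat - bHat * pct
  s2 <- sum(resid^2) / (n - 2)
  seB <- sqrt(s2 / ((n - 1) * var(pct)))
  tB <- bHat / seB
  expect_equal(res$beta, bHat, tolerance = 1e-10)
  expect_equal(res$se_beta, seB, tolerance = 1e-10)
  expect_equal(res$t_statistic, tB, tolerance = 1e-10)
  expect_equal(res$df, n - 2)
  expect_equal(res$p_value, 2 * pt(-abs(tB), n - 2), tolerance = 1e-10)

  ## perfectly collinear data drive the marginal R2 to 1
  ageC <- 2 + 0.1 * pct
  suppressWarnings(expect_message(
    resC <- fitGeneLMM(ageC, pct, rep("h1", n))))
  expect_equal(resC$marginal_r2, 1, tolerance = 1e-6)

  expect_error(fitGeneLMM(age, rep(5, n), rep("h1", n)), "variance")
  expect_error(fitGeneLMM(age[1:2], pct[1:2], rep("h1", 2)), "3 samples")
})

test_that("mixed-model fit recovers slope with Satterthwaite df and sensible marginal R2", {
  set.seed(73)
  n <- 60
  herd <- sample(rep(paste0("h", 1:5), length.out = n))
  herdEff <- setNames(rnorm(5, sd = 1.5), paste0("h", 1:5))
  pct <- rnorm(n, 50, 10)
  age <- 2 + 0.2 * pct + herdEff[herd] + rnorm(n)
  res <- fitGeneLMM(age, pct, herd)
  expect_equal(res$beta, 0.2, tolerance = 0.05)
  expect_lt(res$p_value, 1e-6)
  expect_true(res$df > 10 && res$df < n)
  expect_true(res$marginal_r2 > 0.3 && res$marginal_r2 < 1)
  ## LRT fallback agrees in order of magnitude
  resL <- fitGeneLMM(age, pct, herd, dfMethod = "lrt")
  expect_lt(resL$p_value, 1e-6)
  expect_equal(resL$beta, res$beta)
})

test_that("significance classification applies alpha, Bonferroni and direction rules", {
  results <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    beta = c(0.4, -0.2, 0.3),
    se_beta = 0.1, t_statistic = 3, df = 20,
    p_value = c(0.01, 1e-5, 1e-4),
    marginal_r2 = 0.2, n_used = 30L)
  dirs <- data.frame(gene_id = c("g1", "g2", "g3", "g9"),
    expected_direction = c("positive", "positive", "positive",
      "negative"))
  expect_warning(cls <- classifySignificance(results, dirs,
    alpha = 0.05, nTests = 321), "untested")
  ## g1: p < 0.05 and concordant, but 0.01 > 0.05/321
  expect_true(cls$significant_nominal[1])
  expect_false(cls$significant_bonferroni[1])
  ## g2: tiny p but wrong direction
  expect_false(cls$significant_nominal[2])
  ## g3: 1e-4 < 0.05/321 = 1.558e-4
  expect_true(cls$significant_bonferroni[3])

  ## a gene missing from the direction table fails concordance
  cls2 <- classifySignificance(results, dirs[2:3, ], alpha = 0.05)
  expect_false(cls2$significant_nominal[1])
})

test_that("binomial enrichment tail is exact and monotone in k", {
  expect_equal(enrichmentTest(0, 100), 1)
  expect_equal(enrichmentTest(1, 1, alpha = 0.05), 0.05)
  ## closed form for n = 2: P(X >= 1) = 1 - (1 - a)^2
  expect_equal(enrichmentTest(1, 2, 0.05), 1 - 0.95^2)
  ## exact summation oracle
  expect_equal(enrichmentTest(7, 40, 0.05),
    sum(dbinom(7:40, 40, 0.05)), tolerance = 1e-12)
  p <- vapply(0:20, enrichmentTest, numeric(1), nTested = 50)
  expect_true(all(diff(p) < 0))
  expect_error(enrichmentTest(3, 10, alpha = 1.5), "alpha")
})

test_that("gene scan on simulated data flags true age genes and skips unfittable ones", {
  cfg <- simConfig(nAnimals = 60, nSites = 1200, nGenes = 20,
    clockSlope = 0.5, nRepeatAnimals = 0, meanDepth = 15, seed = 83)
  co <- generateCohort(cfg)
  rec <- simulateMethylation(co, co$truth, cfg)
  gff <- withr::local_tempfile(fileext = ".gff3")
  lst <- withr::local_tempfile(fileext = ".csv")
  generateAnnotation(co$truth, gff, lst)
  genes <- readGeneAnnotation(gff)
  conserved <- readConservedGeneList(lst)

  prof <- filterGeneCoverage(geneMethylationPercent(rec, genes), 10)
  scan <- geneAssociationScan(prof, co$metadata)
  scan <- classifySignificance(scan, conserved)
  truthTab <- co$truth$genes
  sig <- scan$gene_id[scan$significant_nominal]
  trueAge <- truthTab$gene_id[truthTab$is_age_associated]
  ## all flagged genes are truly age-associated (direction rule blocks
  ## decoys, whose expected_direction is unspecified)
  expect_true(all(sig %in% trueAge))
  expect_gt(length(sig), 0)
})
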