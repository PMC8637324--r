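## Gene-level methylation percentages, per-gene mixed models
## age ~ mu + methylation + (1 | herd), direction-concordance
## significance rules and binomial enrichment.

#' Gene-body methylation percentage per sample
#'
#' For each gene and sample, sums the read-level CpG calls of every motif
#' group overlapping the gene body: `C_m` methylated calls, `C` total
#' calls, and the percentage `100 * C_m / C`. A sample with no
#' overlapping coverage (`C = 0`) is excluded for that gene; the number
#' of covered samples per gene is reported alongside.
#'
#' @param records long data.frame of site records (all samples).
#' @param genes `GRanges` of gene intervals with a `gene_id` column.
#' @param flank bp added on both sides of each gene (default 0: gene
#'   bodies only).
#' @return list with `profiles` (data.frame: `gene_id`, `sample_id`,
#'   `c_m`, `c_total`, `percent`) and `coverage` (data.frame: `gene_id`,
#'   `n_covered_samples`).
#' @export
geneMethylationPercent <- function(records, genes, flank = 0) {
  stopifnot(is(genes, "GRanges"), flank >= 0)
  g <- genes
  if (flank > 0) g <- suppressWarnings(GenomicRanges::resize(g,
    GenomicRanges::width(g) + 2 * flank, fix = "center"))
  hits <- findOverlaps(siteRanges(records), g, ignore.strand = TRUE)
  coverage <- data.frame(gene_id = g$gene_id,
    n_covered_samples = 0L, stringsAsFactors = FALSE)
  if (length(hits) == 0) {
    return(list(profiles = data.frame(gene_id = character(),
      sample_id = character(), c_m = integer(), c_total = integer(),
      percent = numeric(), stringsAsFactors = FALSE),
      coverage = coverage))
  }
  dt <- data.table(
    gene_id = g$gene_id[subjectHits(hits)],
    sample_id = records$sample_id[queryHits(hits)],
    c_m = records$called_sites_methylated[queryHits(hits)],
    c_total = records$called_sites[queryHits(hits)])
  prof <- dt[, list(c_m = sum(c_m), c_total = sum(c_total)),
    by = c("gene_id", "sample_id")]
  prof <- prof[prof$c_total > 0, ]
  prof[, "percent" := 100 * c_m / c_total]
  cov <- prof[, list(n_covered_samples = .N), by = "gene_id"]
  i <- match(coverage$gene_id, cov$gene_id)
  coverage$n_covered_samples[!is.na(i)] <-
    cov$n_covered_samples[i[!is.na(i)]]
  list(profiles = setDF(prof[order(prof$gene_id, prof$sample_id), ]),
    coverage = coverage)
}

#' Drop genes with insufficient sample coverage
#'
#' Keeps genes with sequence coverage in strictly more than `minSamples`
#' samples (the default 10 keeps genes covered in 11 or more).
#'
#' @param geneProfiles result of [geneMethylationPercent()].
#' @param minSamples coverage must exceed this count.
#' @return the filtered result, same structure.
#' @export
filterGeneCoverage <- function(geneProfiles, minSamples = 10) {
  keep <- geneProfiles$coverage$gene_id[
    geneProfiles$coverage$n_covered_samples > minSamples]
  list(
    profiles = geneProfiles$profiles[
      geneProfiles$profiles$gene_id %in% keep, , drop = FALSE],
    coverage = geneProfiles$coverage[
      geneProfiles$coverage$gene_id %in% keep, , drop = FALSE])
}

#' Per-gene methylation-age mixed model
#'
#' Fits `age ~ percent + (1 | herd)` by REML with a herd random
#' intercept; the methylation slope is tested with a t-statistic on
#' Satterthwaite degrees of freedom (the default) or by a likelihood
#' ratio test against the slope-free model. The marginal pseudo-R2 is
#' the Nakagawa–Schielzeth ratio
#' `var(fixed fitted) / (var(fixed fitted) + sigma2_herd + sigma2_resid)`.
#' With a single herd the model degenerates to ordinary least squares
#' with classical degrees of freedom (reported via `message()`).
#'
#' @param age numeric vector (years).
#' @param percent gene methylation percentage per sample (NA excluded).
#' @param herd herd labels per sample.
#' @param dfMethod `"satterthwaite"` or `"lrt"`.
#' @return one-row data.frame: `beta` (years per percentage point),
#'   `se_beta`, `t_statistic`, `df`, `p_value`, `marginal_r2`, `n_used`.
#' @export
fitGeneLMM <- function(age, percent, herd,
    dfMethod = c("satterthwaite", "lrt")) {
  dfMethod <- match.arg(dfMethod)
  ok <- !is.na(percent) & !is.na(age)
  age <- age[ok]; percent <- percent[ok]
  herd <- factor(as.character(herd[ok]))
  n <- length(age)
  if (n < 3) stop("need at least 3 samples with defined percent")
  if (var(percent) == 0)
    stop("zero variance in methylation percent: slope undefined")

  if (nlevels(herd) < 2) {
    message("single herd: fitting ordinary regression with classical df")
    fit <- lm(age ~ percent)
    sm <- summary(fit)
    beta <- sm$coefficients["percent", ]
    varF <- var(fitted(fit))
    r2 <- varF / (varF + sm$sigma^2)
    p <- if (dfMethod == "lrt") {
      ll1 <- logLik(fit); ll0 <- logLik(lm(age ~ 1))
      pchisq(2 * (as.numeric(ll1) - as.numeric(ll0)), df = 1,
        lower.tail = FALSE)
    } else beta["Pr(>|t|)"]
    return(data.frame(beta = beta["Estimate"],
      se_beta = beta["Std. Error"], t_statistic = beta["t value"],
      df = fit$df.residual, p_value = unname(p), marginal_r2 = r2,
      n_used = n, row.names = NULL))
  }

  dat <- data.frame(age = age, percent = percent, herd = herd)
  fit <- lmerTest::lmer(age ~ percent + (1 | herd), data = dat,
    REML = TRUE, control = lmerControl(check.conv.singular = "ignore"))
  co <- coef(summary(fit, ddf = "Satterthwaite"))["percent", ]
  vc <- as.data.frame(VarCorr(fit))
  s2herd <- vc$vcov[vc$grp == "herd"]
  s2res <- vc$vcov[vc$grp == "Residual"]
  varF <- var(drop(model.matrix(fit) %*% fixef(fit)))
  r2 <- varF / (varF + s2herd + s2res)
  p <- if (dfMethod == "lrt") {
    full <- lmer(age ~ percent + (1 | herd), data = dat, REML = FALSE,
      control = lmerControl(check.conv.singular = "ignore"))
    null <- lmer(age ~ 1 + (1 | herd), data = dat, REML = FALSE,
      control = lmerControl(check.conv.singular = "ignore"))
    pchisq(2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))),
      df = 1, lower.tail = FALSE)
  } else unname(co["Pr(>|t|)"])
  data.frame(beta = unname(co["Estimate"]),
    se_beta = unname(co["Std. Error"]),
    t_statistic = unname(co["t value"]), df = unname(co["df"]),
    p_value = p, marginal_r2 = r2, n_used = n, row.names = NULL)
}

#' Scan all genes for methylation-age association
#'
#' Runs [fitGeneLMM()] for every gene in a (coverage-filtered) profile
#' set, matching samples to metadata by `sample_id`. Genes whose model
#' cannot be fitted (e.g. constant methylation) are skipped with a
#' message.
#'
#' @param geneProfiles result of [geneMethylationPercent()] /
#'   [filterGeneCoverage()].
#' @param metadata data.frame with `sample_id`, `age_years`, `herd`.
#' @param dfMethod see [fitGeneLMM()].
#' @return data.frame, one row per tested gene, with the [fitGeneLMM()]
#'   columns plus `gene_id`.
#' @export
geneAssociationScan <- function(geneProfiles, metadata,
    dfMethod = c("satterthwaite", "lrt")) {
  dfMethod <- match.arg(dfMethod)
  prof <- geneProfiles$profiles
  out <- lapply(unique(prof$gene_id), function(gid) {
    sub <- prof[prof$gene_id == gid, , drop = FALSE]
    i <- match(sub$sample_id, metadata$sample_id)
    if (anyNA(i)) stop("profiles contain sample(s) absent from metadata")
    res <- tryCatch(
      fitGeneLMM(metadata$age_years[i], sub$percent, metadata$herd[i],
        dfMethod),
      error = function(e) {
        message("skipping ", gid, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) return(NULL)
    cbind(data.frame(gene_id = gid, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Apply significance and direction-concordance rules
#'
#' A gene is nominally significant when its p-value is below `alpha`
#' \emph{and} its slope sign matches the expected direction from the
#' conserved-gene list; Bonferroni significance additionally requires
#' `p < alpha / nTests`. Genes absent from the expected-direction table
#' (or listed as `unspecified`) fail concordance; directions listed for
#' genes that were never tested trigger a warning.
#'
#' @param results data.frame from [geneAssociationScan()].
#' @param expectedDirections data.frame with `gene_id`,
#'   `expected_direction` in \{positive, negative, unspecified\}.
#' @param alpha nominal significance level.
#' @param nTests number of tests for the Bonferroni correction
#'   (default: rows of `results`).
#' @return `results` with added columns `expected_direction`,
#'   `direction_concordant`, `significant_nominal`,
#'   `significant_bonferroni`.
#' @export
classifySignificance <- function(results, expectedDirections,
    alpha = 0.05, nTests = nrow(results)) {
  stopifnot(nTests >= 1, alpha > 0, alpha < 1)
  unknown <- setdiff(expectedDirections$gene_id, results$gene_id)
  if (length(unknown))
    warning("expected directions given for untested gene(s): ",
      paste(head(unknown, 3), collapse = ", "))
  i <- match(results$gene_id, expectedDirections$gene_id)
  dir <- expectedDirections$expected_direction[i]
  dir[is.na(dir)] <- "unspecified"
  results$expected_direction <- dir
  results$direction_concordant <-
    (dir == "positive" & results$beta > 0) |
    (dir == "negative" & results$beta < 0)
  results$significant_nominal <- results$direction_concordant &
    results$p_value < alpha
  results$significant_bonferroni <- results$significant_nominal &
    results$p_value < alpha / nTests
  results
}

#' Binomial enrichment of significant genes
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, alpha)`: the
#' chance of observing at least `k` significant genes among `n` tested
#' if each were a false positive at rate `alpha`. (Because significance
#' additionally requires direction concordance, the true null rate is
#' below `alpha`, making this tail probability conservative in the
#' anti-enrichment direction.)
#'
#' @param kSignificant observed number of significant genes.
#' @param nTested number of genes tested.
#' @param alpha per-gene false-positive rate under the null.
#' @return the exact upper-tail probability.
#' @examples
#' enrichmentTest(43, 321)  # about 5.7e-9
#' @export
enrichmentTest <- function(kSignificant, nTested, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(kSignificant >= 0, kSignificant <= nTested)
  if (kSignificant == 0) return(1)
  pbinom(kSignificant - 1, nTested, alpha, lower.tail = FALSE)
}
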