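## Synthetic cohort generator: per-site methylation frequency files with
## age-dependent "clock" sites, herd-by-site confounding, coverage-driven
## missingness and binomial sampling noise, plus matching GFF3 and
## conserved-gene lists. Ground truth is returned for recovery tests.

#' Simulation configuration
#'
#' Defaults emulate the study cohort the package targets: 66 animals in 5
#' herds with ages spanning 0.35 to 15.7 years and 18 animals sampled
#' twice. Methylation is generated on the logit scale so frequencies stay
#' in (0, 1) at all ages.
#'
#' Clock sites are modelled as switching CpGs: each clock site j has a
#' transition age a_j drawn uniformly over `ageRange` and methylation
#' probability `plogis(slope_j * (age - a_j))`, so its baseline (age-0)
#' level is `plogis(-slope_j * a_j)` and the site crosses 50% methylation
#' at a_j. Spreading a_j over the whole age range gives the cohort sites
#' informative at all ages, mirroring the distributed transition ages of
#' clock CpGs. Non-clock sites have a static baseline drawn from
#' `Beta(baselineAlpha, baselineBeta)` (bimodal by default, as in real
#' methylomes). Herd effects are drawn per herd-by-site so that herd acts
#' as a methylation-pattern confounder, and sign of the clock slope is
#' positive with probability `positiveSignProb` (most conserved clock
#' genes gain methylation with age; a few lose it).
#'
#' @param nAnimals number of animals.
#' @param nHerds number of herds (assigned round-robin then shuffled).
#' @param ageRange numeric length-2, min/max age in years.
#' @param nSites number of CpG motif groups.
#' @param windowSize window width in bp (used downstream).
#' @param fracClockSites fraction of sites carrying age signal.
#' @param clockSlope change in logit-methylation per year at clock sites.
#' @param herdEffectSD SD of per-herd-by-site logit effects.
#' @param baselineAlpha,baselineBeta Beta parameters of non-clock
#'   baseline methylation.
#' @param meanDepth expected reads per site (Poisson).
#' @param missingRate probability a site-by-sample pair has zero coverage.
#' @param nRepeatAnimals animals sampled a second time at age +
#'   Uniform(0.5, 2) years.
#' @param nGenes number of annotated genes (contiguous site blocks).
#' @param fracAgeGenes fraction of genes that are age-associated (these
#'   contain all clock sites).
#' @param positiveSignProb probability an age gene gains methylation.
#' @param seed integer seed; identical configs give identical output.
#' @return a validated list of class `"epiclock_sim_config"`.
#' @export
simConfig <- function(nAnimals = 66, nHerds = 5, ageRange = c(0.35, 15.7),
    nSites = 2000, windowSize = 100, fracClockSites = 0.1,
    clockSlope = 0.3, herdEffectSD = 0.5, baselineAlpha = 0.4,
    baselineBeta = 0.4, meanDepth = 15, missingRate = 0.1,
    nRepeatAnimals = 18, nGenes = 40, fracAgeGenes = 0.25,
    positiveSignProb = 0.9, seed = 1L) {
  cfg <- list(nAnimals = as.integer(nAnimals), nHerds = as.integer(nHerds),
    ageRange = as.numeric(ageRange), nSites = as.integer(nSites),
    windowSize = as.integer(windowSize),
    fracClockSites = fracClockSites, clockSlope = clockSlope,
    herdEffectSD = herdEffectSD, baselineAlpha = baselineAlpha,
    baselineBeta = baselineBeta, meanDepth = meanDepth,
    missingRate = missingRate, nRepeatAnimals = as.integer(nRepeatAnimals),
    nGenes = as.integer(nGenes), fracAgeGenes = fracAgeGenes,
    positiveSignProb = positiveSignProb, seed = as.integer(seed))
  with(cfg, {
    stopifnot(nAnimals >= 1, nHerds >= 1, nSites >= 1, windowSize >= 1,
      nGenes >= 1, nRepeatAnimals >= 0, meanDepth > 0)
    if (nHerds > nAnimals) stop("nHerds must not exceed nAnimals")
    if (nRepeatAnimals > nAnimals)
      stop("nRepeatAnimals must not exceed nAnimals")
    stopifnot(length(ageRange) == 2, ageRange[1] < ageRange[2],
      ageRange[1] > 0)
    for (f in c(fracClockSites, missingRate, fracAgeGenes,
        positiveSignProb))
      if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  })
  nClock <- round(cfg$fracClockSites * cfg$nSites)
  nAge <- max(1L, round(cfg$fracAgeGenes * cfg$nGenes))
  capacity <- nAge * max(1L, floor(0.6 * (cfg$nSites %/% cfg$nGenes)))
  if (nClock > capacity)
    stop("age-associated genes cannot hold ", nClock, " clock sites ",
      "(capacity ", capacity, "); increase nGenes/fracAgeGenes")
  class(cfg) <- "epiclock_sim_config"
  cfg
}

#' Generate a cohort and its simulation ground truth
#'
#' Draws sample metadata (ages uniform on the configured range, herds
#' round-robin then shuffled) and the full generative truth: site layout
#' on one chromosome, gene blocks, clock-site flags/slopes/baselines and
#' herd-by-site effects. Repeat animals receive a second sample at their
#' age plus Uniform(0.5, 2) years under the same animal id and herd.
#'
#' @param config a [simConfig()].
#' @return list with elements `metadata` (data.frame as read by
#'   [readSampleMetadata()]) and `truth` (list: `sites`, `genes`,
#'   `herdEffects`, `sampleAges`).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "epiclock_sim_config"))
  set.seed(config$seed)
  nA <- config$nAnimals
  animalIds <- sprintf("A%04d", seq_len(nA))
  ages <- runif(nA, config$ageRange[1], config$ageRange[2])
  herds <- sample(rep_len(sprintf("herd_%02d", seq_len(config$nHerds)), nA))
  breeds <- setNames(
    rep_len(c("Droughtmaster", "Brahman", "TropicalComposite"),
      config$nHerds), sprintf("herd_%02d", seq_len(config$nHerds)))
  metadata <- data.frame(
    sample_id = sprintf("S%04d", seq_len(nA)),
    animal_id = animalIds, herd = herds,
    breed = unname(breeds[herds]), age_years = ages,
    stringsAsFactors = FALSE)
  if (config$nRepeatAnimals > 0) {
    rep_idx <- sort(sample.int(nA, config$nRepeatAnimals))
    rep_rows <- metadata[rep_idx, , drop = FALSE]
    rep_rows$sample_id <- sprintf("S%04d_r", rep_idx)
    rep_rows$age_years <- rep_rows$age_years +
      runif(config$nRepeatAnimals, 0.5, 2)
    metadata <- rbind(metadata, rep_rows)
    rownames(metadata) <- NULL
  }

  ## site layout: one chromosome, irregular gaps so some windows hold
  ## several motif groups and others none
  m <- config$nSites
  numMotifs <- 1L + rpois(m, 0.3)
  gaps <- 20L + as.integer(round(rexp(m, rate = 1 / 120)))
  starts <- cumsum(gaps)
  ends <- starts + 2L * (numMotifs - 1L)

  ## gene blocks: the site run is split into one block per gene, and the
  ## gene body covers the central 60% of its block's sites — the
  ## flanking sites are intergenic, so the gene-restricted analysis is a
  ## genuine subset of the genome-wide one
  sitesPerGene <- m %/% config$nGenes
  block <- pmin(((seq_len(m) - 1L) %/% sitesPerGene) + 1L,
    config$nGenes)
  posInBlock <- seq_len(m) - (block - 1L) * sitesPerGene
  coverLo <- max(1L, ceiling(0.2 * sitesPerGene))
  coverHi <- max(coverLo, floor(0.8 * sitesPerGene))
  inGene <- posInBlock >= coverLo & posInBlock <= coverHi
  geneOfSite <- ifelse(inGene, block, 0L)
  nAge <- max(1L, round(config$fracAgeGenes * config$nGenes))
  ageGenes <- sort(sample.int(config$nGenes, nAge))
  geneSign <- ifelse(runif(nAge) < config$positiveSignProb, 1, -1)
  names(geneSign) <- as.character(ageGenes)

  nClock <- round(config$fracClockSites * m)
  eligible <- which(geneOfSite %in% ageGenes)
  clockIdx <- sort(sample(eligible, nClock))
  isClock <- seq_len(m) %in% clockIdx

  slope <- numeric(m)
  slope[isClock] <- config$clockSlope *
    geneSign[as.character(geneOfSite[isClock])]
  transitionAge <- rep(NA_real_, m)
  transitionAge[isClock] <- runif(nClock, config$ageRange[1],
    config$ageRange[2])
  baseline <- rbeta(m, config$baselineAlpha, config$baselineBeta)
  ## keep static baselines off the exact binarization boundary
  baseline <- pmin(pmax(baseline, 1e-4), 1 - 1e-4)
  baseline[isClock] <- plogis(-slope[isClock] * transitionAge[isClock])

  sites <- data.frame(
    chrom = "chr1", start = starts, end = ends, num_motifs = numMotifs,
    gene = geneOfSite, is_clock = isClock, slope = slope,
    baseline = baseline, transition_age = transitionAge,
    stringsAsFactors = FALSE)

  geneStart <- vapply(seq_len(config$nGenes), function(g)
    min(starts[geneOfSite == g]), numeric(1))
  geneEnd <- vapply(seq_len(config$nGenes), function(g)
    max(ends[geneOfSite == g]), numeric(1))
  genes <- data.frame(
    gene_id = sprintf("GENE%03d", seq_len(config$nGenes)),
    chrom = "chr1",
    start = as.integer(geneStart), end = as.integer(geneEnd),
    is_age_associated = seq_len(config$nGenes) %in% ageGenes,
    true_direction = "unspecified", stringsAsFactors = FALSE)
  genes$true_direction[ageGenes] <-
    ifelse(geneSign > 0, "positive", "negative")

  herdEffects <- matrix(
    rnorm(config$nHerds * m, sd = config$herdEffectSD),
    nrow = config$nHerds, ncol = m,
    dimnames = list(sprintf("herd_%02d", seq_len(config$nHerds)), NULL))

  truth <- list(sites = sites, genes = genes, herdEffects = herdEffects,
    sampleAges = setNames(metadata$age_years, metadata$sample_id),
    config = config)
  list(metadata = metadata, truth = truth)
}

#' Simulate per-site methylation frequency records
#'
#' For sample i and site j the methylation probability is
#' `plogis(qlogis(baseline_j) + slope_j * age_i + herdEffect[h(i), j])`;
#' read depth is Poisson(`meanDepth`) zeroed with probability
#' `missingRate`, methylated calls are Binomial(depth, p) and the
#' frequency is their ratio. Sites with zero depth are absent from a
#' sample's records, exactly as in real frequency files.
#'
#' @param cohort,truth from [generateCohort()].
#' @param config the same [simConfig()].
#' @return a long data.frame of methylation site records for all samples
#'   (columns as in [readMethylationFrequency()]).
#' @export
simulateMethylation <- function(cohort, truth, config) {
  stopifnot(inherits(config, "epiclock_sim_config"))
  set.seed(config$seed + 1L)
  md <- cohort$metadata
  st <- truth$sites
  n <- nrow(md); m <- nrow(st)

  logitBase <- qlogis(st$baseline)
  eta <- outer(md$age_years, st$slope) +
    matrix(logitBase, n, m, byrow = TRUE) +
    truth$herdEffects[md$herd, , drop = FALSE]
  p <- plogis(eta)

  depth <- matrix(rpois(n * m, config$meanDepth), n, m)
  if (config$missingRate > 0)
    depth[matrix(runif(n * m) < config$missingRate, n, m)] <- 0L
  meth <- matrix(rbinom(n * m, as.vector(depth), as.vector(p)), n, m)

  keep <- which(depth > 0, arr.ind = TRUE)
  rec <- data.frame(
    chrom = st$chrom[keep[, 2]],
    start = st$start[keep[, 2]],
    end = st$end[keep[, 2]],
    num_motifs = st$num_motifs[keep[, 2]],
    called_sites = depth[keep],
    called_sites_methylated = meth[keep],
    methylated_frequency = meth[keep] / depth[keep],
    sample_id = md$sample_id[keep[, 1]],
    stringsAsFactors = FALSE)
  rec <- rec[order(match(rec$sample_id, md$sample_id), rec$start), ,
    drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Write annotation files for a simulated cohort
#'
#' Writes the gene blocks as a GFF3 (readable by [readGeneAnnotation()])
#' and the conserved-gene list CSV: every gene appears in the list;
#' age-associated genes carry their true slope sign as
#' `expected_direction`, decoys are `unspecified`.
#'
#' @param truth from [generateCohort()].
#' @param gff3Path,listPath output paths.
#' @return invisibly, a list with the two paths.
#' @export
generateAnnotation <- function(truth, gff3Path, listPath) {
  g <- truth$genes
  gr <- GRanges(g$chrom, IRanges(start = g$start + 1L, end = g$end + 1L),
    strand = "+")
  mcols(gr)$source <- "epiclock_sim"
  mcols(gr)$type <- "gene"
  mcols(gr)$ID <- g$gene_id
  rtracklayer::export(gr, gff3Path, format = "gff3")
  write.csv(data.frame(gene_id = g$gene_id,
    expected_direction = g$true_direction, stringsAsFactors = FALSE),
    listPath, row.names = FALSE, quote = FALSE)
  invisible(list(gff3 = gff3Path, geneList = listPath))
}

#' Simulate a full study directory
#'
#' Runs [generateCohort()], [simulateMethylation()] and
#' [generateAnnotation()] and writes everything in the exact formats the
#' IO module reads: `metadata.csv`, one `methylation/<sample>.tsv` per
#' sample, `genes.gff3` and `conserved_genes.csv`.
#'
#' @param config a [simConfig()].
#' @param dir output directory (created if absent).
#' @return invisibly, a list with `metadata`, `truth`, `records` and the
#'   file paths.
#' @export
simulateStudy <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  methDir <- file.path(dir, "methylation")
  if (!dir.exists(methDir)) dir.create(methDir)
  cohort <- generateCohort(config)
  records <- simulateMethylation(cohort, cohort$truth, config)

  metaPath <- file.path(dir, "metadata.csv")
  write.csv(cohort$metadata, metaPath, row.names = FALSE, quote = FALSE)
  paths <- character(0)
  for (sid in cohort$metadata$sample_id) {
    p <- file.path(methDir, paste0(sid, ".tsv"))
    writeMethylationFrequency(
      records[records$sample_id == sid, , drop = FALSE], p)
    paths <- c(paths, p)
  }
  ann <- generateAnnotation(cohort$truth, file.path(dir, "genes.gff3"),
    file.path(dir, "conserved_genes.csv"))
  invisible(list(metadata = cohort$metadata, truth = cohort$truth,
    records = records, paths = list(metadata = metaPath,
      methylation = paths, gff3 = ann$gff3, geneList = ann$geneList)))
}
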