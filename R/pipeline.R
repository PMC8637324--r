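## End-to-end orchestration: simulate -> windows -> filter -> mrm ->
## clock -> genes, with a YAML config, derived stage seeds and a JSON
## manifest of parameters and output checksums.

#' Default pipeline configuration
#'
#' Every analysis default is stated explicitly so that a run directory is
#' self-documenting: window size 100 bp, call-rate threshold 0.8,
#' SD threshold 0.5, fold size 5, alpha 0.05, gene coverage > 10
#' samples. The `simulate` block mirrors [simConfig()].
#'
#' @param seed top-level seed; all stage seeds are derived from it.
#' @return a nested list; write it with `yaml::write_yaml()` to obtain a
#'   config file for [runPipeline()].
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    version = 1L,
    seed = as.integer(seed),
    simulate = list(nAnimals = 66L, nHerds = 5L,
      ageRange = c(0.35, 15.7), nSites = 2000L, windowSize = 100L,
      fracClockSites = 0.1, clockSlope = 0.3, herdEffectSD = 0.5,
      baselineAlpha = 0.4, baselineBeta = 0.4, meanDepth = 15,
      missingRate = 0.1, nRepeatAnimals = 18L, nGenes = 40L,
      fracAgeGenes = 0.25, positiveSignProb = 0.9),
    windows = list(windowSize = 100L),
    filter = list(minCallRate = 0.8, minSD = 0.5,
      sdDenominator = "sample"),
    mrm = list(variant = "as_stated"),
    clock = list(foldSize = 5L, useHerd = TRUE, useSeason = FALSE,
      ridge = 1e-6, breaks = c(3, 10)),
    genes = list(alpha = 0.05, minSamples = 10L, flank = 0L,
      dfMethod = "satterthwaite"))
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.validatePipelineConfig <- function(config) {
  required <- c("seed", "simulate", "windows", "filter", "mrm", "clock",
    "genes")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("pipeline config is missing section(s): ",
      paste(missing, collapse = ", "))
  config
}

#' Run the full clock pipeline
#'
#' Executes the six stages in dependency order in `outDir`:
#' \enumerate{
#'   \item \strong{simulate} — write a synthetic study
#'     ([simulateStudy()]);
#'   \item \strong{windows} — read every per-sample TSV back through the
#'     IO module and build the binarized call matrix;
#'   \item \strong{filter} — call-rate then variability filter;
#'   \item \strong{mrm} — genome-wide MRM-1 and the gene-subset MRM-2;
#'   \item \strong{clock} — cross-validated MeBLUP on both matrices;
#'   \item \strong{genes} — gene methylation percentages, per-gene LMM
#'     scan, significance classification and enrichment.
#' }
#' Stage seeds are derived deterministically from the top-level seed, and
#' a `manifest.json` records every stage's parameters, outputs and MD5
#' checksums; re-running an identical config reproduces identical
#' checksums.
#'
#' @param config path to a YAML config, or a config list; values merge
#'   over [defaultPipelineConfig()].
#' @param outDir run directory (created if absent).
#' @return invisibly, a list with the stage results (`callMatrix`,
#'   `filtered`, `mrm1`, `mrm2`, `cv1`, `cv2`, `geneResults`,
#'   `enrichment`, `manifest`).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validatePipelineConfig(
    .mergeConfig(defaultPipelineConfig(), config))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(version = config$version, seed = seed,
    stages = list())
  record <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(parameters = params,
      outputs = as.list(tools::md5sum(files)))
  }

  ## 1. simulate (stage seed = seed; the generator consumes it directly)
  simCfg <- do.call(simConfig, c(config$simulate, list(seed = seed)))
  simDir <- file.path(outDir, "input")
  study <- simulateStudy(simCfg, simDir)
  record("simulate", config$simulate,
    c(study$paths$metadata, study$paths$gff3, study$paths$geneList))

  ## 2. windows: consume the written files through the readers
  metadata <- readSampleMetadata(study$paths$metadata)
  records <- do.call(rbind, lapply(metadata$sample_id, function(sid)
    readMethylationFrequency(
      file.path(simDir, "methylation", paste0(sid, ".tsv")), sid)))
  wcm <- windowCallMatrix(records, config$windows$windowSize,
    sampleOrder = metadata$sample_id)
  callsPath <- file.path(outDir, "call_matrix.tsv")
  writeMatrixTSV(callMatrix(wcm), callsPath)
  record("windows", config$windows, callsPath)

  ## 3. filter
  f1 <- filterCallRate(wcm, config$filter$minCallRate)
  f2 <- filterVariability(f1, config$filter$minSD,
    sdDenominator = config$filter$sdDenominator)
  rep1 <- rbind(filterReport(wcm, f1, "call_rate"),
    filterReport(f1, f2, "variability"))
  filtPath <- file.path(outDir, "filtered_matrix.tsv")
  repPath <- file.path(outDir, "filter_report.tsv")
  writeMatrixTSV(callMatrix(f2), filtPath)
  fwrite(rep1, repPath, sep = "\t")
  record("filter", config$filter, c(filtPath, repPath))

  ## 4. mrm: MRM-1 genome-wide, MRM-2 on conserved-gene windows
  genes <- readGeneAnnotation(study$paths$gff3)
  conserved <- readConservedGeneList(study$paths$geneList)
  genes <- annotateDirections(genes, conserved)
  fGene <- subsetToGenes(f2, genes)
  mrm1 <- computeMRM(imputeMissing(f2), config$mrm$variant)
  mrm2 <- computeMRM(imputeMissing(fGene), config$mrm$variant)
  mrm1Path <- file.path(outDir, "mrm1.tsv")
  mrm2Path <- file.path(outDir, "mrm2.tsv")
  writeMRM(mrm1, mrm1Path)
  writeMRM(mrm2, mrm2Path)
  record("mrm", config$mrm, c(mrm1Path, mrm2Path))

  ## 5. clock: cross-validation on both matrices (stage seed derived)
  clockSeed <- (seed + 1000L) %% .Machine$integer.max
  cv1 <- crossValidate(metadata, mrm1, config$clock$foldSize,
    seed = clockSeed, useHerd = config$clock$useHerd,
    useSeason = config$clock$useSeason, ridge = config$clock$ridge,
    breaks = config$clock$breaks)
  cv2 <- crossValidate(metadata, mrm2, config$clock$foldSize,
    seed = clockSeed, useHerd = config$clock$useHerd,
    useSeason = config$clock$useSeason, ridge = config$clock$ridge,
    breaks = config$clock$breaks)
  predPath <- file.path(outDir, "clock_predictions.tsv")
  fwrite(data.frame(sample_id = names(predictedAges(cv1)),
    actual_age = cv1@actual, predicted_mrm1 = predictedAges(cv1),
    predicted_mrm2 = predictedAges(cv2)[names(predictedAges(cv1))]),
    predPath, sep = "\t")
  fitPath <- file.path(outDir, "clock_report.json")
  jsonlite::write_json(list(
    mrm1 = list(accuracy = accuracy(cv1), accuracy_se = accuracySE(cv1),
      mad_by_class = as.list(madByClass(cv1)), n_sites = nSites(mrm1)),
    mrm2 = list(accuracy = accuracy(cv2), accuracy_se = accuracySE(cv2),
      mad_by_class = as.list(madByClass(cv2)), n_sites = nSites(mrm2))),
    fitPath, auto_unbox = TRUE, digits = NA)
  record("clock", config$clock, c(predPath, fitPath))

  ## 6. genes
  prof <- geneMethylationPercent(records, genes, config$genes$flank)
  prof <- filterGeneCoverage(prof, config$genes$minSamples)
  scan <- geneAssociationScan(prof, metadata, config$genes$dfMethod)
  scan <- classifySignificance(scan, conserved, config$genes$alpha)
  enr <- enrichmentTest(sum(scan$significant_nominal), nrow(scan),
    config$genes$alpha)
  genePath <- file.path(outDir, "gene_association.tsv")
  enrPath <- file.path(outDir, "enrichment.json")
  fwrite(scan, genePath, sep = "\t")
  jsonlite::write_json(list(n_tested = nrow(scan),
    n_significant_nominal = sum(scan$significant_nominal),
    n_significant_bonferroni = sum(scan$significant_bonferroni),
    enrichment_p = enr), enrPath, auto_unbox = TRUE, digits = NA)
  record("genes", config$genes, c(genePath, enrPath))

  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
    digits = NA)
  invisible(list(metadata = metadata, callMatrix = wcm, filtered = f2,
    mrm1 = mrm1, mrm2 = mrm2, cv1 = cv1, cv2 = cv2, geneResults = scan,
    enrichment = enr, manifest = manifest,
    manifestPath = manifestPath, truth = study$truth))
}
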