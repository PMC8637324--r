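## Readers/writers for the methylation-frequency TSV dialect, sample
## metadata, GFF3 gene annotation and conserved-gene lists.

.freqRequiredCols <- c("chromosome", "start", "end", "called_sites",
  "called_sites_methylated", "methylated_frequency")

#' Read a per-sample methylation frequency table
#'
#' Parses the tab-separated "methylation frequency" dialect emitted by
#' nanopolish/f5c: one row per CpG motif group with read-level call counts.
#' Coordinates in the file are 0-based with inclusive ends and are kept
#' as-is in the returned records (`start`/`end` columns); window arithmetic
#' downstream uses the 0-based start directly.
#'
#' Rows with `called_sites = 0` carry no methylation evidence and are
#' dropped; the number dropped is reported via `message()`.
#'
#' @param path path to the TSV file (header required).
#' @param sampleId sample identifier attached to every record.
#' @return a `data.frame` with columns `chrom`, `start`, `end`,
#'   `num_motifs`, `called_sites`, `called_sites_methylated`,
#'   `methylated_frequency`, `sample_id`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   paste("chromosome", "start", "end", "num_motifs_in_group",
#'     "called_sites", "called_sites_methylated", "methylated_frequency",
#'     "group_sequence", sep = "\t"),
#'   paste("chr1", 100, 101, 1, 10, 7, 0.7, "ACGTT", sep = "\t")), tsv)
#' readMethylationFrequency(tsv, "s1")
#' @export
readMethylationFrequency <- function(path, sampleId) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
    data.table = TRUE, showProgress = FALSE)
  missingCols <- setdiff(.freqRequiredCols, names(dt))
  if (length(missingCols))
    stop("methylation frequency file ", path,
      " is missing required column(s): ", paste(missingCols, collapse = ", "))

  numify <- function(col, integer = TRUE) {
    x <- suppressWarnings(if (integer) as.integer(dt[[col]])
      else as.numeric(dt[[col]]))
    bad <- which(is.na(x) & !is.na(dt[[col]]) & dt[[col]] != "NA")
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data line ", bad[1],
        " of ", path)
    x
  }
  rec <- data.frame(
    chrom = dt[["chromosome"]],
    start = numify("start"),
    end = numify("end"),
    num_motifs = if ("num_motifs_in_group" %in% names(dt))
      numify("num_motifs_in_group") else 1L,
    called_sites = numify("called_sites"),
    called_sites_methylated = numify("called_sites_methylated"),
    methylated_frequency = numify("methylated_frequency", integer = FALSE),
    sample_id = sampleId,
    stringsAsFactors = FALSE)

  bad <- which(rec$called_sites_methylated > rec$called_sites)
  if (length(bad))
    stop("called_sites_methylated > called_sites at data line ", bad[1],
      " of ", path)
  bad <- which(rec$start > rec$end)
  if (length(bad))
    stop("start > end at data line ", bad[1], " of ", path)

  nZero <- sum(rec$called_sites == 0L)
  if (nZero > 0) {
    message("dropping ", nZero, " record(s) with called_sites = 0 from ",
      basename(path))
    rec <- rec[rec$called_sites > 0L, , drop = FALSE]
  }
  chk <- abs(rec$methylated_frequency -
    rec$called_sites_methylated / rec$called_sites)
  bad <- which(chk > 1e-6)
  if (length(bad))
    stop("methylated_frequency inconsistent with call counts at data line ",
      bad[1], " of ", path)
  rownames(rec) <- NULL
  rec
}

#' Write methylation site records in the frequency TSV dialect
#'
#' Inverse of [readMethylationFrequency()] for a single sample; round-trips
#' all fields exactly.
#'
#' @param records data.frame of site records (one sample).
#' @param path output path.
#' @param groupSequence optional character vector for the
#'   `group_sequence` column (defaults to a placeholder).
#' @export
writeMethylationFrequency <- function(records, path, groupSequence = NULL) {
  out <- data.frame(
    chromosome = records$chrom,
    start = records$start,
    end = records$end,
    num_motifs_in_group = records$num_motifs,
    called_sites = records$called_sites,
    called_sites_methylated = records$called_sites_methylated,
    methylated_frequency = records$methylated_frequency,
    group_sequence = if (is.null(groupSequence)) "." else groupSequence,
    stringsAsFactors = FALSE)
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' CSV with required columns `sample_id, animal_id, herd, breed, age_years`
#' and an optional `season`. Repeat samples of one animal share an
#' `animal_id` but must have distinct `sample_id`s. Ages must be positive
#' finite numbers (model-bound validation).
#'
#' @param path CSV path.
#' @return data.frame of validated metadata, one row per sample.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "animal_id", "herd", "breed", "age_years")
  missingCols <- setdiff(req, names(df))
  if (length(missingCols))
    stop("metadata is missing required column(s): ",
      paste(missingCols, collapse = ", "))
  extra <- setdiff(names(df), c(req, "season"))
  if (length(extra)) {
    warning("ignoring unknown metadata column(s): ",
      paste(extra, collapse = ", "))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
      df$sample_id[duplicated(df$sample_id)][1])
  age <- suppressWarnings(as.numeric(df$age_years))
  if (any(is.na(age)))
    stop("age_years missing or non-numeric for sample(s): ",
      paste(head(df$sample_id[is.na(age)], 3), collapse = ", "))
  if (any(age <= 0 | !is.finite(age)))
    stop("age_years must be positive and finite for sample(s): ",
      paste(head(df$sample_id[age <= 0 | !is.finite(age)], 3),
        collapse = ", "))
  df$age_years <- age
  df$herd <- as.character(df$herd)
  rownames(df) <- NULL
  df
}

#' Read gene intervals from GFF3
#'
#' Imports a GFF3 annotation and returns the features of the requested
#' type as a `GRanges` (1-based closed, the native Bioconductor
#' convention; GFF3 is also 1-based so coordinates are taken as-is).
#' The gene identifier is taken from the `ID` attribute, falling back to
#' `gene_id`; a feature with neither is an error.
#'
#' @param path GFF3 path.
#' @param featureType feature type to keep (default `"gene"`).
#' @return `GRanges` with metadata columns `gene_id` and
#'   `expected_direction` (initialised to `"unspecified"`).
#' @export
readGeneAnnotation <- function(path, featureType = "gene") {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == featureType]
  ids <- if ("ID" %in% names(mcols(gr))) as.character(gr$ID)
    else rep(NA_character_, length(gr))
  if ("gene_id" %in% names(mcols(gr))) {
    fallback <- as.character(mcols(gr)$gene_id)
    ids[is.na(ids)] <- fallback[is.na(ids)]
  }
  if (any(is.na(ids) | ids == ""))
    stop("feature(s) of type '", featureType, "' without an ID/gene_id ",
      "attribute in ", path, " (e.g. interval ",
      as.character(gr)[which(is.na(ids) | ids == "")[1]], ")")
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
    strand = strand(gr))
  mcols(out)$gene_id <- ids
  mcols(out)$expected_direction <- "unspecified"
  names(out) <- ids
  out
}

#' Read a conserved age-gene list
#'
#' CSV with columns `gene_id, expected_direction` where direction is one of
#' `positive` (methylation gain with age), `negative` (loss) or
#' `unspecified`. This is the cross-species gene set used both to build
#' the gene-restricted relationship matrix and to apply the
#' direction-concordance significance rule.
#'
#' @param path CSV path.
#' @return data.frame with columns `gene_id`, `expected_direction`.
#' @export
readConservedGeneList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "expected_direction") %in% names(df)))
    stop("conserved-gene list must have columns gene_id, expected_direction")
  ok <- df$expected_direction %in% c("positive", "negative", "unspecified")
  if (!all(ok))
    stop("invalid expected_direction value(s): ",
      paste(unique(df$expected_direction[!ok]), collapse = ", "))
  df[, c("gene_id", "expected_direction")]
}

#' Attach expected directions to gene intervals
#'
#' @param genes `GRanges` from [readGeneAnnotation()].
#' @param conserved data.frame from [readConservedGeneList()].
#' @return `genes` with `expected_direction` filled in where listed.
#' @export
annotateDirections <- function(genes, conserved) {
  idx <- match(genes$gene_id, conserved$gene_id)
  dir <- conserved$expected_direction[idx]
  mcols(genes)$expected_direction <-
    ifelse(is.na(dir), "unspecified", dir)
  genes
}

#' Serialize / read a labelled numeric matrix as TSV
#'
#' Human-inspectable serialization used for call matrices and relationship
#' matrices: first column holds row ids, remaining columns are named by
#' the matrix column ids. Missing entries are written as `NA`.
#'
#' @param m matrix with dimnames.
#' @param path file path.
#' @return `readMatrixTSV` returns the matrix with dimnames restored.
#' @export
writeMatrixTSV <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
    stringsAsFactors = FALSE)
  fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, showProgress = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Site records as genomic ranges
#'
#' Converts the 0-based inclusive-end site coordinates of a record
#' data.frame into a 1-based `GRanges` for overlap operations.
#'
#' @param records site record data.frame.
#' @return `GRanges` parallel to the rows of `records`.
#' @export
siteRanges <- function(records) {
  GRanges(records$chrom,
    IRanges(start = records$start + 1L, end = records$end + 1L))
}
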