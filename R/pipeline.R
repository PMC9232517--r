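## Orchestration: a structured run configuration, staged execution with
## ordering checks, deterministic seeding and a checksum manifest.

.RUN_KEYS <- c("outdir", "seed", "k_genome", "k_pirna", "k_mirna",
               "cpm_threshold", "anchor_min", "require_shared_locus",
               "log_level", "paths", "sim")
.PATH_KEYS <- c("mito", "nuclear", "features", "pirna_db", "mirna_db",
                "reads_dir", "samples")
.STAGES <- c("simulate", "collapse", "classify", "annotate", "families",
             "profile")

#' Create, validate, read and write a pipeline run configuration
#'
#' A run configuration holds the input paths, the mismatch allowances
#' (\code{k_genome}, \code{k_pirna}, \code{k_mirna}), the CPM threshold,
#' the family anchor length and the master seed. Configurations
#' round-trip through YAML: writing then reading yields an equal
#' configuration.
#'
#' @param outdir output directory for all stage artifacts.
#' @param seed master seed; all stochastic stages derive named
#'   sub-streams from it.
#' @param k_genome,k_pirna,k_mirna mismatch allowances for genome
#'   mapping (1), piRNA set matching (1) and miRNA set matching (2).
#' @param cpm_threshold retention threshold in counts per million (10).
#' @param anchor_min minimal family anchor length in nt (20).
#' @param require_shared_locus require a shared genomic locus for family
#'   membership.
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @param paths named list of input paths (\code{mito}, \code{nuclear},
#'   \code{features}, \code{pirna_db}, \code{mirna_db},
#'   \code{reads_dir}, \code{samples}); unset entries default to the
#'   simulate stage's outputs.
#' @param sim named list of \link{SimConfig} arguments for the simulate
#'   stage.
#' @param config,path a configuration list and a YAML file path.
#' @return \code{runConfig()} and \code{readRunConfig()} return a
#'   validated configuration list; \code{writeRunConfig()} the path.
#' @export
runConfig <- function(outdir, seed = 1L, k_genome = 1L, k_pirna = 1L,
                      k_mirna = 2L, cpm_threshold = 10,
                      anchor_min = 20L, require_shared_locus = TRUE,
                      log_level = "info", paths = list(), sim = list()) {
  config <- list(outdir = outdir, seed = as.integer(seed),
                 k_genome = as.integer(k_genome),
                 k_pirna = as.integer(k_pirna),
                 k_mirna = as.integer(k_mirna),
                 cpm_threshold = cpm_threshold,
                 anchor_min = as.integer(anchor_min),
                 require_shared_locus = isTRUE(require_shared_locus),
                 log_level = log_level, paths = paths, sim = sim)
  validateRunConfig(config)
  config
}

#' @rdname runConfig
#' @export
validateRunConfig <- function(config) {
  bad <- setdiff(names(config), .RUN_KEYS)
  if (length(bad))
    .stopf("unknown configuration keys: %s", paste(bad, collapse = ", "))
  badp <- setdiff(names(config$paths), .PATH_KEYS)
  if (length(badp))
    .stopf("unknown paths keys: %s", paste(badp, collapse = ", "))
  thr <- c(config$k_genome, config$k_pirna, config$k_mirna,
           config$cpm_threshold, config$anchor_min)
  if (any(thr < 0))
    .stopf("thresholds must be non-negative")
  for (p in unlist(config$paths))
    if (!file.exists(p)) .stopf("configured path does not exist: %s", p)
  invisible(TRUE)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), .RUN_KEYS)]
  bad <- setdiff(names(raw), .RUN_KEYS)
  if (length(bad))
    .stopf("unknown configuration keys: %s", paste(bad, collapse = ", "))
  do.call(runConfig, args)
}

#' @rdname runConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.logmsg <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message("[mitopiR] ", ...)
}

.stageDir <- function(config, stage) file.path(config$outdir, stage)

.needStage <- function(config, stage, files) {
  d <- .stageDir(config, stage)
  miss <- files[!file.exists(file.path(d, files))]
  if (length(miss))
    .stopf("missing outputs of stage '%s' (%s): run that stage first",
           stage, paste(miss, collapse = ", "))
  d
}

.pathOr <- function(config, key, stage, file) {
  p <- config$paths[[key]]
  if (!is.null(p)) return(p)
  file.path(.stageDir(config, stage), file)
}

## Rebuild the SmallRNAExperiment from stage outputs on disk.
.loadCollapsed <- function(config) {
  d <- .needStage(config, "collapse",
                  c("counts.tsv", "library_stats.tsv", "coldata.tsv",
                    "retained.tsv"))
  counts <- .readTsv(file.path(d, "counts.tsv"))
  stats <- .readTsv(file.path(d, "library_stats.tsv"))
  coldata <- .readTsv(file.path(d, "coldata.tsv"))
  ret <- .readTsv(file.path(d, "retained.tsv"))
  m <- as.matrix(counts[, -1L, drop = FALSE])
  rownames(m) <- counts$sequence
  se <- SmallRNAExperiment(m, coldata,
                           librarySize = stats$total_reads[
                             match(colnames(m), stats$sample_id)])
  rmat <- as.matrix(ret[, -1L, drop = FALSE]) > 0
  rownames(rmat) <- ret$sequence
  assay(se, "retainedIn") <- rmat[rownames(m), colnames(m),
                                  drop = FALSE]
  metadata(se)$libraryStats <- stats
  se
}

.attachClassify <- function(se, config) {
  d <- .needStage(config, "classify", c("classes.tsv", "hits.tsv"))
  cls <- .readTsv(file.path(d, "classes.tsv"))
  rowData(se)$genomeClass <-
    cls$genomeClass[match(seqStrings(se), cls$sequence)]
  hits <- data.table::fread(file.path(d, "hits.tsv"), sep = "\t")
  metadata(se)$hits <- hits
  se
}

.attachAnnotate <- function(se, config) {
  d <- .needStage(config, "annotate",
                  c("annotation.tsv", "feature_overlaps.tsv"))
  ann <- .readTsv(file.path(d, "annotation.tsv"))
  i <- match(seqStrings(se), ann$sequence)
  rowData(se)$category <- ann$category[i]
  rowData(se)$pirna_ids <- ifelse(is.na(ann$pirna_ids[i]), "",
                                  ann$pirna_ids[i])
  rowData(se)$pirna_multi <- as.logical(ann$pirna_multi[i])
  rowData(se)$mirna_ids <- ifelse(is.na(ann$mirna_ids[i]), "",
                                  ann$mirna_ids[i])
  fo <- data.table::fread(file.path(d, "feature_overlaps.tsv"),
                          sep = "\t")
  metadata(se)$featureOverlaps <- fo
  se
}

#' Run the pipeline
#'
#' Executes the requested stages in order — \code{simulate},
#' \code{collapse}, \code{classify}, \code{annotate}, \code{families},
#' \code{profile} — writing each stage's artifacts under
#' \code{outdir/<stage>/} and a manifest (inputs, parameters, MD5
#' checksums) at \code{outdir/manifest.json}. Re-running with an
#' identical configuration reproduces identical checksums. Running a
#' stage whose prerequisites are missing raises an error naming the
#' stage to run first.
#'
#' @param config a configuration from \link{runConfig} or
#'   \link{readRunConfig}.
#' @param stages \code{"all"} or a subset of the stage names.
#' @return (invisibly) the manifest list.
#' @export
runPipeline <- function(config, stages = "all") {
  validateRunConfig(config)
  if (identical(stages, "all")) stages <- .STAGES
  bad <- setdiff(stages, .STAGES)
  if (length(bad)) .stopf("unknown stages: %s", paste(bad, collapse = ", "))
  stages <- .STAGES[.STAGES %in% stages]
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())

  for (stage in stages) {
    .logmsg(config, "stage: ", stage)
    switch(stage,
           simulate = .stageSimulate(config, state),
           collapse = .stageCollapse(config, state),
           classify = .stageClassify(config, state),
           annotate = .stageAnnotate(config, state),
           families = .stageFamilies(config, state),
           profile = .stageProfile(config, state))
  }
  manifest <- .writeManifest(config)
  invisible(manifest)
}

.stageSimulate <- function(config, state) {
  cfg <- do.call(SimConfig, c(list(seed = config$seed), config$sim))
  state$sim <- simulateDataset(cfg, .stageDir(config, "simulate"))
}

.stageCollapse <- function(config, state) {
  rdir <- .pathOr(config, "reads_dir", "simulate", "reads")
  if (!dir.exists(rdir))
    .stopf("reads directory '%s' not found: run the simulate stage first or set paths$reads_dir",
           rdir)
  files <- sort(list.files(rdir, pattern = "\\.(fastq|fq|fasta|fa)(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) .stopf("no read files in %s", rdir)
  names(files) <- sub("\\.(fastq|fq|fasta|fa)(\\.gz)?$", "",
                      basename(files))
  samplesPath <- .pathOr(config, "samples", "simulate", "samples.tsv")
  sampleData <- if (file.exists(samplesPath)) .readTsv(samplesPath)
                else NULL
  if (!is.null(sampleData))
    files <- files[intersect(sampleData$sample_id, names(files))]
  se <- collapseReads(files, sampleData)
  se <- filterCPM(se, config$cpm_threshold)
  d <- .stageDir(config, "collapse")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  counts <- assay(se, "counts")
  .writeTsv(data.frame(sequence = rownames(counts), counts,
                       check.names = FALSE), file.path(d, "counts.tsv"))
  ret <- assay(se, "retainedIn")
  .writeTsv(data.frame(sequence = rownames(ret), ret * 1L,
                       check.names = FALSE), file.path(d, "retained.tsv"))
  .writeTsv(metadata(se)$libraryStats,
            file.path(d, "library_stats.tsv"))
  .writeTsv(as.data.frame(colData(se)), file.path(d, "coldata.tsv"))
  state$se <- se
}

.stageClassify <- function(config, state) {
  if (is.null(state$se)) state$se <- .loadCollapsed(config)
  nuclear <- as.character(Biostrings::readDNAStringSet(
    .pathOr(config, "nuclear", "simulate", "nuclear.fa")))
  mito <- as.character(Biostrings::readDNAStringSet(
    .pathOr(config, "mito", "simulate", "mito.fa")))
  se <- classifySequences(state$se, nuclear, mito, k = config$k_genome)
  d <- .stageDir(config, "classify")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  .writeTsv(data.frame(sequence = seqStrings(se),
                       length = nchar(seqStrings(se)),
                       genomeClass = genomeClasses(se)),
            file.path(d, "classes.tsv"))
  .writeTsv(as.data.frame(genomeHits(se)), file.path(d, "hits.tsv"))
  writeHits(se, file.path(d, "hits.bed"), format = "bed",
            contigLengths = c(chrM = nchar(mito[[1]])))
  state$se <- se
  state$mitoLength <- nchar(mito[[1]])
}

.stageAnnotate <- function(config, state) {
  if (is.null(state$se))
    state$se <- .attachClassify(.loadCollapsed(config), config)
  pirnaDb <- readReferenceSet(
    .pathOr(config, "pirna_db", "simulate", "pirna_db.fa"))
  mirnaDb <- readReferenceSet(
    .pathOr(config, "mirna_db", "simulate", "mirna_db.fa"))
  if (is.null(state$mitoLength)) {
    mito <- as.character(Biostrings::readDNAStringSet(
      .pathOr(config, "mito", "simulate", "mito.fa")))
    state$mitoLength <- nchar(mito[[1]])
  }
  features <- readFeatureAnnotation(
    .pathOr(config, "features", "simulate", "mito_features.gff3"),
    state$mitoLength)
  se <- annotateDb(state$se, pirnaDb, mirnaDb,
                   kPirna = config$k_pirna, kMirna = config$k_mirna)
  se <- assignFeatures(se, features)
  d <- .stageDir(config, "annotate")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  rd <- rowData(se)
  .writeTsv(data.frame(sequence = rd$sequence, length = rd$length,
                       genomeClass = genomeClasses(se),
                       category = rd$category,
                       pirna_ids = rd$pirna_ids,
                       pirna_multi = rd$pirna_multi,
                       mirna_ids = rd$mirna_ids),
            file.path(d, "annotation.tsv"))
  .writeTsv(as.data.frame(metadata(se)$featureOverlaps),
            file.path(d, "feature_overlaps.tsv"))
  state$se <- se
  state$features <- features
}

.stageFamilies <- function(config, state) {
  if (is.null(state$se)) {
    se <- .attachClassify(.loadCollapsed(config), config)
    state$se <- .attachAnnotate(se, config)
  }
  fams <- buildFamilies(state$se, anchorMin = config$anchor_min,
                        requireSharedLocus = config$require_shared_locus)
  d <- .stageDir(config, "families")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  .writeTsv(as.data.frame(familyTable(fams)),
            file.path(d, "families.tsv"))
  writeFamilyMembers(fams, state$se, file.path(d, "members.tsv"))
  dp <- directionProportions(fams)
  dpOut <- list(counts = as.list(dp$counts),
                percentages = as.list(dp$percentages),
                denominator = dp$denominator,
                unresolved = dp$unresolved, empty = dp$empty)
  jsonlite::write_json(dpOut, file.path(d, "direction_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  state$families <- fams
}

.stageProfile <- function(config, state) {
  if (is.null(state$se)) {
    se <- .attachClassify(.loadCollapsed(config), config)
    state$se <- .attachAnnotate(se, config)
  }
  se <- state$se
  d <- .stageDir(config, "profile")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  summ <- summarizeCounts(se)
  .writeTsv(summ$table, file.path(d, "sample_table.tsv"))
  mitoSub <- which(genomeClasses(se) %in% c("MT", "NUMT"))
  metrics <- list(proportions = as.list(summ$proportions))
  if (length(mitoSub)) {
    bs <- positionalBias(se, "sequence", mitoSub, "mito-matching")
    br <- positionalBias(se, "read", mitoSub, "mito-matching")
    .writeTsv(data.frame(position = seq_len(nrow(bs)), bs),
              file.path(d, "bias_sequence.tsv"))
    .writeTsv(data.frame(position = seq_len(nrow(br)), br),
              file.path(d, "bias_read.tsv"))
    metrics$pos1 <- list(
      sequence_weighted = as.list(bs[1, ]),
      read_weighted = as.list(br[1, ]),
      modal_sequence = attr(bs, "pos1Modal"),
      modal_read = attr(br, "pos1Modal"))
  }
  fd <- featureDistribution(se)
  .writeTsv(fd, file.path(d, "feature_distribution.tsv"))
  if (!is.null(state$features)) {
    .writeTsv(perKbEnrichment(se, state$features),
              file.path(d, "per_kb_enrichment.tsv"))
  }
  sm <- strandMatrix(se)
  .writeTsv(data.frame(row = rownames(sm), sm, check.names = FALSE),
            file.path(d, "strand_matrix.tsv"))
  if (ncol(se) >= 3L && nrow(sm)) {
    pca <- pcaSamples(sm)
    .writeTsv(data.frame(sample_id = rownames(pca$coordinates),
                         pca$coordinates,
                         check.names = FALSE),
              file.path(d, "pca.tsv"))
    metrics$pca_variance_explained <- pca$varianceExplained
  }
  dsPath <- file.path(.stageDir(config, "families"),
                      "direction_summary.json")
  if (file.exists(dsPath))
    metrics$direction <- jsonlite::read_json(dsPath)
  jsonlite::write_json(metrics, file.path(d, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Write the family member table in report layout
#'
#' One row per member: sequence, length, MT/NUMT class, role, the
#' matching piRNA ids (prefixed with \code{*} when multiple piRNAs match
#' within the allowed mismatch), and per-sample read counts.
#'
#' @param fams a \link{PiRNAFamilySet}.
#' @param se the \link{SmallRNAExperiment} the families were built from.
#' @param file output TSV path.
#' @return the path, invisibly.
#' @export
writeFamilyMembers <- function(fams, se, file) {
  mt <- as.data.frame(memberTable(fams))
  counts <- assay(se, "counts")
  i <- match(mt$sequence, seqStrings(se))
  ann <- ifelse(mt$pirna_multi, paste0("*", mt$pirna_ids), mt$pirna_ids)
  out <- data.frame(family_id = mt$family_id, sequence = mt$sequence,
                    length = mt$length, class = mt$genome_class,
                    role = mt$role, annotation = ann,
                    counts[i, , drop = FALSE], check.names = FALSE,
                    stringsAsFactors = FALSE)
  .writeTsv(out, file)
}

.writeManifest <- function(config) {
  stages <- list()
  for (stage in .STAGES) {
    d <- .stageDir(config, stage)
    if (!dir.exists(d)) next
    files <- sort(list.files(d, recursive = TRUE, full.names = TRUE))
    stages[[stage]] <- list(
      files = as.list(file.path(stage, sort(list.files(d,
                                                       recursive = TRUE)))),
      md5 = as.list(unname(tools::md5sum(files))))
  }
  manifest <- list(parameters = config[setdiff(names(config), "outdir")],
                   stages = stages)
  jsonlite::write_json(manifest, file.path(config$outdir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
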