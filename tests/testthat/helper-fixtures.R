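# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

tinySimConfig <- function(seed = 7L, ...) {
  defaults <- list(seed = seed,
                   nuclearContigs = c(chr1 = 30000L, chr2 = 20000L),
                   readsPerSample = 3000L,
                   samples = sampleGrid(3000L),
                   nBackgroundLoci = 60L,
                   familyMeanReads = 50,
                   numtDivergence = 0,
                   decoyDbEntries = 15L)
  override <- list(...)
  do.call(SimConfig, modifyList(defaults, override))
}

# A small complete dataset plus a fully processed SmallRNAExperiment and
# families, shared across test files.
tinyRun <- function() {
  if (!is.null(.fixtureCache$tiny)) return(.fixtureCache$tiny)
  cfg <- tinySimConfig()
  dir <- file.path(tempdir(), "mitopiR-tiny")
  sim <- suppressWarnings(simulateDataset(cfg, dir))
  files <- setNames(sim$reads$files,
                    sub("\\.fastq$", "", basename(sim$reads$files)))
  se <- collapseReads(files, cfg@samples)
  se <- filterCPM(se, 10)
  se <- classifySequences(se, sim$nuclear$contigs, sim$mito$genome)
  se <- annotateDb(se, sim$plan$pirnaDb, sim$plan$mirnaDb)
  se <- assignFeatures(se, sim$mito$features)
  fams <- buildFamilies(se)
  .fixtureCache$tiny <- list(cfg = cfg, sim = sim, se = se, fams = fams,
                             dir = dir)
  .fixtureCache$tiny
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutateAt <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  }
  paste(chars, collapse = "")
}
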