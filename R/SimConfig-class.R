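#' Configuration for the synthetic small RNA dataset generator
#'
#' A \code{SimConfig} collects every knob of the synthetic-data module:
#' genome sizes, NUMT insertions, planted piRNA families, sequencing depth,
#' the 12-sample design grid, the first-position adenine bias of background
#' reads and the fraction of D-loop reads emitted antisense to the reference.
#' The same configuration (including \code{seed}) always produces
#' byte-identical outputs.
#'
#' @slot seed integer master seed; every stochastic stage derives a named
#'   sub-stream from it.
#' @slot mitoLength length of the circular mitochondrial genome (nt).
#' @slot nuclearContigs named integer vector of nuclear contig lengths (nt).
#' @slot nNumts number of mitochondrial fragments copied into the nuclear
#'   contigs (NUMTs).
#' @slot numtLengthRange integer \code{c(min, max)} NUMT length (nt).
#' @slot numtDivergence per-base substitution probability applied to each
#'   NUMT copy, in [0, 1].
#' @slot nFamilies number of planted piRNA families.
#' @slot familyLadder member lengths of each family, precursor first,
#'   strictly decreasing; the shorter lengths are the 5'-anchored mature
#'   forms obtained by 3' trimming.
#' @slot directionMix named numeric \code{c(retrograde=, anterograde=,
#'   self=)} proportions of planted family directions; sums to 1.
#' @slot pos1ABias probability that a background read starts with adenine
#'   (the 1A bias observed for mito-piRNAs).
#' @slot samples data.frame with columns \code{sample_id}, \code{cell_type}
#'   (PGC/SC), \code{sex} (F/M), \code{dpc} (11.5/12.5/13.5),
#'   \code{total_reads}.
#' @slot readsPerSample reads emitted per sample.
#' @slot dloopReverseFraction probability that a background read from the
#'   D-loop is emitted antisense to the forward reference strand.
#' @slot decoyDbEntries number of random decoy entries added to each
#'   reference set; decoys are certified absent (Hamming distance >= 2)
#'   from both genomes.
#' @slot nBackgroundLoci number of expressed background loci.
#' @slot bgMitoFraction fraction of background expression drawn from the
#'   mitochondrial genome.
#' @slot noiseFraction fraction of reads drawn from unmappable noise
#'   sequences.
#' @slot familyMeanReads lognormal mean expression (reads/sample) of a
#'   planted family member.
#' @slot plantDual also place one mature family member in the miRNA set to
#'   create a dual miRNA/piRNA case.
#' @slot plantMulti add one redundant piRNA entry (same sequence, second
#'   id) so one mature matches multiple piRNA ids.
#' @slot nTrna,nRrna,nCds number of tRNA, rRNA and protein-coding features
#'   annotated on the mitochondrial genome.
#'
#' @return \code{SimConfig()} returns a validated \code{SimConfig} object.
#' @examples
#' cfg <- SimConfig(seed = 1L, readsPerSample = 2000L)
#' cfg
#' @aliases SimConfig
#' @export SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed = "integer",
    mitoLength = "integer",
    nuclearContigs = "integer",
    nNumts = "integer",
    numtLengthRange = "integer",
    numtDivergence = "numeric",
    nFamilies = "integer",
    familyLadder = "integer",
    directionMix = "numeric",
    pos1ABias = "numeric",
    samples = "data.frame",
    readsPerSample = "integer",
    dloopReverseFraction = "numeric",
    decoyDbEntries = "integer",
    nBackgroundLoci = "integer",
    bgMitoFraction = "numeric",
    noiseFraction = "numeric",
    familyMeanReads = "numeric",
    plantDual = "logical",
    plantMulti = "logical",
    nTrna = "integer",
    nRrna = "integer",
    nCds = "integer"
  )
)

#' Standard 12-sample design grid
#'
#' Cell type (PGC, SC) crossed with sex (F, M) and developmental day
#' (11.5, 12.5, 13.5 dpc) gives the 12 gonadal-cell samples profiled by the
#' pipeline's default study design.
#'
#' @param totalReads reads per sample.
#' @return data.frame with one row per sample.
#' @export
#' @examples
#' sampleGrid(1000L)
sampleGrid <- function(totalReads = 100000L) {
  grid <- expand.grid(sex = c("F", "M"), dpc = c("11.5", "12.5", "13.5"),
                      cell_type = c("PGC", "SC"),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = paste0(grid$cell_type, substr(grid$dpc, 1, 2), grid$sex),
    cell_type = grid$cell_type,
    sex = grid$sex,
    dpc = grid$dpc,
    total_reads = as.integer(totalReads),
    stringsAsFactors = FALSE
  )
}

SimConfig <- function(seed = 1L,
                      mitoLength = 16299L,
                      nuclearContigs = c(chr1 = 60000L, chr2 = 40000L),
                      nNumts = 12L,
                      numtLengthRange = c(120L, 400L),
                      numtDivergence = 0.02,
                      nFamilies = 10L,
                      familyLadder = c(60L, 30L, 28L, 25L),
                      directionMix = c(retrograde = 0.7, anterograde = 0.2,
                                       self = 0.1),
                      pos1ABias = 0.8,
                      readsPerSample = 100000L,
                      samples = sampleGrid(readsPerSample),
                      dloopReverseFraction = 1.0,
                      decoyDbEntries = 50L,
                      nBackgroundLoci = 300L,
                      bgMitoFraction = 0.35,
                      noiseFraction = 0.01,
                      familyMeanReads = 500,
                      plantDual = TRUE,
                      plantMulti = TRUE,
                      nTrna = 22L,
                      nRrna = 2L,
                      nCds = 13L) {
  new("SimConfig",
      seed = as.integer(seed), mitoLength = as.integer(mitoLength),
      nuclearContigs = setNames(as.integer(nuclearContigs),
                                names(nuclearContigs)),
      nNumts = as.integer(nNumts),
      numtLengthRange = as.integer(numtLengthRange),
      numtDivergence = numtDivergence, nFamilies = as.integer(nFamilies),
      familyLadder = as.integer(familyLadder), directionMix = directionMix,
      pos1ABias = pos1ABias, samples = samples,
      readsPerSample = as.integer(readsPerSample),
      dloopReverseFraction = dloopReverseFraction,
      decoyDbEntries = as.integer(decoyDbEntries),
      nBackgroundLoci = as.integer(nBackgroundLoci),
      bgMitoFraction = bgMitoFraction, noiseFraction = noiseFraction,
      familyMeanReads = familyMeanReads, plantDual = plantDual,
      plantMulti = plantMulti, nTrna = as.integer(nTrna),
      nRrna = as.integer(nRrna), nCds = as.integer(nCds))
}

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@mitoLength <= 0L || any(object@nuclearContigs <= 0L))
    msg <- c(msg, "all genome lengths must be positive")
  if (is.null(names(object@nuclearContigs)) ||
      anyDuplicated(names(object@nuclearContigs)))
    msg <- c(msg, "nuclearContigs must have unique names")
  probs <- c(object@numtDivergence, object@pos1ABias,
             object@dloopReverseFraction, object@bgMitoFraction,
             object@noiseFraction)
  if (any(probs < 0) || any(probs > 1))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  if (length(object@familyLadder) < 2L ||
      any(diff(object@familyLadder) >= 0L))
    msg <- c(msg, "familyLadder must be strictly decreasing")
  if (max(object@familyLadder) > 75L)
    msg <- c(msg, "familyLadder lengths must be <= 75 nt")
  if (min(object@familyLadder) < 20L)
    msg <- c(msg, "familyLadder lengths must be >= 20 nt (5' anchor)")
  if (length(object@numtLengthRange) != 2L ||
      object@numtLengthRange[1] > object@numtLengthRange[2] ||
      object@numtLengthRange[1] <= 0L)
    msg <- c(msg, "numtLengthRange must be a positive (min, max) pair")
  if (abs(sum(object@directionMix) - 1) > 1e-8 ||
      !all(c("retrograde", "anterograde", "self") %in%
           names(object@directionMix)))
    msg <- c(msg, paste("directionMix must be named",
                        "(retrograde, anterograde, self) and sum to 1"))
  s <- object@samples
  need <- c("sample_id", "cell_type", "sex", "dpc", "total_reads")
  if (!all(need %in% colnames(s))) {
    msg <- c(msg, paste("samples must have columns",
                        paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(s$sample_id))
      msg <- c(msg, "sample_id must be unique")
    if (any(s$total_reads <= 0))
      msg <- c(msg, "total_reads must be positive")
  }
  if (object@readsPerSample <= 0L)
    msg <- c(msg, "readsPerSample must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (seed ", object@seed, ")\n", sep = "")
  cat("  mito genome: ", object@mitoLength, " nt (circular); nuclear: ",
      paste0(names(object@nuclearContigs), "=", object@nuclearContigs,
             collapse = ", "), "\n", sep = "")
  cat("  NUMTs: ", object@nNumts, " (", object@numtLengthRange[1], "-",
      object@numtLengthRange[2], " nt, divergence ",
      object@numtDivergence, ")\n", sep = "")
  cat("  families: ", object@nFamilies, " ladder [",
      paste(object@familyLadder, collapse = ","), "] mix ",
      paste0(round(100 * object@directionMix), "%",
             collapse = "/"), "\n", sep = "")
  cat("  samples: ", nrow(object@samples), " x ",
      object@readsPerSample, " reads; pos1 A bias ", object@pos1ABias,
      "; D-loop reverse ", object@dloopReverseFraction, "\n", sep = "")
})
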