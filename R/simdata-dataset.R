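#' Generate and write a complete synthetic dataset
#'
#' Runs the whole generator — mitochondrial genome and features, nuclear
#' contigs with NUMTs, planted families and reference sets, reads — and
#' writes every artifact in standard formats: genome FASTA, feature
#' annotation as GFF3 and BED6, reference sets as FASTA, per-sample
#' FASTQ, sample metadata, the NUMT table, the family plan and the truth
#' table as TSV.
#'
#' @param cfg a \link{SimConfig}.
#' @param dir output directory.
#' @return (invisibly) list with the in-memory pieces (\code{mito},
#'   \code{nuclear}, \code{plan}, \code{reads}) and \code{files}.
#' @export
#' @importFrom Biostrings writeXStringSet
#' @examples
#' \donttest{
#' cfg <- SimConfig(seed = 1L, readsPerSample = 2000L,
#'                  nBackgroundLoci = 60L, familyMeanReads = 40)
#' sim <- simulateDataset(cfg, tempfile("sim"))
#' head(sim$reads$truth$sequence)
#' }
simulateDataset <- function(cfg, dir) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mito <- genMitoGenome(cfg)
  nuclear <- genNuclearGenome(cfg, mito)
  plan <- plantFamilies(cfg, mito, nuclear)
  reads <- simulateReads(cfg, mito, nuclear, plan, dir)
  fp <- function(...) file.path(dir, ...)
  writeXStringSet(DNAStringSet(c(chrM = mito$genome[["chrM"]])),
                  fp("mito.fa"))
  writeXStringSet(DNAStringSet(nuclear$contigs), fp("nuclear.fa"))
  writeFeatureAnnotation(mito$features, fp("mito_features.gff3"))
  writeFeatureAnnotation(mito$features, fp("mito_features.bed"))
  writeXStringSet(Biostrings::BStringSet(plan$pirnaDb),
                  fp("pirna_db.fa"))
  writeXStringSet(Biostrings::BStringSet(plan$mirnaDb),
                  fp("mirna_db.fa"))
  .writeTsv(cfg@samples, fp("samples.tsv"))
  .writeTsv(nuclear$numts, fp("numt_table.tsv"))
  planOut <- plan$members[, setdiff(colnames(plan$members),
                                    c("iv_start", "iv_end"))]
  .writeTsv(planOut, fp("family_plan.tsv"))
  .writeTsv(reads$truth, fp("truth.tsv"))
  countsOut <- data.frame(sequence = rownames(reads$counts),
                          reads$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  .writeTsv(countsOut, fp("true_counts.tsv"))
  files <- c(fp(c("mito.fa", "nuclear.fa", "mito_features.gff3",
                  "mito_features.bed", "pirna_db.fa", "mirna_db.fa",
                  "samples.tsv", "numt_table.tsv", "family_plan.tsv",
                  "truth.tsv", "true_counts.tsv")), reads$files)
  invisible(list(mito = mito, nuclear = nuclear, plan = plan,
                 reads = reads, files = files))
}

#' Read a piRNA/miRNA reference set
#'
#' Accepts FASTA (id in header) or two-column TSV (\code{id},
#' \code{sequence}); RNA alphabets are mapped to DNA and sequences
#' uppercased.
#'
#' @param path reference set file.
#' @return named character vector, id -> sequence.
#' @export
readReferenceSet <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    x <- Biostrings::readBStringSet(path)
    out <- setNames(as.character(x), names(x))
  } else {
    tab <- .readTsv(path)
    if (!all(c("id", "sequence") %in% colnames(tab)))
      .stopf("TSV reference set needs 'id' and 'sequence' columns")
    out <- setNames(tab$sequence, tab$id)
  }
  toupper(chartr("Uu", "Tt", out))
}
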