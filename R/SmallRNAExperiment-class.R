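#' Container for collapsed small RNA sequences
#'
#' \code{SmallRNAExperiment} extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: rows are unique
#' (collapsed) read sequences, columns are samples. The \code{counts} assay
#' holds per-sample read counts, \code{cpm} the counts-per-million values
#' computed against the per-sample library size (total trimmed reads
#' entering collapse), and, after filtering, \code{retainedIn} flags the
#' samples in which a sequence passes the CPM threshold. Pipeline stages
#' add row annotation (genome class, category, reference-set matches) and
#' cache genome placements in \code{metadata(x)$hits}.
#'
#' @param counts integer matrix, sequences x samples; rownames are the
#'   sequences (uppercase DNA).
#' @param sampleData data.frame of per-sample metadata, one row per column
#'   of \code{counts}.
#' @param librarySize named numeric vector of per-sample totals used as
#'   the CPM denominator; defaults to \code{colSums(counts)}.
#' @param x a \code{SmallRNAExperiment}.
#'
#' @return \code{SmallRNAExperiment()} returns the constructed object.
#'   \code{seqStrings()} the character vector of sequences;
#'   \code{genomeClasses()} the NU/MT/NUMT/UNMAPPED labels (NA before
#'   classification); \code{categories()} the piRNA/miRNA/dual/other
#'   labels; \code{librarySizes()} the CPM denominators; \code{genomeHits()}
#'   the cached placement table.
#'
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2,
#'             dimnames = list(c("ACGTACGTACGTACGTACGT",
#'                               "TTTTACGTACGTACGTACGT"), c("s1", "s2")))
#' se <- SmallRNAExperiment(m, data.frame(sample_id = c("s1", "s2")))
#' seqStrings(se)
#' @aliases SmallRNAExperiment seqStrings genomeClasses categories
#'   librarySizes genomeHits
#' @export SmallRNAExperiment
#' @exportClass SmallRNAExperiment
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData rowData<- colData<- assay<-
#' @importFrom S4Vectors metadata metadata<- DataFrame
setClass("SmallRNAExperiment", contains = "SummarizedExperiment")

SmallRNAExperiment <- function(counts, sampleData,
                               librarySize = colSums(counts)) {
  stopifnot(is.matrix(counts),
            nrow(counts) == 0L || !is.null(rownames(counts)))
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts)) && nrow(sampleData) == ncol(counts))
    colnames(counts) <- sampleData$sample_id
  ls <- setNames(as.numeric(librarySize), colnames(counts))
  cpm <- sweep(counts, 2, pmax(ls, 1), "/") * 1e6
  cpm[, ls == 0] <- 0
  seqv <- if (is.null(rownames(counts))) character(0) else
    rownames(counts)
  rd <- DataFrame(sequence = seqv, length = nchar(seqv))
  se <- SummarizedExperiment(
    assays = list(counts = counts, cpm = cpm),
    rowData = rd,
    colData = DataFrame(sampleData, row.names = colnames(counts)))
  metadata(se)$librarySize <- ls
  new("SmallRNAExperiment", se)
}

setValidity("SmallRNAExperiment", function(object) {
  msg <- character(0)
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else if (any(assay(object, "counts") < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  sq <- rowData(object)$sequence
  if (is.null(sq))
    msg <- c(msg, "rowData column 'sequence' is required")
  else if (length(sq) && any(grepl("[^ACGT]", sq)))
    msg <- c(msg, "sequences must be uppercase A/C/G/T only")
  if (length(msg)) msg else TRUE
})

#' @rdname SmallRNAExperiment-class
#' @export
setMethod("seqStrings", "SmallRNAExperiment", function(x)
  as.character(rowData(x)$sequence))

#' @rdname SmallRNAExperiment-class
#' @export
setMethod("genomeClasses", "SmallRNAExperiment", function(x) {
  cl <- rowData(x)$genomeClass
  if (is.null(cl)) rep(NA_character_, nrow(x)) else as.character(cl)
})

#' @rdname SmallRNAExperiment-class
#' @export
setMethod("categories", "SmallRNAExperiment", function(x) {
  ct <- rowData(x)$category
  if (is.null(ct)) rep(NA_character_, nrow(x)) else as.character(ct)
})

#' @rdname SmallRNAExperiment-class
#' @export
setMethod("librarySizes", "SmallRNAExperiment", function(x)
  metadata(x)$librarySize)

#' @rdname SmallRNAExperiment-class
#' @export
setMethod("genomeHits", "SmallRNAExperiment", function(x)
  metadata(x)$hits)

setMethod("show", "SmallRNAExperiment", function(object) {
  cat("SmallRNAExperiment: ", nrow(object), " unique sequences x ",
      ncol(object), " samples\n", sep = "")
  cat("  lengths: ", min(rowData(object)$length), "-",
      max(rowData(object)$length), " nt\n", sep = "")
  cl <- genomeClasses(object)
  if (!all(is.na(cl))) {
    tb <- table(cl)
    cat("  classes: ",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n", sep = "")
  }
  ct <- categories(object)
  if (!all(is.na(ct))) {
    tb <- table(ct)
    cat("  categories: ",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n", sep = "")
  }
  cat("  assays: ", paste(assayNames(object), collapse = ", "),
      "\n", sep = "")
})
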