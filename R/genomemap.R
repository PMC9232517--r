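## Bounded-mismatch placement of unique sequences on the nuclear and
## mitochondrial genomes and derivation of the NU/MT/NUMT class.
##
## Matching is Hamming-only (no indels), mirroring an ungapped -v style
## alignment; only the minimal-mismatch stratum is reported (best/strata
## semantics) but all placements within that stratum are kept, which the
## NUMT logic requires. The mitochondrial genome is circular: the search
## runs on the sequence extended by its first (query length - 1) bases so
## junction-spanning placements are found, with coordinates reported
## modulo the genome length.

.asDNAStringSet <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is(genome, "DNAString")) return(Biostrings::DNAStringSet(genome))
  if (is.character(genome)) {
    out <- Biostrings::DNAStringSet(unname(genome))
    names(out) <- if (is.null(names(genome)))
      paste0("contig", seq_along(genome)) else names(genome)
    return(out)
  }
  .stopf("genome must be a character vector or DNAStringSet")
}

#' Place a sequence on a genome with at most k mismatches
#'
#' Returns all placements of \code{query} (both strands) at Hamming
#' distance at most \code{k}, restricted to the minimal-distance stratum:
#' if any 0-mismatch placement exists only those are returned, else
#' 1-mismatch placements, and so on. \code{start} is the 1-based position
#' of the sequence's 5' end on the forward reference coordinate system
#' (so, for minus-strand placements, the higher coordinate of the covered
#' interval) — with this convention all members of a 5'-anchored family
#' share the same \code{start}.
#'
#' @param query DNA string (A/C/G/T only), at most 75 nt.
#' @param genome named character vector of contig sequences or a
#'   \code{DNAStringSet}.
#' @param k maximum number of mismatches (0-3).
#' @param circular treat each contig as circular (used for the
#'   mitochondrial genome).
#' @return data.frame with columns \code{contig}, \code{strand},
#'   \code{start}, \code{mismatches}; zero rows when the sequence does
#'   not place.
#' @export
#' @importFrom Biostrings DNAString DNAStringSet matchPattern
#'   reverseComplement neditStartingAt
#' @examples
#' findHits("ACGTACGTACGTACGTACGTACGT",
#'          c(chr = paste0("GGGG", "ACGTACGTACGTACGTACGTACGT", "GGGG")),
#'          k = 1)
findHits <- function(query, genome, k = 1L, circular = FALSE) {
  if (!is.character(query) || length(query) != 1L)
    .stopf("query must be a single character string")
  if (grepl("[^ACGT]", query))
    .stopf("query must contain only A/C/G/T (ambiguity codes are rejected upstream)")
  if (!is.numeric(k) || k < 0 || k > 3)
    .stopf("k must be between 0 and 3")
  L <- nchar(query)
  if (L > 75L) .stopf("query length must be <= 75 nt")
  gset <- .asDNAStringSet(genome)
  qDNA <- DNAString(query)
  qRC <- reverseComplement(qDNA)
  rows <- list()
  for (ci in seq_along(gset)) {
    subj <- gset[[ci]]
    cl <- length(subj)
    if (L > cl) next
    subjS <- if (circular && L > 1L)
      Biostrings::xscat(subj, Biostrings::subseq(subj, 1L, L - 1L))
    else subj
    for (str in c("+", "-")) {
      pat <- if (str == "+") qDNA else qRC
      m <- matchPattern(pat, subjS, max.mismatch = k,
                        with.indels = FALSE)
      if (!length(m)) next
      st <- Biostrings::start(m)
      mm <- neditStartingAt(pat, subjS, starting.at = st,
                            with.indels = FALSE)
      pos5 <- if (str == "+") st else st + L - 1L
      if (circular) pos5 <- ((pos5 - 1L) %% cl) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        contig = names(gset)[ci], strand = str, start = pos5,
        mismatches = as.integer(mm), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(0), strand = character(0),
                      start = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  hits <- unique(hits)
  hits <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  hits <- hits[order(hits$contig, hits$strand, hits$start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Classify every sequence as NU, MT, NUMT or UNMAPPED
#'
#' Runs \link{findHits} against the nuclear and mitochondrial genomes
#' independently (minimal-mismatch stratum per genome) and labels each
#' sequence by hit existence: \code{NUMT} if it places in both genomes,
#' \code{MT} if only in the mitochondrial genome, \code{NU} if only in
#' the nuclear genome, \code{UNMAPPED} otherwise. All placements are
#' cached in \code{metadata(se)$hits} for feature annotation and family
#' building.
#'
#' @param se a \link{SmallRNAExperiment}.
#' @param nuclear named character vector (or DNAStringSet) of nuclear
#'   contigs.
#' @param mito mitochondrial genome: a single named character string (or
#'   the list returned by \link{genMitoGenome}).
#' @param k maximum mismatches per genome (default 1).
#' @return \code{se} with \code{rowData(se)$genomeClass} filled in and
#'   hits cached.
#' @export
classifySequences <- function(se, nuclear, mito, k = 1L) {
  stopifnot(is(se, "SmallRNAExperiment"))
  if (is.list(mito) && !is.null(mito$genome)) mito <- mito$genome
  seqs <- seqStrings(se)
  nucSet <- .asDNAStringSet(nuclear)
  mtSet <- .asDNAStringSet(mito)
  hitList <- vector("list", length(seqs))
  cls <- character(length(seqs))
  for (i in seq_along(seqs)) {
    hn <- findHits(seqs[i], nucSet, k = k, circular = FALSE)
    hm <- findHits(seqs[i], mtSet, k = k, circular = TRUE)
    cls[i] <- if (nrow(hn) && nrow(hm)) "NUMT"
      else if (nrow(hm)) "MT"
      else if (nrow(hn)) "NU"
      else "UNMAPPED"
    both <- rbind(
      if (nrow(hn)) cbind(genome = "nuclear", hn,
                          stringsAsFactors = FALSE) else NULL,
      if (nrow(hm)) cbind(genome = "mito", hm,
                          stringsAsFactors = FALSE) else NULL)
    if (!is.null(both) && nrow(both)) {
      both$sequence <- seqs[i]
      both$length <- nchar(seqs[i])
      hitList[[i]] <- both
    }
  }
  rowData(se)$genomeClass <- cls
  hits <- data.table::rbindlist(hitList[!vapply(hitList, is.null,
                                                logical(1))])
  metadata(se)$hits <- if (nrow(hits)) hits else
    data.table::data.table(genome = character(0), contig = character(0),
                           strand = character(0), start = integer(0),
                           mismatches = integer(0),
                           sequence = character(0), length = integer(0))
  metadata(se)$kGenome <- k
  se
}

#' Inclusive span between two 1-based coordinates
#'
#' The length of the interval between coordinates \code{a} and \code{b}
#' under the 1-based inclusive convention, order-free: |a - b| + 1. When
#' \code{circularLength} is given (mitochondrial genome), the
#' complementary span through the origin is reported as well.
#'
#' @param a,b 1-based coordinates.
#' @param circularLength genome length for the circular alternative.
#' @return named numeric: \code{linear}, plus \code{circular} when
#'   \code{circularLength} is given.
#' @export
#' @examples
#' spanLength(16119, 16188)  # 70
spanLength <- function(a, b, circularLength = NULL) {
  if (any(c(a, b) < 1)) .stopf("coordinates must be >= 1")
  lin <- abs(a - b) + 1
  if (is.null(circularLength)) return(c(linear = lin))
  c(linear = lin, circular = circularLength - abs(a - b) + 1)
}

#' Export cached genome hits
#'
#' Writes the hits table as TSV (1-based inclusive, 5'-anchored) or BED6
#' (0-based half-open; junction-spanning mitochondrial placements are
#' split into two lines).
#'
#' @param se a classified \link{SmallRNAExperiment}.
#' @param file output path.
#' @param format \code{"tsv"} or \code{"bed"}.
#' @param contigLengths named lengths used to split circular hits for BED.
#' @return the path, invisibly.
#' @export
writeHits <- function(se, file, format = c("tsv", "bed"),
                      contigLengths = NULL) {
  format <- match.arg(format)
  hits <- as.data.frame(genomeHits(se))
  if (format == "tsv") {
    .writeTsv(hits, file)
    return(invisible(file))
  }
  if (!nrow(hits)) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  a <- ifelse(hits$strand == "+", hits$start,
              hits$start - hits$length + 1L)
  b <- a + hits$length - 1L
  lines <- character(0)
  for (i in seq_len(nrow(hits))) {
    cl <- if (!is.null(contigLengths) &&
              hits$contig[i] %in% names(contigLengths))
      contigLengths[[hits$contig[i]]] else NA_integer_
    ivs <- if (!is.na(cl) && (a[i] < 1L || b[i] > cl))
      .circularPieces(a[i], b[i], cl)
    else list(start = a[i], end = b[i])
    lines <- c(lines, paste(hits$contig[i], ivs$start - 1L, ivs$end,
                            hits$sequence[i], hits$mismatches[i],
                            hits$strand[i], sep = "\t"))
  }
  writeLines(lines, file)
  invisible(file)
}
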