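## Annotation: equal-length bounded-mismatch matching against the piRNA
## and miRNA reference sets, the piRNA/miRNA/dual/other category call,
## and assignment of mitochondrial placements to annotated features with
## read orientation.

#' Match a sequence against a reference set
#'
#' An entry matches if it has the same length as the query and Hamming
#' distance at most \code{k} (same-strand comparison); only the
#' minimal-distance stratum is returned. Equal-length matching keeps the
#' mature-versus-precursor distinction sharp: a precursor never "matches"
#' the reference set through its 5' prefix (prefix relations are the
#' business of family building).
#'
#' @param query DNA string.
#' @param db named character vector, id -> sequence (DNA alphabet).
#' @param k maximum mismatches (1 for piRNA sets, 2 for miRNA sets by
#'   convention).
#' @return data.frame with columns \code{id}, \code{mismatches}.
#' @export
#' @examples
#' matchDb("ACGTACGTACGTACGTACGTACGTA",
#'         c(p1 = "ACGTACGTACGTACGTACGTACGTA"), k = 1)
matchDb <- function(query, db, k = 1L) {
  L <- nchar(query)
  cand <- which(nchar(db) == L)
  if (!length(cand))
    return(data.frame(id = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  q <- utf8ToInt(query)
  mm <- vapply(db[cand], function(s) sum(utf8ToInt(s) != q), integer(1))
  keep <- mm <= k
  if (!any(keep))
    return(data.frame(id = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  mm <- mm[keep]
  ids <- names(db)[cand][keep]
  strat <- mm == min(mm)
  data.frame(id = ids[strat], mismatches = as.integer(mm[strat]),
             stringsAsFactors = FALSE)
}

#' Annotate sequences against the piRNA and miRNA reference sets
#'
#' Calls \link{matchDb} per sequence and derives the category:
#' \code{dual} when both sets match, \code{piRNA} or \code{miRNA} when
#' only one does, \code{other} when neither does. 'Other' sequences are
#' retained — they count toward mitochondrial small-RNA totals but not
#' toward the piRNA/miRNA columns.
#'
#' @param se a \link{SmallRNAExperiment}.
#' @param pirnaDb,mirnaDb named character vectors, id -> sequence.
#' @param kPirna,kMirna mismatch allowances (defaults 1 and 2).
#' @return \code{se} with rowData columns \code{category},
#'   \code{pirna_ids}, \code{pirna_multi}, \code{mirna_ids}.
#' @export
annotateDb <- function(se, pirnaDb, mirnaDb, kPirna = 1L, kMirna = 2L) {
  stopifnot(is(se, "SmallRNAExperiment"))
  seqs <- seqStrings(se)
  pir <- lapply(seqs, matchDb, db = pirnaDb, k = kPirna)
  mir <- lapply(seqs, matchDb, db = mirnaDb, k = kMirna)
  nPir <- vapply(pir, nrow, integer(1))
  nMir <- vapply(mir, nrow, integer(1))
  rowData(se)$category <- ifelse(nPir > 0L & nMir > 0L, "dual",
                          ifelse(nPir > 0L, "piRNA",
                          ifelse(nMir > 0L, "miRNA", "other")))
  rowData(se)$pirna_ids <- vapply(pir, function(d)
    paste(d$id, collapse = ","), character(1))
  rowData(se)$pirna_multi <- nPir > 1L
  rowData(se)$mirna_ids <- vapply(mir, function(d)
    paste(d$id, collapse = ","), character(1))
  metadata(se)$kPirna <- kPirna
  metadata(se)$kMirna <- kMirna
  se
}

#' Feature overlaps of a single mitochondrial placement
#'
#' All annotated features overlapping the covered interval
#' (circular-aware) with the number of overlapping bases; positions not
#' covered by any feature are reported as one \code{intergenic} record,
#' so overlap lengths always sum to the read length. Orientation is the
#' read strand relative to the feature's annotated strand; for strandless
#' features (D-loop, origin) relative to the forward reference strand.
#'
#' @param strand read strand (\code{+}/\code{-}).
#' @param start 5'-end coordinate of the placement (1-based).
#' @param length read length (nt).
#' @param features mitochondrial feature annotation (\code{GRanges} with
#'   \code{name} and \code{type}).
#' @param genomeLength circular genome length.
#' @return data.frame with columns \code{feature_name},
#'   \code{feature_type}, \code{orientation}, \code{overlap_nt}.
#' @export
hitFeatureOverlaps <- function(strand, start, length, features,
                               genomeLength) {
  if (strand == "+") { a <- start; b <- start + length - 1L }
  else { a <- start - length + 1L; b <- start }
  pieces <- .circularPieces(a, b, genomeLength)
  gr <- GRanges("chrM", IRanges(pieces$start, pieces$end))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(features)
  ov <- findOverlaps(gr, features)
  out <- NULL
  covered <- 0L
  if (length(ov)) {
    w <- width(pintersect(gr[queryHits(ov)], features[subjectHits(ov)]))
    agg <- tapply(w, subjectHits(ov), sum)
    fIdx <- as.integer(names(agg))
    out <- data.frame(
      feature_name = as.character(features$name[fIdx]),
      feature_type = as.character(features$type[fIdx]),
      orientation = vapply(fIdx, function(j)
        .orientationVs(strand,
                       as.character(GenomicRanges::strand(features)[j])),
        character(1)),
      overlap_nt = as.integer(agg), stringsAsFactors = FALSE)
    covered <- sum(agg)
  }
  if (covered < length) {
    out <- rbind(out, data.frame(
      feature_name = "intergenic", feature_type = "intergenic",
      orientation = .orientationVs(strand, "*"),
      overlap_nt = as.integer(length - covered),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Assign mitochondrial placements to annotated features
#'
#' Computes \link{hitFeatureOverlaps} for every cached mitochondrial hit
#' and stores the long-format overlap table in
#' \code{metadata(se)$featureOverlaps}. Expression attribution divides
#' each sequence's count equally among its minimal-stratum mitochondrial
#' placements (recorded as the \code{hit_weight} column) so downstream
#' feature aggregation never double counts.
#'
#' @param se a classified \link{SmallRNAExperiment}.
#' @param features mitochondrial feature annotation (\code{GRanges}).
#' @return \code{se} with the overlap table cached.
#' @export
assignFeatures <- function(se, features) {
  stopifnot(is(se, "SmallRNAExperiment"))
  hits <- genomeHits(se)
  if (is.null(hits))
    .stopf("run classifySequences() before assignFeatures()")
  L <- GenomeInfoDb::seqlengths(features)[["chrM"]]
  mh <- hits[hits$genome == "mito"]
  if (!nrow(mh)) {
    metadata(se)$featureOverlaps <- data.table::data.table()
    return(se)
  }
  nHits <- table(mh$sequence)
  rows <- vector("list", nrow(mh))
  for (i in seq_len(nrow(mh))) {
    fo <- hitFeatureOverlaps(mh$strand[i], mh$start[i], mh$length[i],
                             features, L)
    fo$sequence <- mh$sequence[i]
    fo$hit_strand <- mh$strand[i]
    fo$hit_start <- mh$start[i]
    fo$hit_weight <- 1 / as.integer(nHits[[mh$sequence[i]]])
    rows[[i]] <- fo
  }
  metadata(se)$featureOverlaps <- data.table::rbindlist(rows)
  se
}

#' Read a mitochondrial feature annotation from BED6 or GFF3
#'
#' GFF3 files carry the feature type natively; for BED6 the name column
#' uses the \code{type:name} convention written by
#' \link{writeFeatureAnnotation}. Coordinates are validated at load time.
#'
#' @param path annotation file (.bed, .gff3/.gff).
#' @param genomeLength mitochondrial genome length.
#' @return \code{GRanges} with \code{name} and \code{type} columns.
#' @export
#' @importFrom rtracklayer import export
readFeatureAnnotation <- function(path, genomeLength) {
  gr <- rtracklayer::import(path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    parts <- strsplit(as.character(gr$name), ":", fixed = TRUE)
    gr$type <- vapply(parts, `[`, character(1), 1L)
    gr$name <- vapply(parts, function(p)
      paste(p[-1], collapse = ":"), character(1))
  } else {
    if (is.null(gr$type))
      .stopf("GFF3 annotation lacks a type column")
    gr$type <- as.character(gr$type)
    if (!is.null(gr$name)) gr$name <- as.character(gr$name)
    else gr$name <- gr$type
  }
  if (any(start(gr) < 1L) || any(end(gr) > genomeLength))
    .stopf("annotation interval outside 1..%d", genomeLength)
  if (any(end(gr) < start(gr)))
    .stopf("annotation interval with end < start")
  GenomeInfoDb::seqlevels(gr) <- "chrM"
  GenomeInfoDb::seqlengths(gr) <- c(chrM = genomeLength)
  GenomeInfoDb::isCircular(gr) <- TRUE
  gr[, c("name", "type")]
}

#' Write a mitochondrial feature annotation
#'
#' @param features \code{GRanges} with \code{name} and \code{type}.
#' @param path output path; format chosen by extension (.bed writes BED6
#'   with \code{type:name} in the name column, otherwise GFF3).
#' @return the path, invisibly.
#' @export
writeFeatureAnnotation <- function(features, path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    out <- features
    out$name <- paste0(out$type, ":", out$name)
    out$type <- NULL
    rtracklayer::export(out, path, format = "BED")
  } else {
    rtracklayer::export(features, path, format = "GFF3")
  }
  invisible(path)
}
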