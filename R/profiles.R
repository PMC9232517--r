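## Summary surfaces: per-sample count table, positional nucleotide bias,
## mitochondrial feature distribution, strand-resolved expression
## matrices, and sample PCA.

#' Per-sample summary of sequences and reads by category and class
#'
#' The Table-1-shaped summary: per sample (using per-sample retention
#' flags), total retained sequences/reads, mitochondrial small-RNA
#' sequences/reads (class MT or NUMT), and sequences/reads for miRNAs and
#' piRNAs split by NU/NUMT/MT class. Dual miRNA/piRNA sequences are
#' counted with the piRNAs (membership in the piRNA set defines a piRNA
#' here); the mitochondrial remainder is the 'other' small RNAs. Cohort
#' averages and the derived proportions (mitochondrial fraction of total
#' reads; per-category fractions of mitochondrial reads) are attached.
#'
#' @param se a \link{SmallRNAExperiment} after \link{filterCPM},
#'   \link{classifySequences} and \link{annotateDb}.
#' @return list with \code{table} (data.frame, one row per sample plus
#'   an \code{Average} row) and \code{proportions} (named numeric, in
#'   percent).
#' @export
summarizeCounts <- function(se) {
  cls <- genomeClasses(se)
  cat_ <- categories(se)
  if (all(is.na(cls)) || all(is.na(cat_)))
    .stopf("run classifySequences() and annotateDb() before summarizeCounts()")
  counts <- assay(se, "counts")
  retained <- if ("retainedIn" %in% assayNames(se))
    assay(se, "retainedIn") else counts > 0L
  isMito <- cls %in% c("MT", "NUMT")
  isPir <- cat_ %in% c("piRNA", "dual")
  isMir <- cat_ == "miRNA"
  groups <- list(
    total = rep(TRUE, nrow(se)),
    mito = isMito,
    mirna_NU = isMir & cls == "NU",
    mirna_NUMT = isMir & cls == "NUMT",
    mirna_MT = isMir & cls == "MT",
    pirna_NU = isPir & cls == "NU",
    pirna_NUMT = isPir & cls == "NUMT",
    pirna_MT = isPir & cls == "MT")
  rows <- lapply(colnames(counts), function(s) {
    sel <- retained[, s]
    vals <- unlist(lapply(groups, function(g) {
      c(seq = sum(sel & g), reads = sum(counts[sel & g, s]))
    }))
    data.frame(sample_id = s, t(vals), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  avg <- colMeans(tab[, -1L])
  tab <- rbind(tab, data.frame(sample_id = "Average", t(avg),
                               stringsAsFactors = FALSE))
  mitoReads <- avg[["mito.reads"]]
  props <- c(
    mito_pct_of_total_reads = 100 * mitoReads / avg[["total.reads"]],
    mirna_NUMT_pct_of_mito = 100 * avg[["mirna_NUMT.reads"]] / mitoReads,
    mirna_MT_pct_of_mito = 100 * avg[["mirna_MT.reads"]] / mitoReads,
    pirna_NUMT_pct_of_mito = 100 * avg[["pirna_NUMT.reads"]] / mitoReads,
    pirna_MT_pct_of_mito = 100 * avg[["pirna_MT.reads"]] / mitoReads)
  props["pirna_pct_of_mito"] <- props[["pirna_NUMT_pct_of_mito"]] +
    props[["pirna_MT_pct_of_mito"]]
  if (mitoReads == 0) props[] <- NA_real_
  list(table = tab, proportions = props)
}

#' Positional nucleotide bias matrix
#'
#' Per-position base frequencies over positions 1..\code{lmax}, either
#' sequence-weighted (each unique sequence once) or read-weighted. At
#' each position, frequencies are over the sequences long enough to
#' cover it and sum to 1. The modal position-1 nucleotide is attached as
#' attribute \code{pos1Modal}; an adenine rather than the canonical
#' uridine at position 1 is the expected signature of mito-piRNAs.
#'
#' @param se a \link{SmallRNAExperiment}.
#' @param weight \code{"sequence"} or \code{"read"}.
#' @param subset optional logical/integer row subset (e.g. the
#'   mitochondria-matching sequences).
#' @param subsetName label used in error messages for empty subsets.
#' @param lmax last position profiled (default 35, the canonical upper
#'   bound of piRNA length; longer sequences contribute to positions
#'   1..35 only).
#' @return numeric matrix positions x c(A, C, G, T).
#' @export
positionalBias <- function(se, weight = c("sequence", "read"),
                           subset = NULL, subsetName = "all sequences",
                           lmax = 35L) {
  weight <- match.arg(weight)
  seqs <- seqStrings(se)
  w <- if (weight == "read") as.numeric(rowSums(assay(se, "counts")))
       else rep(1, length(seqs))
  if (!is.null(subset)) {
    seqs <- seqs[subset]
    w <- w[subset]
  }
  if (!length(seqs) || sum(w) == 0)
    .stopf("positionalBias: empty subset (%s)", subsetName)
  lmax <- min(lmax, max(nchar(seqs)))
  out <- matrix(0, lmax, 4L, dimnames = list(seq_len(lmax), DNA_BASES4))
  for (p in seq_len(lmax)) {
    ok <- nchar(seqs) >= p
    if (!any(ok)) break
    base <- substr(seqs[ok], p, p)
    agg <- rowsum(w[ok], base)
    out[p, rownames(agg)] <- agg[, 1] / sum(agg)
  }
  attr(out, "pos1Modal") <- DNA_BASES4[which.max(out[1L, ])]
  attr(out, "weight") <- weight
  out
}

.overlapWeights <- function(se, categories = NULL) {
  fo <- metadata(se)$featureOverlaps
  if (is.null(fo))
    .stopf("run assignFeatures() before feature profiling")
  fo <- as.data.frame(fo)
  if (!nrow(fo)) return(fo)
  if (!is.null(categories)) {
    cat_ <- setNames(categories(se), seqStrings(se))
    fo <- fo[cat_[fo$sequence] %in% categories, , drop = FALSE]
  }
  lens <- setNames(nchar(seqStrings(se)), seqStrings(se))
  fo$frac <- fo$hit_weight * fo$overlap_nt / lens[fo$sequence]
  fo
}

#' Distribution of mitochondria-matching expression over feature types
#'
#' Aggregates reads over mitochondrial feature types using the
#' equal-split attribution rule: each sequence's reads are divided
#' equally among its minimal-stratum mitochondrial placements, then
#' proportionally to the overlapped bases of each feature (the
#' uncovered remainder goes to \code{intergenic}), so totals are
#' conserved. Reported separately for MT and NUMT classes.
#'
#' @param se a \link{SmallRNAExperiment} after \link{assignFeatures}.
#' @param categories optional restriction, e.g. \code{c("piRNA",
#'   "dual")} for a piRNA-only profile; NULL profiles every
#'   mitochondria-matching sequence.
#' @return data.frame with columns \code{feature_type},
#'   \code{genome_class}, \code{sequences}, \code{reads}.
#' @export
featureDistribution <- function(se, categories = NULL) {
  fo <- .overlapWeights(se, categories)
  if (!nrow(fo))
    return(data.frame(feature_type = character(0),
                      genome_class = character(0),
                      sequences = integer(0), reads = numeric(0)))
  reads <- setNames(as.numeric(rowSums(assay(se, "counts"))),
                    seqStrings(se))
  cls <- setNames(genomeClasses(se), seqStrings(se))
  dt <- data.table::as.data.table(fo)
  dt$w <- reads[dt$sequence] * dt$frac
  dt$genome_class <- cls[dt$sequence]
  out <- dt[, list(sequences = length(unique(sequence)),
                   reads = sum(w)),
            by = c("feature_type", "genome_class")]
  as.data.frame(out[order(feature_type, genome_class)])
}

#' Per-kilobase enrichment of feature types
#'
#' Reads per annotated kilobase for each mitochondrial feature type:
#' the feature-distribution read totals divided by the annotated extent
#' of the type (in kb).
#'
#' @inheritParams featureDistribution
#' @param features the mitochondrial feature annotation (GRanges).
#' @return data.frame with \code{feature_type}, \code{annotated_kb},
#'   \code{reads}, \code{reads_per_kb}.
#' @export
perKbEnrichment <- function(se, features, categories = NULL) {
  fd <- featureDistribution(se, categories)
  if (!nrow(fd))
    return(data.frame(feature_type = character(0),
                      annotated_kb = numeric(0), reads = numeric(0),
                      reads_per_kb = numeric(0)))
  reads <- tapply(fd$reads, fd$feature_type, sum)
  kb <- tapply(GenomicRanges::width(features),
               as.character(features$type), sum) / 1000
  L <- GenomeInfoDb::seqlengths(features)[["chrM"]]
  kb <- c(kb, intergenic = max(L - sum(GenomicRanges::width(
    GenomicRanges::reduce(features, ignore.strand = TRUE))), 1) / 1000)
  types <- names(reads)
  data.frame(feature_type = types,
             annotated_kb = as.numeric(kb[types]),
             reads = as.numeric(reads),
             reads_per_kb = as.numeric(reads) / as.numeric(kb[types]),
             stringsAsFactors = FALSE)
}

#' Strand-resolved feature expression matrix
#'
#' CPM aggregated per (feature, orientation) row and sample column,
#' using the same attribution rule as \link{featureDistribution}. Rows
#' are labelled \code{<feature>|Fwd} and \code{<feature>|Rvr}; both
#' orientations are always present (zero-filled), so a forced
#' orientation shows up as an identically zero row.
#'
#' @inheritParams featureDistribution
#' @param by row resolution: \code{"name"} (individual features) or
#'   \code{"type"}.
#' @return numeric matrix, (feature x orientation) rows by samples.
#' @export
strandMatrix <- function(se, categories = NULL,
                         by = c("name", "type")) {
  by <- match.arg(by)
  fo <- .overlapWeights(se, categories)
  samples <- colnames(se)
  if (!nrow(fo))
    return(matrix(0, 0, length(samples),
                  dimnames = list(character(0), samples)))
  cpm <- assay(se, "cpm")
  key <- if (by == "name") fo$feature_name else fo$feature_type
  lab <- paste0(key, "|", ifelse(fo$orientation == "forward",
                                 "Fwd", "Rvr"))
  allRows <- as.vector(outer(sort(unique(key)), c("Fwd", "Rvr"),
                             function(a, b) paste0(a, "|", b)))
  out <- matrix(0, length(allRows), length(samples),
                dimnames = list(sort(allRows), samples))
  idx <- match(fo$sequence, seqStrings(se))
  for (s in samples) {
    v <- cpm[idx, s] * fo$frac
    agg <- rowsum(v, lab)
    out[rownames(agg), s] <- agg[, 1]
  }
  out
}

#' Principal component analysis of samples
#'
#' Singular value decomposition of the log2(x + 1)-transformed,
#' row-centred matrix. Deterministic up to component sign; the sign is
#' fixed by making each component's largest-magnitude feature loading
#' positive. With identical columns the decomposition is degenerate and
#' all explained variances are zero.
#'
#' @param mat numeric matrix, features x samples (CPM or counts), e.g. a
#'   \link{strandMatrix}.
#' @param nComp number of components returned (default 2).
#' @return list with \code{coordinates} (samples x components),
#'   \code{varianceExplained} (fractions, sum <= 1) and \code{sdev}.
#' @export
pcaSamples <- function(mat, nComp = 2L) {
  if (ncol(mat) < 3L)
    .stopf("pcaSamples needs at least 3 samples (got %d)", ncol(mat))
  if (nComp > ncol(mat))
    .stopf("cannot extract %d components from %d samples", nComp,
           ncol(mat))
  x <- log2(mat + 1)
  xc <- x - rowMeans(x)
  sv <- svd(xc)
  tot <- sum(sv$d^2)
  varExp <- if (tot > 1e-12) sv$d^2 / tot else rep(0, length(sv$d))
  for (j in seq_len(nComp)) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  coords <- sv$v[, seq_len(nComp), drop = FALSE] %*%
    diag(sv$d[seq_len(nComp)], nComp)
  dimnames(coords) <- list(colnames(mat), paste0("PC", seq_len(nComp)))
  list(coordinates = coords,
       varianceExplained = varExp[seq_len(nComp)],
       sdev = sv$d / sqrt(max(ncol(mat) - 1L, 1L)))
}
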