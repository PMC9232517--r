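## 5'-anchored piRNA families: exact-prefix clustering, precursor/mature
## role assignment, the eligibility rule, and per-family mito-nuclear
## communication direction.
##
## A family is a connected component of the exact 5'-prefix relation
## (the shorter sequence must equal a prefix of the longer one) among
## sequences of at least `anchorMin` nt that share at least one genomic
## locus (same genome, contig, strand and 5' coordinate within the
## minimal-mismatch stratum). This replaces greedy identity clustering
## with the family concept itself: same 5' end, variable 3' trimming.

#' Build 5'-anchored piRNA families
#'
#' @param se a \link{SmallRNAExperiment} that has been through
#'   \link{classifySequences} and \link{annotateDb}.
#' @param anchorMin minimal sequence length considered (default 20 nt,
#'   the canonical lower bound of mature piRNA length).
#' @param requireSharedLocus require prefix-related sequences to share a
#'   genomic 5' locus before joining a family (default TRUE).
#' @return a \link{PiRNAFamilySet}. Singleton components are discarded
#'   from the family output (the sequences remain in \code{se}).
#' @export
buildFamilies <- function(se, anchorMin = 20L, requireSharedLocus = TRUE) {
  stopifnot(is(se, "SmallRNAExperiment"))
  rd <- rowData(se)
  if (is.null(rd$genomeClass) || is.null(rd$pirna_ids))
    .stopf("run classifySequences() and annotateDb() before buildFamilies()")
  seqs <- as.character(rd$sequence)
  keep <- nchar(seqs) >= anchorMin
  idx <- which(keep)
  if (!length(idx))
    return(PiRNAFamilySet(.emptyFamilyTable(), .emptyMemberTable()))
  hits <- genomeHits(se)
  locusKeys <- split(paste(hits$genome, hits$contig, hits$strand,
                           hits$start), hits$sequence)
  keysOf <- function(s) locusKeys[[s]]

  anchors <- substr(seqs[idx], 1L, anchorMin)
  parent <- seq_along(idx)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  groups <- split(seq_along(idx), anchors)
  for (g in groups) {
    if (length(g) < 2L) next
    ord <- g[order(nchar(seqs[idx[g]]))]
    for (ii in seq_along(ord)) {
      for (jj in seq_len(ii - 1L)) {
        a <- ord[jj]; b <- ord[ii]  # len(a) <= len(b)
        if (!startsWith(seqs[idx[b]], seqs[idx[a]])) next
        if (requireSharedLocus) {
          ka <- keysOf(seqs[idx[a]]); kb <- keysOf(seqs[idx[b]])
          if (!length(ka) || !length(kb) || !any(ka %in% kb)) next
        }
        ra <- findRoot(a); rb <- findRoot(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  comp <- vapply(seq_along(idx), findRoot, integer(1))
  tbl <- table(comp)
  multi <- names(tbl)[tbl >= 2L]
  if (!length(multi))
    return(PiRNAFamilySet(.emptyFamilyTable(), .emptyMemberTable()))

  counts <- assay(se, "counts")
  famRows <- list()
  memRows <- list()
  ## stable ordering: by representative sequence
  compMembers <- split(idx, comp)[multi]
  reps <- vapply(compMembers, function(m) {
    ln <- nchar(seqs[m])
    cand <- seqs[m][ln == max(ln)]
    sort(cand)[1]
  }, character(1))
  ordC <- order(reps)
  for (ci in seq_along(ordC)) {
    m <- compMembers[[ordC[ci]]]
    fid <- sprintf("F%03d", ci)
    rep_ <- reps[[ordC[ci]]]
    mseq <- seqs[m]
    pir <- as.character(rd$pirna_ids[m])
    cls <- as.character(rd$genomeClass[m])
    isMature <- nzchar(pir)
    matureMax <- if (any(isMature)) max(nchar(mseq)[isMature]) else 0L
    isPrec <- !isMature & nchar(mseq) > matureMax & cls != "UNMAPPED"
    role <- ifelse(isMature, "mature",
                   ifelse(isPrec, "precursor", "none"))
    nElig <- sum(role != "none")
    eligible <- nElig >= 3L && any(role == "precursor") &&
      any(role == "mature") &&
      any(cls[role != "none"] %in% c("NUMT", "MT"))
    dir <- if (!eligible) "unresolved"
      else inferDirection(cls[role == "precursor"],
                          cls[role == "mature"])
    repHits <- hits[hits$sequence == rep_]
    if (nrow(repHits)) {
      repHits <- repHits[order(match(repHits$genome, c("mito", "nuclear")),
                               repHits$contig, repHits$start)]
      anchor <- repHits[1L]
    } else anchor <- NULL
    famRows[[ci]] <- data.frame(
      family_id = fid, representative = rep_,
      n_members = length(m), n_counted = nElig,
      eligible = eligible, direction = dir,
      anchor_genome = if (is.null(anchor)) NA_character_ else
        anchor$genome,
      anchor_contig = if (is.null(anchor)) NA_character_ else
        anchor$contig,
      anchor_strand = if (is.null(anchor)) NA_character_ else
        anchor$strand,
      anchor_start = if (is.null(anchor)) NA_integer_ else anchor$start,
      stringsAsFactors = FALSE)
    memRows[[ci]] <- data.frame(
      family_id = fid, sequence = mseq, length = nchar(mseq),
      role = role, genome_class = cls,
      pirna_ids = pir, pirna_multi = as.logical(rd$pirna_multi[m]),
      mirna_ids = as.character(rd$mirna_ids[m]),
      reads_total = as.integer(rowSums(counts[m, , drop = FALSE])),
      stringsAsFactors = FALSE)
  }
  PiRNAFamilySet(do.call(rbind, famRows), do.call(rbind, memRows))
}

.emptyFamilyTable <- function() {
  data.frame(family_id = character(0), representative = character(0),
             n_members = integer(0), n_counted = integer(0),
             eligible = logical(0), direction = character(0),
             anchor_genome = character(0), anchor_contig = character(0),
             anchor_strand = character(0), anchor_start = integer(0),
             stringsAsFactors = FALSE)
}

.emptyMemberTable <- function() {
  data.frame(family_id = character(0), sequence = character(0),
             length = integer(0), role = character(0),
             genome_class = character(0), pirna_ids = character(0),
             pirna_multi = logical(0), mirna_ids = character(0),
             reads_total = integer(0), stringsAsFactors = FALSE)
}

#' Infer the mito-nuclear communication direction of a family
#'
#' A pure function of the precursor and mature genome classes:
#' \describe{
#'   \item{retrograde}{every precursor is exclusively mitochondrial (MT)
#'     and at least one mature also matches the nuclear genome (NUMT):
#'     the precursor is transcribed from mtDNA and the processed piRNA
#'     has a nuclear-compatible sequence.}
#'   \item{anterograde}{every precursor is exclusively nuclear (NU) and
#'     at least one mature matches the mitochondrial genome (NUMT or
#'     MT).}
#'   \item{self}{precursors and matures are confined to a single genome
#'     (all MT, or all NU).}
#'   \item{unresolved}{any other combination.}
#' }
#'
#' @param precursorClasses character vector of precursor genome classes.
#' @param matureClasses character vector of mature genome classes.
#' @return one of \code{"retrograde"}, \code{"anterograde"},
#'   \code{"self"}, \code{"unresolved"}.
#' @export
#' @examples
#' inferDirection("MT", c("NUMT", "NUMT", "MT"))   # retrograde
#' inferDirection("NU", "NUMT")                    # anterograde
#' inferDirection("MT", "MT")                      # self
inferDirection <- function(precursorClasses, matureClasses) {
  P <- unique(precursorClasses)
  M <- unique(matureClasses)
  if (!length(P) || !length(M)) return("unresolved")
  if (all(P == "MT") && any(M == "NUMT")) return("retrograde")
  if (all(P == "NU") && any(M %in% c("NUMT", "MT")))
    return("anterograde")
  allCls <- c(P, M)
  if (all(allCls == "MT") || all(allCls == "NU")) return("self")
  "unresolved"
}

#' Proportions of communication directions across eligible families
#'
#' Counts and percentages of eligible, resolved families per direction
#' label; percentages are over \{retrograde, anterograde, self\} and sum
#' to 100; unresolved families are reported separately.
#'
#' @param x a \link{PiRNAFamilySet}.
#' @param ... unused.
#' @return list with \code{counts}, \code{percentages},
#'   \code{denominator}, \code{unresolved} and \code{empty} (TRUE when
#'   no eligible family exists).
#' @rdname directionProportions
#' @export
setMethod("directionProportions", "PiRNAFamilySet", function(x, ...) {
  f <- familyTable(x)
  elig <- f[f$eligible, , drop = FALSE]
  labs <- c("retrograde", "anterograde", "self")
  resolved <- elig[elig$direction %in% labs, , drop = FALSE]
  counts <- setNames(integer(3), labs)
  tb <- table(factor(resolved$direction, levels = labs))
  counts[names(tb)] <- as.integer(tb)
  denom <- sum(counts)
  pct <- if (denom > 0) 100 * counts / denom else setNames(rep(NA_real_, 3),
                                                           labs)
  list(counts = counts, percentages = pct, denominator = denom,
       unresolved = sum(elig$direction == "unresolved"),
       empty = nrow(elig) == 0L)
})

#' Read-weighted length distribution by genome class and role
#'
#' The histogram of sequence length for mitochondria-matching sequences
#' (MT or NUMT), weighted by total read count and stratified by class
#' and by family role — the surface on which exclusively mitochondrial
#' precursors separate from NUMT-type matures.
#'
#' @param se a classified \link{SmallRNAExperiment}.
#' @param families optional \link{PiRNAFamilySet} supplying roles;
#'   sequences outside families get role \code{"none"}.
#' @return data.frame with columns \code{length}, \code{genome_class},
#'   \code{role}, \code{reads}, \code{sequences}.
#' @export
lengthByClass <- function(se, families = NULL) {
  cls <- genomeClasses(se)
  keep <- cls %in% c("MT", "NUMT")
  if (!any(keep))
    return(data.frame(length = integer(0), genome_class = character(0),
                      role = character(0), reads = numeric(0),
                      sequences = integer(0)))
  seqs <- seqStrings(se)[keep]
  reads <- rowSums(assay(se, "counts"))[keep]
  role <- rep("none", length(seqs))
  if (!is.null(families)) {
    mt <- memberTable(families)
    mIdx <- match(seqs, mt$sequence)
    role[!is.na(mIdx)] <- as.character(mt$role[mIdx[!is.na(mIdx)]])
  }
  dt <- data.table::data.table(length = nchar(seqs),
                               genome_class = cls[keep], role = role,
                               reads = as.numeric(reads))
  out <- dt[, list(reads = sum(reads), sequences = .N),
            by = c("length", "genome_class", "role")]
  out <- as.data.frame(out[order(length, genome_class, role)])
  out
}
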