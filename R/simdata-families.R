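## Planting of piRNA families with known mito-nuclear communication
## direction. A family is a precursor (longest ladder length) plus its
## 5'-anchored prefixes at the remaining ladder lengths; the locus is
## chosen so that the genome classes of precursor and matures realise the
## requested direction label:
##   retrograde  - precursor transcribed from mtDNA only; matures short
##                 enough to fall inside a NUMT, hence present in both
##                 genomes (NUMT class);
##   anterograde - precursor anchored in a nuclear NUMT copy, extending
##                 into unique nuclear flank (NU only); matures inside the
##                 copy, hence also matching the mitochondrial source;
##   self        - the whole ladder confined to one genome (here: mtDNA).

## Majority-overlap mitochondrial feature for a read locus given its 5'
## coordinate, length and strand; circular-aware. Returns name/type/strand
## of the best-overlapping feature, or intergenic.
#' @importFrom GenomicRanges findOverlaps pintersect width start end
#' @importFrom S4Vectors queryHits subjectHits
.locusFeature <- function(start5, len, strand, features, L) {
  if (strand == "+") { a <- start5; b <- start5 + len - 1L }
  else { a <- start5 - len + 1L; b <- start5 }
  pieces <- .circularPieces(a, b, L)
  gr <- GRanges("chrM", IRanges(pieces$start, pieces$end))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(features)
  ov <- findOverlaps(gr, features)
  if (!length(ov))
    return(list(name = "intergenic", type = "intergenic", fstrand = "*",
                overlap = 0L))
  w <- width(pintersect(gr[queryHits(ov)], features[subjectHits(ov)]))
  agg <- tapply(w, subjectHits(ov), sum)
  best <- as.integer(names(agg)[which.max(agg)])
  list(name = as.character(features$name[best]),
       type = as.character(features$type[best]),
       fstrand = as.character(GenomicRanges::strand(features)[best]),
       overlap = as.integer(max(agg)))
}

## Split a possibly out-of-bounds circular interval into linear pieces.
.circularPieces <- function(a, b, L) {
  if (a >= 1L && b <= L) return(list(start = a, end = b))
  if (a < 1L) return(list(start = c(a + L, 1L), end = c(L, b)))
  list(start = c(a, 1L), end = c(L, b - L))  # b > L
}

.orientationVs <- function(readStrand, featureStrand) {
  base <- if (featureStrand %in% c("+", "-")) featureStrand else "+"
  if (readStrand == base) "forward" else "reverse"
}

#' Plant piRNA families and build the reference sets
#'
#' Chooses, for each family, a genomic locus whose NU/MT/NUMT composition
#' realises the requested direction label (see the package vignette), then
#' derives the member ladder by 3' trimming. The piRNA reference set
#' receives every mature-length member (never the precursor) plus random
#' decoys certified absent from both genomes; the miRNA reference set
#' receives decoys plus, optionally, one duplicated mature creating a dual
#' miRNA/piRNA case, and optionally one near-duplicate piRNA entry so a
#' mature matches multiple piRNA ids.
#'
#' @param cfg a \link{SimConfig}.
#' @param mito result of \link{genMitoGenome}.
#' @param nuclear result of \link{genNuclearGenome}.
#' @return list with \code{members} (data.frame: one row per planted
#'   sequence with its truth), \code{pirnaDb} and \code{mirnaDb} (named
#'   character vectors id -> sequence), and \code{directionCounts}.
#' @export
plantFamilies <- function(cfg, mito, nuclear) {
  stopifnot(is(cfg, "SimConfig"))
  mtSeq <- unname(mito$genome[[1]])
  L <- nchar(mtSeq)
  contigs <- nuclear$contigs
  numts <- nuclear$numts
  ladder <- cfg@familyLadder
  prec <- ladder[1]
  matures <- ladder[-1]
  maxMat <- max(matures)
  .withSeed(cfg@seed, "families", {
    mixOrd <- c("retrograde", "anterograde", "self")
    cnt <- .apportion(cfg@nFamilies, cfg@directionMix[mixOrd])
    directions <- rep(mixOrd, cnt)
    usedIv <- data.frame(genome = character(0), start = integer(0),
                         end = integer(0))
    prefixes <- character(0)
    members <- list()
    usedNumt <- integer(0)   # one planted family per NUMT row
    extraKeys <- character(0)  # genomic 5' keys blocked for background loci
    overlapsUsed <- function(genome, a, b) {
      any(usedIv$genome == genome & !(b < usedIv$start | a > usedIv$end))
    }
    nucAbsent <- function(s) {
      all(vapply(contigs, function(ct)
        .minHammingBothStrands(s, ct) >= 2L, logical(1)))
    }
    dloopSrc <- if (nrow(numts)) {
      dl <- mito$features[mito$features$type == "D-loop"]
      which(numts$mito_start >= start(dl) & numts$mito_end <= end(dl))
    } else integer(0)

    addFamily <- function(fid, dir, rows) {
      stopifnot(nrow(rows) == length(ladder))
      members[[fid]] <<- rows
      usedIv <<- rbind(usedIv, data.frame(
        genome = rows$anchor_genome[1],
        start = min(rows$iv_start), end = max(rows$iv_end)))
      prefixes <<- c(prefixes, substr(rows$sequence[1], 1L, 20L))
    }

    mkRows <- function(fid, dir, seqs, roles, classes, genome, strand,
                       anchor5, mitoStrand, mitoAnchor5, ivs, ive) {
      featInfo <- lapply(seq_along(seqs), function(j) {
        if (is.na(mitoStrand[j]))
          return(list(name = NA_character_, type = NA_character_,
                      fstrand = NA_character_))
        .locusFeature(mitoAnchor5[j], nchar(seqs[j]), mitoStrand[j],
                      mito$features, L)
      })
      data.frame(
        family_id = fid, direction = dir,
        role = roles, sequence = seqs, member_len = nchar(seqs),
        true_class = classes, anchor_genome = genome, strand = strand,
        anchor5 = anchor5, mito_strand = mitoStrand,
        mito_anchor5 = mitoAnchor5,
        feature_name = vapply(featInfo, `[[`, character(1), "name"),
        feature_type = vapply(featInfo, `[[`, character(1), "type"),
        orientation = vapply(seq_along(seqs), function(j) {
          if (is.na(mitoStrand[j])) return(NA_character_)
          .orientationVs(mitoStrand[j], featInfo[[j]]$fstrand)
        }, character(1)),
        iv_start = ivs, iv_end = ive, stringsAsFactors = FALSE)
    }

    for (i in seq_along(directions)) {
      dir <- directions[i]
      fid <- sprintf("fam%02d", i)
      placed <- FALSE
      if (dir == "retrograde") {
        if (!nrow(numts))
          .stopf("retrograde families require NUMTs (n_numts = 0)")
        cand <- setdiff(sample(nrow(numts)), usedNumt)
        if (i == 1L && length(dloopSrc))
          cand <- c(setdiff(dloopSrc, usedNumt), setdiff(cand, dloopSrc))
        for (j in cand) {
          row <- numts[j, ]
          ms <- row$mito_start; me <- row$mito_end
          useMinus <- j %in% dloopSrc
          anchors <- if (useMinus) {
            lo <- ms + maxMat - 1L; hi <- min(me, ms + prec - 2L)
            if (lo > hi) integer(0) else (lo:hi)[lo:hi - prec + 1L >= 1L]
          } else {
            lo <- max(ms, me - prec + 2L); hi <- me - maxMat + 1L
            if (lo > hi) integer(0) else (lo:hi)[lo:hi + prec - 1L <= L]
          }
          if (!length(anchors)) next
          for (a in .shuffle(anchors)[seq_len(min(30L, length(anchors)))]) {
            if (useMinus) {
              wS <- a - prec + 1L; wE <- a
              matWin <- c(a - maxMat + 1L, a)
            } else {
              wS <- a; wE <- a + prec - 1L
              matWin <- c(a, a + maxMat - 1L)
            }
            if (overlapsUsed("chrM", wS, wE)) next
            if (.subsInMitoWindow(row, matWin[1], matWin[2]) > 0L) next
            strand <- if (useMinus) "-" else "+"
            seqs <- vapply(ladder, function(l) {
              if (useMinus) .revcomp(substr(mtSeq, a - l + 1L, a))
              else substr(mtSeq, a, a + l - 1L)
            }, character(1))
            if (substr(seqs[1], 1, 20) %in% prefixes) next
            if (!nucAbsent(seqs[1])) next
            addFamily(fid, dir, mkRows(
              fid, dir, seqs,
              c("precursor", rep("mature", length(matures))),
              c("MT", rep("NUMT", length(matures))),
              "chrM", strand, rep(a, length(ladder)),
              rep(strand, length(ladder)), rep(a, length(ladder)),
              rep(wS, length(ladder)), rep(wE, length(ladder))))
            usedNumt <- c(usedNumt, j)
            nucPos <- if (row$strand == "+")
              row$copy_start + (a - ms) else row$copy_start + (me - a)
            extraKeys <- c(extraKeys, paste0(row$contig, ":", nucPos))
            placed <- TRUE; break
          }
          if (placed) break
        }
      } else if (dir == "anterograde") {
        if (!nrow(numts))
          .stopf("anterograde families require NUMTs (n_numts = 0)")
        ## D-loop-sourced copies are excluded: their matures would map to
        ## the D-loop in the forward sense, which the study design forbids
        ## (all D-loop reads are reverse-oriented).
        for (j in .shuffle(setdiff(seq_len(nrow(numts)),
                                   c(dloopSrc, usedNumt)))) {
          row <- numts[j, ]
          ns <- row$copy_start; ne <- row$copy_end
          ct <- row$contig
          lo <- max(ns, ne - prec + 2L); hi <- ne - maxMat + 1L
          if (lo > hi) next
          anchors <- (lo:hi)[lo:hi + prec - 1L <= nchar(contigs[[ct]])]
          if (!length(anchors)) next
          for (a in .shuffle(anchors)[seq_len(min(30L, length(anchors)))]) {
            if (overlapsUsed(ct, a, a + prec - 1L)) next
            if (.subsInCopyWindow(row, a, a + maxMat - 1L) > 0L) next
            seqs <- vapply(ladder, function(l)
              substr(contigs[[ct]], a, a + l - 1L), character(1))
            if (substr(seqs[1], 1, 20) %in% prefixes) next
            if (.minHammingBothStrands(seqs[1], mtSeq, circular = TRUE)
                < 2L) next
            mitoStrand <- if (row$strand == "+") "+" else "-"
            m5 <- if (row$strand == "+") row$mito_start + (a - ns)
                  else row$mito_end - (a - ns)
            addFamily(fid, dir, mkRows(
              fid, dir, seqs,
              c("precursor", rep("mature", length(matures))),
              c("NU", rep("NUMT", length(matures))),
              ct, "+", rep(a, length(ladder)),
              c(NA_character_, rep(mitoStrand, length(matures))),
              c(NA_integer_, rep(m5, length(matures))),
              rep(a, length(ladder)),
              rep(a + prec - 1L, length(ladder))))
            usedNumt <- c(usedNumt, j)
            placed <- TRUE; break
          }
          if (placed) break
        }
      } else {  # self: whole ladder confined to the mitochondrial genome
        dl <- mito$features[mito$features$type == "D-loop"]
        for (try in seq_len(2000L)) {
          a <- .sampleOne(seq_len(L - prec + 1L))
          wE <- a + prec - 1L
          if (nrow(numts) &&
              any(!(wE < numts$mito_start | a > numts$mito_end))) next
          ## forward-stranded; keep out of the D-loop (reverse-only region)
          if (length(dl) && !(wE < start(dl) || a > end(dl))) next
          if (overlapsUsed("chrM", a, wE)) next
          seqs <- vapply(ladder, function(l)
            substr(mtSeq, a, a + l - 1L), character(1))
          if (substr(seqs[1], 1, 20) %in% prefixes) next
          if (!all(vapply(seqs, nucAbsent, logical(1)))) next
          addFamily(fid, dir, mkRows(
            fid, dir, seqs,
            c("precursor", rep("mature", length(matures))),
            rep("MT", length(ladder)),
            "chrM", "+", rep(a, length(ladder)),
            rep("+", length(ladder)), rep(a, length(ladder)),
            rep(a, length(ladder)), rep(wE, length(ladder))))
          placed <- TRUE; break
        }
      }
      if (!placed)
        .stopf("retry budget exceeded: no locus available to plant a %s family",
               dir)
    }
    members <- do.call(rbind, members)
    rownames(members) <- NULL

    ## reference sets
    matRows <- members[members$role == "mature", ]
    pirnaDb <- setNames(matRows$sequence,
                        sprintf("piR-sim-%07d", seq_len(nrow(matRows))))
    nextPir <- nrow(matRows) + 1L
    if (cfg@plantMulti && nrow(matRows)) {
      ## a redundant entry (same sequence, second id), as piRNA databases
      ## carry: the mature then matches multiple ids within the minimal
      ## stratum and is flagged with '*'
      pirnaDb <- c(pirnaDb,
                   setNames(matRows$sequence[1],
                            sprintf("piR-sim-%07d", nextPir)))
      nextPir <- nextPir + 1L
    }
    genomeScan <- function(s) {
      d <- .minHammingBothStrands(s, mtSeq, circular = TRUE)
      if (d < 2L) return(FALSE)
      all(vapply(contigs, function(ct)
        .minHammingBothStrands(s, ct) >= 2L, logical(1)))
    }
    mkDecoys <- function(n, lens, existing) {
      out <- character(0)
      while (length(out) < n) {
        s <- .randDNA(sample(lens, 1L))
        if (s %in% existing || s %in% out) next
        if (!genomeScan(s)) next
        out <- c(out, s)
      }
      out
    }
    pirDecoys <- mkDecoys(cfg@decoyDbEntries, 24:32, pirnaDb)
    pirnaDb <- c(pirnaDb, setNames(
      pirDecoys, sprintf("piR-sim-%07d", nextPir + seq_along(pirDecoys) - 1L)))
    mirDecoys <- mkDecoys(cfg@decoyDbEntries, 21:23, pirnaDb)
    mirnaDb <- setNames(mirDecoys,
                        sprintf("mmu-mir-sim%d", seq_along(mirDecoys)))
    if (cfg@plantDual && nrow(matRows)) {
      dual <- matRows$sequence[nrow(matRows)]
      mirnaDb <- c(mirnaDb,
                   setNames(dual, sprintf("mmu-mir-sim%d",
                                          length(mirnaDb) + 1L)))
    }
    list(members = members, pirnaDb = pirnaDb, mirnaDb = mirnaDb,
         directionCounts = setNames(cnt, mixOrd),
         blockedKeys = extraKeys)
  })
}
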