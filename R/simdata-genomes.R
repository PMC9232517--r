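## Synthetic genome construction: a toy circular mitochondrial genome with
## a realistic feature complement (tRNAs, rRNAs, protein-coding genes, a
## replication origin and the regulatory D-loop pinned at the
## high-coordinate end), and nuclear contigs carrying NUMT insertions.

.MT_TRNA_NAMES <- c("Phe", "Val", "LeuTAA", "Ile", "Gln", "Met", "Trp",
                    "Ala", "Asn", "Cys", "Tyr", "SerTGA", "Asp", "Lys",
                    "Gly", "Arg", "His", "SerGCT", "LeuTAG", "Glu", "Thr",
                    "Pro")
.MT_CDS_NAMES <- c("ND1", "ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3",
                   "ND3", "ND4L", "ND4", "ND5", "ND6", "CYTB")

## Largest-remainder apportionment of n into proportions p.
.apportion <- function(n, p) {
  raw <- n * p / sum(p)
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  as.integer(out)
}

#' Generate the synthetic mitochondrial genome and its feature annotation
#'
#' Builds a random circular genome (materialised as a linear sequence; the
#' mapper restores circularity) with non-overlapping features laid out in
#' random order with random intergenic gaps: \code{nRrna} rRNAs (forward
#' strand), \code{nTrna} tRNAs (~70 nt, mixed strands), \code{nCds}
#' protein-coding genes (one on the reverse strand, like ND6), one
#' replication origin, and exactly one D-loop occupying the
#' high-coordinate end of the genome. Coordinates are 1-based inclusive.
#'
#' @param cfg a \link{SimConfig}.
#' @return list with \code{genome} (named character, \code{chrM}) and
#'   \code{features} (a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{name} and \code{type}).
#' @export
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths<- isCircular<-
#' @examples
#' mt <- genMitoGenome(SimConfig(seed = 7L))
#' table(as.character(mt$features$type))
genMitoGenome <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  .withSeed(cfg@seed, "mito", {
    L <- cfg@mitoLength
    dloopLen <- min(880L, max(200L, as.integer(round(0.054 * L))))
    oriLen <- 32L
    rrnaLens <- if (cfg@nRrna == 2L) c(950L, 1580L) else
      rep(1000L, cfg@nRrna)
    trnaLens <- sample(68:72, cfg@nTrna, replace = TRUE)
    budget <- L - dloopLen - oriLen - sum(rrnaLens) - sum(trnaLens)
    minCds <- 200L
    if (budget < cfg@nCds * minCds + 50L)
      .stopf(paste("mitochondrial genome of %d nt cannot hold %d rRNAs,",
                   "%d tRNAs, %d CDS blocks and the D-loop without",
                   "overlap"), L, cfg@nRrna, cfg@nTrna, cfg@nCds)
    w <- runif(cfg@nCds, 0.3, 1.8)
    cdsLens <- pmax(minCds,
                    as.integer(floor(0.85 * budget * w / sum(w))))
    trnaNames <- if (cfg@nTrna <= length(.MT_TRNA_NAMES))
      paste0("tRNA-", .MT_TRNA_NAMES[seq_len(cfg@nTrna)])
    else paste0("tRNA-", c(.MT_TRNA_NAMES,
      paste0("X", seq_len(cfg@nTrna - length(.MT_TRNA_NAMES)))))
    rrnaNames <- if (cfg@nRrna == 2L) c("12S-rRNA", "16S-rRNA") else
      paste0("rRNA-", seq_len(cfg@nRrna))
    cdsNames <- if (cfg@nCds <= length(.MT_CDS_NAMES))
      .MT_CDS_NAMES[seq_len(cfg@nCds)]
    else c(.MT_CDS_NAMES,
           paste0("CDS", seq_len(cfg@nCds - length(.MT_CDS_NAMES))))
    trnaStrand <- sample(rep(c("+", "-"),
                             c(cfg@nTrna - cfg@nTrna %/% 3,
                               cfg@nTrna %/% 3)))
    cdsStrand <- rep("+", cfg@nCds)
    if (cfg@nCds >= 2L) cdsStrand[sample(cfg@nCds, 1L)] <- "-"
    feat <- data.frame(
      name = c(rrnaNames, trnaNames, cdsNames, "OriL"),
      type = c(rep("rRNA", cfg@nRrna), rep("tRNA", cfg@nTrna),
               rep("CDS", cfg@nCds), "origin"),
      len = c(rrnaLens, trnaLens, cdsLens, oriLen),
      strand = c(rep("+", cfg@nRrna), trnaStrand, cdsStrand, "*"),
      stringsAsFactors = FALSE)
    feat <- feat[sample(nrow(feat)), , drop = FALSE]
    slack <- L - dloopLen - sum(feat$len)
    stopifnot(slack >= 0L)
    gapW <- runif(nrow(feat) + 1L)
    gaps <- .apportion(slack, gapW)
    pos <- 1L
    starts <- integer(nrow(feat))
    for (i in seq_len(nrow(feat))) {
      pos <- pos + gaps[i]
      starts[i] <- pos
      pos <- pos + feat$len[i]
    }
    feat$start <- starts
    feat$end <- starts + feat$len - 1L
    stopifnot(max(feat$end) <= L - dloopLen)
    feat <- rbind(feat, data.frame(name = "D-loop", type = "D-loop",
                                   len = dloopLen,
                                   strand = "*",
                                   start = L - dloopLen + 1L, end = L))
    genome <- .randDNA(L)
    gr <- GRanges("chrM", IRanges(feat$start, feat$end),
                  strand = feat$strand, name = feat$name, type = feat$type)
    seqlengths(gr) <- c(chrM = L)
    isCircular(gr) <- TRUE
    list(genome = c(chrM = genome), features = gr)
  })
}

#' Generate synthetic nuclear contigs carrying NUMT insertions
#'
#' Random nuclear contigs into which \code{nNumts} fragments of the
#' mitochondrial genome are copied (random source interval, random strand,
#' random insertion point) with per-base substitution probability
#' \code{numtDivergence}. The first NUMT sources from the D-loop so a
#' D-loop-anchored family with nuclear-compatible matures can be planted.
#' Source intervals are pairwise disjoint.
#'
#' @param cfg a \link{SimConfig}.
#' @param mito the mitochondrial genome and features, as returned by
#'   \link{genMitoGenome}.
#' @return list with \code{contigs} (named character) and \code{numts},
#'   a data.frame with one row per insertion: source interval
#'   (\code{mito_start}, \code{mito_end}), destination (\code{contig},
#'   \code{copy_start}, \code{copy_end}), \code{strand}, \code{n_subs}
#'   and \code{sub_positions} (1-based offsets of substitutions within
#'   the inserted copy, comma-separated).
#' @export
#' @examples
#' cfg <- SimConfig(seed = 7L)
#' mt <- genMitoGenome(cfg)
#' nuc <- genNuclearGenome(cfg, mt)
#' nrow(nuc$numts)
genNuclearGenome <- function(cfg, mito) {
  stopifnot(is(cfg, "SimConfig"), nzchar(mito$genome[[1]]))
  mtSeq <- unname(mito$genome[[1]])
  L <- nchar(mtSeq)
  .withSeed(cfg@seed, "nuclear", {
    contigs <- vapply(cfg@nuclearContigs, .randDNA, character(1))
    names(contigs) <- names(cfg@nuclearContigs)
    n <- cfg@nNumts
    if (n == 0L)
      return(list(contigs = contigs, numts = .emptyNumtTable()))
    if (cfg@numtLengthRange[2] > min(nchar(contigs)))
      .stopf("NUMT length range (max %d) exceeds shortest contig (%d nt)",
             cfg@numtLengthRange[2], min(nchar(contigs)))
    ## disjoint source intervals (gap >= 80 nt), first one inside D-loop
    feats <- mito$features
    dl <- feats[feats$type == "D-loop"]
    srcs <- matrix(0L, n, 2)
    for (i in seq_len(n)) {
      for (try in seq_len(2000L)) {
        len <- .sampleOne(cfg@numtLengthRange[1]:cfg@numtLengthRange[2])
        if (i == 1L && length(dl) &&
            GenomicRanges::width(dl) > cfg@numtLengthRange[1] + 2L) {
          len <- min(len, GenomicRanges::width(dl) - 2L)
          s <- .sampleOne(GenomicRanges::start(dl):
                            (GenomicRanges::end(dl) - len + 1L))
        } else {
          s <- .sampleOne(seq_len(L - len + 1L))
        }
        e <- s + len - 1L
        ok <- all(e < srcs[seq_len(i - 1L), 1] - 80L |
                    s > srcs[seq_len(i - 1L), 2] + 80L)
        if (ok) { srcs[i, ] <- c(s, e); break }
        if (try == 2000L)
          .stopf("could not place %d disjoint NUMT source intervals", n)
      }
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    destContig <- sample(names(contigs), n, replace = TRUE,
                         prob = nchar(contigs))
    insPoint <- vapply(destContig, function(ct)
      sample(nchar(contigs[[ct]]) - 1L, 1L), integer(1))
    frag <- substr(rep(mtSeq, n), srcs[, 1], srcs[, 2])
    frag[strand == "-"] <- .revcomp(frag[strand == "-"])
    subPos <- vector("list", n)
    for (i in seq_len(n)) {
      fl <- nchar(frag[i])
      hit <- which(runif(fl) < cfg@numtDivergence)
      if (length(hit)) {
        chars <- strsplit(frag[i], "")[[1]]
        chars[hit] <- vapply(chars[hit], function(b)
          sample(setdiff(DNA_BASES4, b), 1L), character(1))
        frag[i] <- paste(chars, collapse = "")
      }
      subPos[[i]] <- hit
    }
    ## splice copies in, per contig, left to right, tracking final coords
    numts <- data.frame(
      numt_id = paste0("numt", seq_len(n)),
      mito_start = srcs[, 1], mito_end = srcs[, 2],
      contig = destContig, insertion_point = insPoint,
      copy_start = NA_integer_, copy_end = NA_integer_,
      strand = strand, n_subs = lengths(subPos),
      sub_positions = vapply(subPos, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE)
    for (ct in names(contigs)) {
      idx <- which(numts$contig == ct)
      if (!length(idx)) next
      idx <- idx[order(numts$insertion_point[idx])]
      offset <- 0L
      seqparts <- character(0)
      prev <- 0L
      base <- contigs[[ct]]
      for (i in idx) {
        ip <- numts$insertion_point[i]
        seqparts <- c(seqparts, substr(base, prev + 1L, ip), frag[i])
        numts$copy_start[i] <- ip + offset + 1L
        numts$copy_end[i] <- ip + offset + nchar(frag[i])
        offset <- offset + nchar(frag[i])
        prev <- ip
      }
      seqparts <- c(seqparts, substr(base, prev + 1L, nchar(base)))
      contigs[[ct]] <- paste(seqparts, collapse = "")
    }
    list(contigs = contigs, numts = numts)
  })
}

.emptyNumtTable <- function() {
  data.frame(numt_id = character(0), mito_start = integer(0),
             mito_end = integer(0), contig = character(0),
             insertion_point = integer(0), copy_start = integer(0),
             copy_end = integer(0), strand = character(0),
             n_subs = integer(0), sub_positions = character(0),
             stringsAsFactors = FALSE)
}

## Number of recorded substitutions of NUMT row `row` falling inside the
## copy region that corresponds to mito interval [a, b].
.subsInMitoWindow <- function(row, a, b) {
  if (row$n_subs == 0L) return(0L)
  subs <- as.integer(strsplit(row$sub_positions, ",")[[1]])
  if (row$strand == "+") {
    lo <- a - row$mito_start + 1L
    hi <- b - row$mito_start + 1L
  } else {
    lo <- row$mito_end - b + 1L
    hi <- row$mito_end - a + 1L
  }
  sum(subs >= lo & subs <= hi)
}

## Number of recorded substitutions inside copy-coordinate window [a, b].
.subsInCopyWindow <- function(row, a, b) {
  if (row$n_subs == 0L) return(0L)
  subs <- as.integer(strsplit(row$sub_positions, ",")[[1]])
  lo <- a - row$copy_start + 1L
  hi <- b - row$copy_start + 1L
  sum(subs >= lo & subs <= hi)
}
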