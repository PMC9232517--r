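## Read simulation: per-sample multinomial sampling over a pool of
## expressed entities (planted family members, background genomic loci,
## unmappable noise), with a per-read binomial first-position adenine bias
## on background reads and per-read antisense emission for D-loop reads.

.substrCirc <- function(x, a, len) {
  L <- nchar(x)
  b <- a + len - 1L
  if (b <= L) return(substr(x, a, b))
  paste0(substr(x, a, L), substr(x, 1L, b - L))
}

## Sample background loci for one genome. Returns a data.frame of loci
## with sense sequence, 5' coordinate, strand, truth class and feature.
.sampleBackgroundLoci <- function(n, genomeName, genomeSeq, circular,
                                  features, numts, usedKeys, aClass,
                                  forceDloop = rep(FALSE, n),
                                  dloopRange = NULL,
                                  dloopReverseFraction = 0) {
  L <- nchar(genomeSeq)
  out <- vector("list", n)
  dl <- if (!is.null(features)) features[features$type == "D-loop"] else
    GRanges()
  ## NUMT copies whose source overlaps the D-loop: nuclear background
  ## loci must avoid them — their mitochondrial placements would show up
  ## in the D-loop in the forward sense, and the study design has every
  ## D-loop read antisense.
  dlCopies <- if (!circular && !is.null(dloopRange) && nrow(numts))
    which(!(numts$mito_end < dloopRange[1] |
              numts$mito_start > dloopRange[2]))
  else integer(0)
  overlapsDloopCirc <- function(s, e) {
    if (circular && length(dl)) {
      pieces <- .circularPieces(s, e, L)
      any(pieces$end >= start(dl) & pieces$start <= end(dl))
    } else FALSE
  }
  for (i in seq_len(n)) {
    done <- FALSE
    for (try in seq_len(1000L)) {
      len <- .sampleOne(20:35)
      if (forceDloop[i] && length(dl)) {
        s <- .sampleOne(start(dl):(end(dl) - len + 1L))
      } else if (circular) {
        s <- .sampleOne(seq_len(L))
      } else {
        s <- .sampleOne(seq_len(L - len + 1L))
      }
      e <- s + len - 1L
      inDloop <- overlapsDloopCirc(s, e)
      if (!is.null(features)) {
        fi <- .locusFeature(s, len, "+", features, L)
        ## any D-loop overlap puts the locus under the antisense rule:
        ## the locus emits antisense to the forward reference strand
        ## with probability dloopReverseFraction, and the first-position
        ## bias applies to the emitted sequence
        strand <- if (inDloop) {
          if (runif(1) < dloopReverseFraction) "-" else "+"
        } else if (fi$fstrand %in% c("+", "-")) fi$fstrand else "+"
      } else {
        fi <- list(name = NA_character_, type = NA_character_,
                   fstrand = NA_character_)
        strand <- "+"
      }
      start5 <- if (strand == "+") s else ((e - 1L) %% L) + 1L
      key <- paste0(genomeName, ":", start5)
      if (key %in% usedKeys) next
      fwdSeq <- .substrCirc(genomeSeq, s, len)
      senseSeq <- if (strand == "+") fwdSeq else .revcomp(fwdSeq)
      first <- substr(senseSeq, 1L, 1L)
      if (aClass[i] != (first == "A")) next
      ## truth class from NUMT bookkeeping. Windows straddling a
      ## source/copy boundary are rejected: a short overhang can match
      ## the other genome within the mismatch budget, which would make
      ## the bookkeeping class unreliable.
      if (circular) {
        ovl <- which(!(numts$mito_end < s | numts$mito_start > e))
        contained <- e <= L & numts$mito_start <= s & numts$mito_end >= e
        if (length(ovl) && !any(contained[ovl])) next
        cls <- if (length(ovl) &&
                   any(vapply(ovl, function(j)
                     .subsInMitoWindow(numts[j, ], s, e) <= 1L,
                     logical(1))))
          "NUMT" else "MT"
      } else {
        here <- numts$contig == genomeName
        ovl <- which(here & !(numts$copy_end < s | numts$copy_start > e))
        if (any(ovl %in% dlCopies)) next
        contained <- numts$copy_start <= s & numts$copy_end >= e
        if (length(ovl) && !any(contained[ovl])) next
        cls <- if (length(ovl) &&
                   any(vapply(ovl, function(j)
                     .subsInCopyWindow(numts[j, ], s, e) <= 1L,
                     logical(1))))
          "NUMT" else "NU"
      }
      ori <- if (!is.null(features))
        .orientationVs(strand, fi$fstrand) else NA_character_
      out[[i]] <- data.frame(
        sequence = senseSeq, genome = genomeName, strand = strand,
        anchor5 = start5, true_class = cls, feature_name = fi$name,
        feature_type = fi$type, feature_strand = fi$fstrand,
        orientation = ori, dloop = inDloop, stringsAsFactors = FALSE)
      usedKeys <- c(usedKeys, key)
      done <- TRUE
      break
    }
    if (!done)
      .stopf("could not place background locus %d in %s", i, genomeName)
  }
  list(loci = do.call(rbind, out), usedKeys = usedKeys)
}

#' Simulate small RNA reads and the ground-truth table
#'
#' Draws, for every sample, exactly \code{readsPerSample} reads from the
#' planted family members, background genomic loci and unmappable noise,
#' using a per-sample multinomial over expression weights (lognormal,
#' shared across samples). A binomial fraction \code{pos1ABias} of
#' background reads is drawn from adenine-starting loci; background reads
#' from the D-loop are emitted antisense to the forward reference strand
#' with probability \code{dloopReverseFraction}. FASTQ files (constant
#' quality) are written to \code{dir/reads/}, one per sample, together
#' with the truth table keyed by collapsed sequence.
#'
#' @param cfg a \link{SimConfig}.
#' @param mito,nuclear,plan results of \link{genMitoGenome},
#'   \link{genNuclearGenome}, \link{plantFamilies}.
#' @param dir output directory (created if missing). With \code{dir =
#'   NULL} nothing is written and reads exist only as the returned count
#'   matrix.
#' @return list with \code{truth} (data.frame, one row per emitted
#'   collapsed sequence), \code{counts} (matrix, truth rows x samples),
#'   and \code{files} (FASTQ paths, if written).
#' @export
simulateReads <- function(cfg, mito, nuclear, plan, dir = NULL) {
  stopifnot(is(cfg, "SimConfig"))
  mtSeq <- unname(mito$genome[[1]])
  samples <- cfg@samples
  .withSeed(cfg@seed, "reads", {
    N <- cfg@readsPerSample
    fam <- plan$members
    nFamRows <- nrow(fam)
    famW <- rlnorm(nFamRows, log(cfg@familyMeanReads), 0.6)
    usedKeys <- c(paste0(fam$anchor_genome, ":", fam$anchor5),
                  paste0("chrM:", fam$mito_anchor5[
                    !is.na(fam$mito_anchor5)]),
                  plan$blockedKeys)
    nBg <- cfg@nBackgroundLoci
    nBgM <- as.integer(round(nBg * cfg@bgMitoFraction))
    nBgN <- nBg - nBgM
    hasDl <- any(mito$features$type == "D-loop")
    forceDl <- rep(FALSE, nBgM)
    if (hasDl && nBgM >= 4L)
      forceDl[seq_len(max(2L, round(0.15 * nBgM)))] <- TRUE
    aClassM <- rep_len(c(TRUE, FALSE), nBgM)
    aClassN <- rep_len(c(TRUE, FALSE), nBgN)
    bgM <- if (nBgM)
      .sampleBackgroundLoci(nBgM, "chrM", mtSeq, TRUE, mito$features,
                            nuclear$numts, usedKeys, aClassM, forceDl,
                            dloopReverseFraction =
                              cfg@dloopReverseFraction)
    else list(loci = NULL, usedKeys = usedKeys)
    dlFeat <- mito$features[mito$features$type == "D-loop"]
    dlRange <- if (length(dlFeat)) c(start(dlFeat)[1], end(dlFeat)[1])
               else NULL
    bgN <- if (nBgN) {
      cts <- nuclear$contigs
      perCt <- .apportion(nBgN, nchar(cts))
      res <- NULL
      uk <- bgM$usedKeys
      off <- 0L
      for (ci in seq_along(cts)) {
        if (!perCt[ci]) next
        r <- .sampleBackgroundLoci(perCt[ci], names(cts)[ci], cts[[ci]],
                                   FALSE, NULL, nuclear$numts, uk,
                                   aClassN[off + seq_len(perCt[ci])],
                                   dloopRange = dlRange)
        res <- rbind(res, r$loci)
        uk <- r$usedKeys
        off <- off + perCt[ci]
      }
      list(loci = res)
    } else list(loci = NULL)

    nNoise <- if (cfg@noiseFraction > 0) 20L else 0L
    noiseSeqs <- character(0)
    while (length(noiseSeqs) < nNoise) {
      s <- .randDNA(.sampleOne(20:30))
      if (s %in% noiseSeqs) next
      if (.minHammingBothStrands(s, mtSeq, circular = TRUE) < 2L) next
      if (!all(vapply(nuclear$contigs, function(ct)
        .minHammingBothStrands(s, ct) >= 2L, logical(1)))) next
      noiseSeqs <- c(noiseSeqs, s)
    }

    ## pool assembly -------------------------------------------------------
    mkPool <- function(df, kind) {
      if (is.null(df) || !nrow(df)) return(NULL)
      data.frame(sequence = df$sequence, kind = kind,
                 true_class = df$true_class,
                 family_id = NA_character_, role = "noise",
                 direction = "none", genome = df$genome,
                 strand = df$strand, anchor5 = df$anchor5,
                 feature_name = df$feature_name,
                 feature_type = df$feature_type,
                 feature_strand = df$feature_strand,
                 orientation = df$orientation, dloop = df$dloop,
                 aclass = substr(df$sequence, 1, 1) == "A",
                 stringsAsFactors = FALSE)
    }
    poolFam <- if (nFamRows) data.frame(
      sequence = fam$sequence, kind = "family",
      true_class = fam$true_class, family_id = fam$family_id,
      role = fam$role, direction = fam$direction,
      genome = fam$anchor_genome, strand = fam$strand,
      anchor5 = fam$anchor5, feature_name = fam$feature_name,
      feature_type = fam$feature_type,
      feature_strand = NA_character_, orientation = fam$orientation,
      dloop = FALSE, aclass = FALSE, stringsAsFactors = FALSE) else NULL
    poolBgM <- mkPool(bgM$loci, "background")
    poolBgN <- mkPool(bgN$loci, "background")
    poolNoise <- if (nNoise) data.frame(
      sequence = noiseSeqs, kind = "noise", true_class = "UNMAPPED",
      family_id = NA_character_, role = "noise", direction = "none",
      genome = NA_character_, strand = NA_character_,
      anchor5 = NA_integer_, feature_name = NA_character_,
      feature_type = NA_character_, feature_strand = NA_character_,
      orientation = NA_character_, dloop = FALSE, aclass = FALSE,
      stringsAsFactors = FALSE) else NULL
    pool <- rbind(poolFam, poolBgM, poolBgN, poolNoise)
    rownames(pool) <- NULL

    ## group masses: family expression is absolute (reads/sample); the
    ## background absorbs the remaining depth; noise a fixed fraction.
    famTot <- sum(famW)
    noiseTot <- cfg@noiseFraction * N
    bgTot <- max(N - famTot - noiseTot, 0.1 * N)
    p <- cfg@pos1ABias
    groupOf <- rep("fam", nrow(pool))
    groupOf[pool$kind == "background" & pool$genome == "chrM" &
              pool$aclass] <- "bgmA"
    groupOf[pool$kind == "background" & pool$genome == "chrM" &
              !pool$aclass] <- "bgmO"
    groupOf[pool$kind == "background" & pool$genome != "chrM" &
              pool$aclass] <- "bgnA"
    groupOf[pool$kind == "background" & pool$genome != "chrM" &
              !pool$aclass] <- "bgnO"
    groupOf[pool$kind == "noise"] <- "noise"
    bgmTot <- bgTot * cfg@bgMitoFraction
    bgnTot <- bgTot - bgmTot
    mass <- c(fam = famTot, bgmA = bgmTot * p, bgmO = bgmTot * (1 - p),
              bgnA = bgnTot * p, bgnO = bgnTot * (1 - p),
              noise = noiseTot)
    mass[!names(mass) %in% groupOf] <- 0
    if (sum(mass) == 0) .stopf("empty read pool: nothing to simulate")
    withinW <- numeric(nrow(pool))
    withinW[groupOf == "fam"] <- famW
    for (g in setdiff(unique(groupOf), "fam"))
      withinW[groupOf == g] <- rlnorm(sum(groupOf == g), 0, 1)

    counts <- matrix(0L, nrow(pool), nrow(samples),
                     dimnames = list(NULL, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      Ns <- samples$total_reads[s]
      sizes <- as.vector(rmultinom(1, Ns, mass / sum(mass)))
      names(sizes) <- names(mass)
      for (g in names(sizes)) {
        idx <- which(groupOf == g)
        if (!length(idx) || sizes[g] == 0L) next
        counts[idx, s] <- as.vector(
          rmultinom(1, sizes[g], withinW[idx] / sum(withinW[idx])))
      }
    }

    keep <- rowSums(counts) > 0L | pool$kind == "family"
    pool <- pool[keep, , drop = FALSE]
    counts <- counts[keep, , drop = FALSE]
    if (anyDuplicated(pool$sequence)) {
      ord <- order(match(pool$kind, c("family", "background", "noise")))
      pool <- pool[ord, , drop = FALSE]
      counts <- counts[ord, , drop = FALSE]
      first <- !duplicated(pool$sequence)
      counts <- rowsum(counts, group = match(pool$sequence,
                                             pool$sequence[first]))
      counts <- counts[order(as.integer(rownames(counts))), ,
                       drop = FALSE]
      pool <- pool[first, , drop = FALSE]
    }
    truth <- pool[, setdiff(colnames(pool), c("dloop", "aclass"))]
    rownames(truth) <- NULL
    dimnames(counts) <- list(truth$sequence, samples$sample_id)

    files <- NULL
    if (!is.null(dir)) {
      rdir <- file.path(dir, "reads")
      dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
      files <- character(0)
      for (s in seq_len(ncol(counts))) {
        sid <- colnames(counts)[s]
        idx <- rep.int(seq_len(nrow(counts)), counts[, s])
        idx <- .shuffle(idx)
        seqs <- truth$sequence[idx]
        heads <- paste0("@", sid, "_r", seq_along(idx))
        quals <- strrep("I", nchar(seqs))
        path <- file.path(rdir, paste0(sid, ".fastq"))
        con <- file(path, open = "wb")
        writeLines(as.vector(rbind(heads, seqs, "+", quals)), con,
                   sep = "\n")
        close(con)
        files <- c(files, path)
      }
    }
    list(truth = truth, counts = counts, files = files)
  })
}
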