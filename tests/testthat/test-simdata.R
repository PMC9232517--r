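test_that("the mitochondrial genome layout honours the configuration", {
  cfg <- tinySimConfig(nTrna = 8L, nCds = 6L)
  mt <- genMitoGenome(cfg)
  expect_equal(nchar(mt$genome[["chrM"]]), cfg@mitoLength)
  feats <- mt$features
  expect_equal(sum(feats$type == "tRNA"), 8L)
  dl <- feats[feats$type == "D-loop"]
  expect_equal(length(dl), 1L)
  expect_equal(end(dl), cfg@mitoLength)  # pinned at the sequence end
  expect_true(sum(width(feats)) < cfg@mitoLength)  # gaps remain
  # non-overlapping features
  expect_equal(sum(width(reduce(feats, ignore.strand = TRUE))),
               sum(width(feats)))
  # both strands represented among tRNAs
  expect_setequal(unique(as.character(strand(feats[feats$type == "tRNA"]))),
                  c("+", "-"))
  # an impossible feature load raises a sizing error
  expect_error(genMitoGenome(tinySimConfig(mitoLength = 3000L)),
               "cannot hold")
})

test_that("NUMT insertions are recorded and verbatim at zero divergence", {
  cfg <- tinySimConfig()
  mt <- genMitoGenome(cfg)
  nuc <- genNuclearGenome(cfg, mt)
  expect_equal(nrow(nuc$numts), cfg@nNumts)
  for (i in seq_len(nrow(nuc$numts))) {
    row <- nuc$numts[i, ]
    frag <- substr(mt$genome[["chrM"]], row$mito_start, row$mito_end)
    if (row$strand == "-") frag <- oracleRevcomp(frag)
    copied <- substr(nuc$contigs[[row$contig]], row$copy_start,
                     row$copy_end)
    expect_identical(copied, frag)  # numtDivergence = 0
  }
  # divergence records substitutions
  cfgD <- tinySimConfig(numtDivergence = 0.05)
  nucD <- genNuclearGenome(cfgD, genMitoGenome(cfgD))
  expect_true(sum(nucD$numts$n_subs) > 0)
  expect_error(genNuclearGenome(
    tinySimConfig(numtLengthRange = c(25000L, 25000L)), mt), "contig")
})

test_that("without NUMTs no planted family sequence occurs in the nuclear genome", {
  cfg <- tinySimConfig(nNumts = 0L,
                       directionMix = c(retrograde = 0, anterograde = 0,
                                        self = 1),
                       nFamilies = 3L, nBackgroundLoci = 20L)
  mt <- genMitoGenome(cfg)
  nuc <- genNuclearGenome(cfg, mt)
  expect_equal(nrow(nuc$numts), 0L)
  plan <- plantFamilies(cfg, mt, nuc)
  # brute-force substring scan of every member against every contig
  for (s in plan$members$sequence) {
    for (ct in nuc$contigs) {
      expect_false(grepl(s, ct, fixed = TRUE))
      expect_false(grepl(oracleRevcomp(s), ct, fixed = TRUE))
    }
  }
})

test_that("planted families realise their direction label by construction", {
  run <- tinyRun()
  plan <- run$sim$plan
  mtSeq <- run$sim$mito$genome[["chrM"]]
  contigs <- run$sim$nuclear$contigs
  ladder <- run$cfg@familyLadder
  # ladder structure: db gains the matures, never the precursor
  for (fid in unique(plan$members$family_id)) {
    fam <- plan$members[plan$members$family_id == fid, ]
    expect_equal(sort(fam$member_len), sort(ladder))
    prec <- fam$sequence[fam$role == "precursor"]
    expect_false(prec %in% plan$pirnaDb)
    expect_true(all(fam$sequence[fam$role == "mature"] %in%
                      plan$pirnaDb))
    # every member is a 5' prefix of the precursor
    expect_true(all(startsWith(prec, fam$sequence)))
  }
  # a retrograde family: precursor found only in mito, matures in both
  retro <- plan$members[plan$members$direction == "retrograde", ]
  fam <- retro[retro$family_id == retro$family_id[1], ]
  prec <- fam$sequence[fam$role == "precursor"]
  inGenome <- function(s, g) grepl(s, g, fixed = TRUE) ||
    grepl(oracleRevcomp(s), g, fixed = TRUE)
  circ <- paste0(mtSeq, substr(mtSeq, 1, 80))
  expect_true(inGenome(prec, circ))
  expect_false(any(vapply(contigs, inGenome, logical(1), s = prec)))
  mat <- fam$sequence[fam$role == "mature"][1]
  expect_true(inGenome(mat, circ))
  expect_true(any(vapply(contigs, inGenome, logical(1), s = mat)))
  # exactly one dual sequence across the two reference sets
  expect_equal(sum(plan$pirnaDb %in% plan$mirnaDb), 1L)
})

test_that("read emission conserves depth and is deterministic", {
  run <- tinyRun()
  expect_true(all(colSums(run$sim$reads$counts) ==
                    run$cfg@readsPerSample))
  expect_false(anyDuplicated(run$sim$reads$truth$sequence) > 0)
  # byte-identical regeneration under the same config
  dir2 <- file.path(tempdir(), "mitopiR-tiny2")
  sim2 <- suppressWarnings(simulateDataset(tinySimConfig(), dir2))
  f1 <- sort(list.files(run$dir, recursive = TRUE))
  f2 <- sort(list.files(dir2, recursive = TRUE))
  expect_identical(f1, f2)
  m1 <- tools::md5sum(file.path(run$dir, f1))
  m2 <- tools::md5sum(file.path(dir2, f2))
  expect_identical(unname(m1), unname(m2))
})

test_that("forced biases are exact at the extremes", {
  cfg <- tinySimConfig(seed = 21L, pos1ABias = 1.0,
                       samples = sampleGrid(1500L),
                       readsPerSample = 1500L, nBackgroundLoci = 40L)
  mt <- genMitoGenome(cfg)
  nuc <- genNuclearGenome(cfg, mt)
  plan <- plantFamilies(cfg, mt, nuc)
  reads <- simulateReads(cfg, mt, nuc, plan, dir = NULL)
  truth <- reads$truth
  bg <- truth$kind == "background"
  emitted <- rowSums(reads$counts) > 0
  expect_true(all(startsWith(truth$sequence[bg & emitted], "A")))
  # dloopReverseFraction = 1 (default): every D-loop read antisense
  dl <- bg & !is.na(truth$feature_type) & truth$feature_type == "D-loop"
  expect_true(any(dl))
  expect_true(all(truth$orientation[dl] == "reverse"))
  expect_true(all(truth$strand[dl] == "-"))
})
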