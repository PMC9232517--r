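# Helper: build a SmallRNAExperiment directly from sequences, classes
# and piRNA matches, bypassing the mapping stage (hits are injected).
makeAnnotatedSE <- function(seqs, classes, pirnaIds, hits) {
  counts <- matrix(10L, length(seqs), 2,
                   dimnames = list(seqs, c("s1", "s2")))
  se <- SmallRNAExperiment(counts, data.frame(sample_id = c("s1", "s2")))
  SummarizedExperiment::rowData(se)$genomeClass <- classes
  SummarizedExperiment::rowData(se)$pirna_ids <- pirnaIds
  SummarizedExperiment::rowData(se)$pirna_multi <- FALSE
  SummarizedExperiment::rowData(se)$mirna_ids <- ""
  S4Vectors::metadata(se)$hits <- data.table::data.table(hits)
  se
}

test_that("a planted trimming ladder forms one family led by its precursor", {
  set.seed(41)
  prec <- randomDNA(60)
  ladder <- c(60, 30, 28, 25)
  seqs <- substr(rep(prec, 4), 1, ladder)
  hits <- data.frame(genome = "mito", contig = "chrM", strand = "+",
                     start = 500L, mismatches = 0L, sequence = seqs,
                     length = ladder)
  se <- makeAnnotatedSE(seqs, c("MT", "NUMT", "NUMT", "NUMT"),
                        c("", "piR-1", "piR-2", "piR-3"), hits)
  fams <- buildFamilies(se)
  expect_equal(length(fams), 1L)
  f <- as.data.frame(familyTable(fams))
  expect_equal(f$representative, prec)
  expect_equal(f$n_members, 4L)
  expect_true(f$eligible)
  expect_equal(f$direction, "retrograde")
  m <- as.data.frame(memberTable(fams))
  expect_equal(m$role[m$length == 60], "precursor")
  expect_true(all(m$role[m$length < 60] == "mature"))
  # prefix-closure: sorted by length, each member prefixes the next
  msorted <- m$sequence[order(m$length)]
  for (i in seq_len(nrow(m) - 1))
    expect_true(startsWith(msorted[i + 1], msorted[i]))
})

test_that("a 19-nt shared prefix does not anchor a family", {
  set.seed(42)
  base <- randomDNA(19)
  a <- paste0(base, "AACCGGTT")   # diverge at position 20
  b <- paste0(base, "CACCGGTT")
  hits <- data.frame(genome = "mito", contig = "chrM", strand = "+",
                     start = 100L, mismatches = 0L,
                     sequence = c(a, b), length = nchar(c(a, b)))
  se <- makeAnnotatedSE(c(a, b), c("MT", "MT"), c("", "piR-9"), hits)
  expect_equal(length(buildFamilies(se)), 0L)
})

test_that("sequences sharing a prefix but not a locus stay apart", {
  set.seed(43)
  prec <- randomDNA(40)
  short <- substr(prec, 1, 25)
  hits <- data.frame(genome = "mito", contig = "chrM", strand = "+",
                     start = c(100L, 900L), mismatches = 0L,
                     sequence = c(prec, short), length = c(40L, 25L))
  se <- makeAnnotatedSE(c(prec, short), c("MT", "MT"), c("", "piR-1"),
                        hits)
  expect_equal(length(buildFamilies(se, requireSharedLocus = TRUE)), 0L)
  expect_equal(length(buildFamilies(se, requireSharedLocus = FALSE)), 1L)
})

test_that("role assignment follows the precursor definition", {
  set.seed(44)
  prec <- randomDNA(60)
  seqs <- c(substr(prec, 1, 60), substr(prec, 1, 50),
            substr(prec, 1, 45), substr(prec, 1, 30))
  hits <- data.frame(genome = "mito", contig = "chrM", strand = "+",
                     start = 700L, mismatches = 0L, sequence = seqs,
                     length = nchar(seqs))
  # the 50-mer is a db-matched mature; the 45-mer matches nothing and is
  # SHORTER than the longest mature, so it cannot be a precursor
  se <- makeAnnotatedSE(seqs, rep("MT", 4),
                        c("", "piR-50", "", "piR-30"), hits)
  m <- as.data.frame(memberTable(buildFamilies(se)))
  expect_equal(m$role[m$length == 60], "precursor")
  expect_equal(m$role[m$length == 50], "mature")
  expect_equal(m$role[m$length == 45], "none")
  expect_equal(m$role[m$length == 30], "mature")
})

test_that("direction inference is a pure function of roles and classes", {
  expect_equal(inferDirection("MT", c("NUMT", "NUMT", "MT")),
               "retrograde")
  expect_equal(inferDirection("NU", "NUMT"), "anterograde")
  expect_equal(inferDirection("NU", "MT"), "anterograde")
  expect_equal(inferDirection("MT", "MT"), "self")
  expect_equal(inferDirection(c("NU", "NU"), "NU"), "self")
  expect_equal(inferDirection(c("MT", "NU"), "NUMT"), "unresolved")
  expect_equal(inferDirection("NUMT", "NUMT"), "unresolved")
  # permutation invariance
  set.seed(45)
  cls <- c("MT", "NUMT", "NU", "UNMAPPED")
  for (i in 1:25) {
    P <- sample(cls, sample(1:3, 1), replace = TRUE)
    M <- sample(cls, sample(1:3, 1), replace = TRUE)
    expect_equal(inferDirection(P, M),
                 inferDirection(sample(P), sample(M)))
  }
})

test_that("eligibility requires three counted members, both roles and a mito class", {
  set.seed(46)
  prec <- randomDNA(60)
  seqs <- c(substr(prec, 1, 60), substr(prec, 1, 30))
  hits <- data.frame(genome = "mito", contig = "chrM", strand = "+",
                     start = 300L, mismatches = 0L, sequence = seqs,
                     length = nchar(seqs))
  se <- makeAnnotatedSE(seqs, c("MT", "NUMT"), c("", "piR-1"), hits)
  f <- as.data.frame(familyTable(buildFamilies(se)))
  expect_false(f$eligible)          # only two counted members
  expect_equal(f$direction, "unresolved")
})

test_that("direction proportions sum to 100 and flag the empty case", {
  fams <- data.frame(
    family_id = sprintf("F%02d", 1:10),
    representative = vapply(1:10, function(i) randomDNA(40),
                            character(1)),
    n_members = 4L, n_counted = 4L, eligible = TRUE,
    direction = rep(c("retrograde", "anterograde"), c(8, 2)),
    anchor_genome = "mito", anchor_contig = "chrM",
    anchor_strand = "+", anchor_start = 1:10 * 100L)
  mem <- data.frame(family_id = fams$family_id,
                    sequence = fams$representative, length = 40L,
                    role = "precursor", genome_class = "MT",
                    pirna_ids = "", pirna_multi = FALSE, mirna_ids = "",
                    reads_total = 10L)
  dp <- directionProportions(PiRNAFamilySet(fams, mem))
  expect_equal(unname(dp$percentages),
               c(80, 20, 0))
  expect_equal(dp$denominator, 10L)
  expect_equal(sum(dp$percentages), 100)
  empty <- PiRNAFamilySet(mitopiR:::.emptyFamilyTable(),
                          mitopiR:::.emptyMemberTable())
  dpe <- directionProportions(empty)
  expect_true(dpe$empty)
  expect_equal(dpe$denominator, 0L)
})

test_that("families are disjoint and prefix-closed on simulated data", {
  run <- tinyRun()
  m <- as.data.frame(memberTable(run$fams))
  expect_false(anyDuplicated(m$sequence) > 0)
  for (fid in unique(m$family_id)) {
    ms <- m$sequence[m$family_id == fid]
    ms <- ms[order(nchar(ms))]
    for (i in seq_len(length(ms) - 1))
      expect_true(startsWith(ms[i + 1], ms[i]))
  }
})

test_that("the length histogram separates MT precursors from NUMT matures", {
  run <- tinyRun()
  lb <- lengthByClass(run$se, run$fams)
  expect_true(all(lb$reads >= 0))
  # total conservation over mito-matching sequences
  cls <- genomeClasses(run$se)
  mitoReads <- sum(SummarizedExperiment::assay(run$se, "counts")[
    cls %in% c("MT", "NUMT"), ])
  expect_equal(sum(lb$reads), mitoReads)
  # precursor length bin is dominated by MT, mature bins carry NUMT mass
  precLen <- run$cfg@familyLadder[1]
  precRows <- lb[lb$length == precLen & lb$role == "precursor", ]
  expect_true(all(precRows$genome_class == "MT"))
  matNUMT <- lb[lb$role == "mature" & lb$genome_class == "NUMT", ]
  expect_true(sum(matNUMT$reads) > 0)
})
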