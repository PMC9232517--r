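test_that("reference-set matching is equal-length bounded-Hamming", {
  db <- c(p1 = "ACGTACGTACGTACGTACGTACGTA",
          p2 = "ACGTACGTACGTACGTACGTACGTT",
          p3 = "ACGTACGTACGTACGTACGTACGT")   # one base shorter
  q <- "ACGTACGTACGTACGTACGTACGTA"
  m <- matchDb(q, db, k = 1)
  # p1 at distance 0, p2 at distance 1: minimal stratum keeps p1 only
  expect_equal(m$id, "p1")
  expect_equal(m$mismatches, 0L)
  # equal-length rule: the 24-mer p3 never matches a 25-mer query,
  # even though it is a perfect prefix
  expect_false("p3" %in% m$id)
  # a query equidistant (1) from two entries returns both
  q2 <- "ACGTACGTACGTACGTACGTACGTC"
  m2 <- matchDb(q2, db, k = 1)
  expect_setequal(m2$id, c("p1", "p2"))
  expect_true(all(m2$mismatches == 1L))
})

test_that("matching is symmetric under the equal-length rule", {
  set.seed(31)
  for (i in 1:20) {
    a <- randomDNA(24)
    b <- if (i %% 2 == 0) mutateAt(a, sample(24, 1)) else randomDNA(24)
    fwd <- nrow(matchDb(a, c(x = b), k = 1)) > 0
    rev <- nrow(matchDb(b, c(x = a), k = 1)) > 0
    expect_equal(fwd, rev)
  }
})

test_that("categories partition the sequences and recover planted truth", {
  run <- tinyRun()
  cat_ <- categories(run$se)
  expect_false(any(is.na(cat_)))
  expect_equal(sum(table(cat_)), nrow(run$se))
  truth <- run$sim$reads$truth
  plan <- run$sim$plan$members
  seqs <- seqStrings(run$se)
  # every planted mature is found as piRNA (or dual), never 'other'
  matures <- plan$sequence[plan$role == "mature"]
  got <- cat_[match(matures, seqs)]
  expect_true(all(got %in% c("piRNA", "dual")))
  # the planted dual sequence is called dual
  dualSeq <- intersect(run$sim$plan$pirnaDb, run$sim$plan$mirnaDb)
  expect_equal(unname(cat_[match(dualSeq, seqs)]), "dual")
  # noise sequences match nothing
  noise <- truth$sequence[truth$kind == "noise"]
  expect_true(all(cat_[match(noise, seqs)] == "other", na.rm = TRUE))
  # the redundant database entry flags one mature as multi-matching
  expect_true(any(rowData(run$se)$pirna_multi[match(matures, seqs)]))
})

test_that("feature overlaps respect strand conventions and conserve length", {
  L <- 1000L
  features <- GenomicRanges::GRanges(
    "chrM", IRanges::IRanges(c(101, 131, 901), c(130, 400, 1000)),
    strand = c("-", "+", "*"),
    name = c("tRNA-Test", "ND9", "D-loop"),
    type = c("tRNA", "CDS", "D-loop"))
  GenomeInfoDb::seqlengths(features) <- c(chrM = L)
  GenomeInfoDb::isCircular(features) <- TRUE
  # read on '-' fully inside a '-' tRNA: forward orientation
  fo <- hitFeatureOverlaps("-", start = 125, length = 20,
                           features = features, genomeLength = L)
  expect_equal(fo$feature_type, "tRNA")
  expect_equal(fo$orientation, "forward")
  expect_equal(sum(fo$overlap_nt), 20L)
  # read on '-' inside the strandless D-loop: reverse by convention
  fo2 <- hitFeatureOverlaps("-", start = 960, length = 25,
                            features = features, genomeLength = L)
  expect_equal(fo2$feature_type, "D-loop")
  expect_equal(fo2$orientation, "reverse")
  # read straddling the tRNA/CDS boundary: overlaps sum to read length
  fo3 <- hitFeatureOverlaps("+", start = 121, length = 30,
                            features = features, genomeLength = L)
  expect_setequal(fo3$feature_type, c("tRNA", "CDS"))
  expect_equal(sum(fo3$overlap_nt), 30L)
  expect_equal(fo3$overlap_nt[fo3$feature_type == "tRNA"], 10L)
  # junction-spanning read: D-loop end plus genome start (intergenic)
  fo4 <- hitFeatureOverlaps("+", start = 991, length = 30,
                            features = features, genomeLength = L)
  expect_equal(sum(fo4$overlap_nt), 30L)
  expect_setequal(fo4$feature_type, c("D-loop", "intergenic"))
  # no feature at all: one intergenic record covering the read
  fo5 <- hitFeatureOverlaps("+", start = 501, length = 20,
                            features = features, genomeLength = L)
  expect_equal(fo5$feature_type, "intergenic")
  expect_equal(fo5$overlap_nt, 20L)
})

test_that("overlap conservation holds across all cached hits", {
  run <- tinyRun()
  fo <- S4Vectors::metadata(run$se)$featureOverlaps
  lens <- setNames(nchar(seqStrings(run$se)), seqStrings(run$se))
  agg <- tapply(fo$overlap_nt,
                paste(fo$sequence, fo$hit_strand, fo$hit_start), sum)
  seqOf <- vapply(strsplit(names(agg), " "), `[`, character(1), 1)
  expect_true(all(agg == lens[seqOf]))
})

test_that("feature annotations round-trip through GFF3 and BED6", {
  run <- tinyRun()
  feats <- run$sim$mito$features
  L <- run$cfg@mitoLength
  gff <- file.path(tempdir(), "feat.gff3")
  bed <- file.path(tempdir(), "feat.bed")
  suppressWarnings(writeFeatureAnnotation(feats, gff))
  writeFeatureAnnotation(feats, bed)
  for (path in c(gff, bed)) {
    back <- readFeatureAnnotation(path, L)
    expect_equal(length(back), length(feats))
    key <- function(g) sort(paste(GenomicRanges::start(g),
                                  GenomicRanges::end(g),
                                  as.character(GenomicRanges::strand(g)),
                                  g$type, g$name))
    expect_identical(key(back), key(feats))
  }
})
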