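test_that("the sample table is internally consistent", {
  run <- tinyRun()
  summ <- summarizeCounts(run$se)
  tab <- summ$table
  smp <- tab[tab$sample_id != "Average", ]
  # mito reads bound the category splits; the remainder is 'other'
  mitoCats <- smp$mirna_NUMT.reads + smp$mirna_MT.reads +
    smp$pirna_NUMT.reads + smp$pirna_MT.reads
  expect_true(all(smp$mito.reads >= mitoCats))
  expect_true(all(smp$mito.reads <= smp$total.reads))
  expect_true(all(smp$mito.seq <= smp$total.seq))
  p <- summ$proportions
  expect_true(all(p >= 0 & p <= 100, na.rm = TRUE))
  expect_equal(unname(p["pirna_pct_of_mito"]),
               unname(p["pirna_NUMT_pct_of_mito"] +
                        p["pirna_MT_pct_of_mito"]))
  # averages are the column means of the per-sample rows
  expect_equal(unname(tab$mito.reads[tab$sample_id == "Average"]),
               mean(smp$mito.reads))
})

test_that("a known composition yields exact summary proportions", {
  seqs <- vapply(1:5, function(i) randomDNA(25), character(1))
  counts <- matrix(c(700L, 100L, 100L, 50L, 50L), 5, 2,
                   dimnames = list(seqs, c("a", "b")))
  se <- SmallRNAExperiment(counts, data.frame(sample_id = c("a", "b")))
  SummarizedExperiment::rowData(se)$genomeClass <-
    c("NU", "NUMT", "MT", "NUMT", "NU")
  SummarizedExperiment::rowData(se)$category <-
    c("piRNA", "piRNA", "piRNA", "miRNA", "other")
  summ <- summarizeCounts(se)
  p <- summ$proportions
  # mito reads = 250 of 1000 per sample
  expect_equal(unname(p["mito_pct_of_total_reads"]), 25)
  expect_equal(unname(p["pirna_NUMT_pct_of_mito"]), 100 * 100 / 250)
  expect_equal(unname(p["pirna_MT_pct_of_mito"]), 100 * 100 / 250)
  expect_equal(unname(p["pirna_pct_of_mito"]), 80)
  expect_equal(unname(p["mirna_NUMT_pct_of_mito"]), 20)
})

test_that("positional bias matrices behave under both weightings", {
  seqs <- c("ACGAACGTACGTACGTACGT", "AGGAACGTACGTACGTACGT",
            "GTTAACGTACGTACGTACGT")
  counts <- matrix(c(10L, 10L, 80L), 3, 1,
                   dimnames = list(seqs, "s"))
  se <- SmallRNAExperiment(counts, data.frame(sample_id = "s"))
  bs <- positionalBias(se, "sequence")
  expect_equal(unname(bs[1, "A"]), 2 / 3)
  br <- positionalBias(se, "read")
  expect_equal(unname(br[1, "G"]), 0.8)
  expect_equal(attr(br, "pos1Modal"), "G")
  # rows sum to one at covered positions
  expect_true(all(abs(rowSums(bs) - 1) < 1e-9))
  # read-weighting with unit counts equals sequence-weighting
  counts1 <- matrix(1L, 3, 1, dimnames = list(seqs, "s"))
  se1 <- SmallRNAExperiment(counts1, data.frame(sample_id = "s"))
  expect_equal(positionalBias(se1, "read")[, ],
               positionalBias(se1, "sequence")[, ])
  expect_error(positionalBias(se, subset = integer(0),
                              subsetName = "mito"), "mito")
})

test_that("bias positions beyond 35 nt are not profiled", {
  long <- randomDNA(60)
  counts <- matrix(5L, 1, 1, dimnames = list(long, "s"))
  se <- SmallRNAExperiment(counts, data.frame(sample_id = "s"))
  b <- positionalBias(se)
  expect_equal(nrow(b), 35L)
})

test_that("feature distribution conserves mitochondrial expression", {
  run <- tinyRun()
  fd <- featureDistribution(run$se)
  cls <- genomeClasses(run$se)
  counts <- SummarizedExperiment::assay(run$se, "counts")
  hits <- genomeHits(run$se)
  mitoSeqs <- unique(hits$sequence[hits$genome == "mito"])
  total <- sum(counts[match(mitoSeqs, seqStrings(run$se)), ])
  expect_equal(sum(fd$reads), total, tolerance = 1e-9)
  expect_true(all(fd$genome_class %in% c("MT", "NUMT")))
  # per-kb enrichment is reads / annotated kb
  pk <- perKbEnrichment(run$se, run$sim$mito$features)
  i <- match(pk$feature_type, pk$feature_type)
  expect_equal(pk$reads_per_kb, pk$reads / pk$annotated_kb)
})

test_that("the strand matrix is CPM-conserving and orientation-complete", {
  run <- tinyRun()
  sm <- strandMatrix(run$se)
  expect_true(all(endsWith(rownames(sm), "|Fwd") |
                    endsWith(rownames(sm), "|Rvr")))
  # column sums equal the per-sample mito CPM totals
  cpm <- SummarizedExperiment::assay(run$se, "cpm")
  hits <- genomeHits(run$se)
  mitoSeqs <- unique(hits$sequence[hits$genome == "mito"])
  expect_equal(unname(colSums(sm)),
               unname(colSums(cpm[match(mitoSeqs, seqStrings(run$se)), ,
                                  drop = FALSE])),
               tolerance = 1e-9)
  # forced reverse D-loop emission: the forward row is identically zero
  expect_true(all(sm["D-loop|Fwd", ] == 0))
  expect_true(sum(sm["D-loop|Rvr", ]) > 0)
})

test_that("matrices round-trip through TSV at 1e-9", {
  run <- tinyRun()
  sm <- strandMatrix(run$se)
  path <- file.path(tempdir(), "sm.tsv")
  write.table(data.frame(row = rownames(sm), sm, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.table(path, sep = "\t", header = TRUE,
                     check.names = FALSE)
  m2 <- as.matrix(back[, -1]); rownames(m2) <- back$row
  expect_equal(m2, sm, tolerance = 1e-9)
})

test_that("sample PCA is deterministic, sign-fixed and degenerate-safe", {
  # identical columns: zero variance everywhere
  m0 <- matrix(rep(c(5, 1, 3, 7), 12), 4, 12,
               dimnames = list(NULL, paste0("s", 1:12)))
  p0 <- pcaSamples(m0)
  expect_equal(unname(p0$varianceExplained), c(0, 0))
  expect_true(all(abs(p0$coordinates) < 1e-9))
  # two planted groups separate on PC1
  set.seed(51)
  base <- matrix(rexp(20 * 12, 1 / 50), 20, 12)
  base[1:5, 7:12] <- base[1:5, 7:12] * 8   # group effect
  colnames(base) <- paste0("s", 1:12)
  p <- pcaSamples(base)
  g <- rep(c(1, 2), each = 6)
  pc1 <- p$coordinates[, 1]
  between <- abs(mean(pc1[g == 1]) - mean(pc1[g == 2]))
  within <- mean(c(stats::sd(pc1[g == 1]), stats::sd(pc1[g == 2])))
  expect_true(between > within)  # positive silhouette-like separation
  expect_true(sum(p$varianceExplained) <= 1 + 1e-9)
  # sign fix: rerunning on a column-permuted copy gives the same PC1
  # geometry (distances preserved)
  p2 <- pcaSamples(base[, c(2:12, 1)])
  expect_equal(sort(abs(p2$coordinates[, 1])), sort(abs(pc1)),
               tolerance = 1e-6)
  expect_error(pcaSamples(base[, 1:2]), "at least 3")
  expect_error(pcaSamples(base, nComp = 20), "components")
})
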