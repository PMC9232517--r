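test_that("findHits matches the naive Hamming scan on small genomes", {
  set.seed(11)
  genome <- c(chrA = randomDNA(2000))
  queries <- c(
    substr(genome, 101, 130),                      # planted exact
    mutateAt(substr(genome, 501, 530), 7),         # 1 mismatch
    mutateAt(substr(genome, 901, 925), c(3, 17)),  # 2 mismatches
    oracleRevcomp(substr(genome, 1501, 1532)),     # minus strand
    randomDNA(28))                                 # absent
  for (k in 0:2) {
    for (q in queries) {
      expect_same_hits(findHits(q, genome, k = k),
                       oracleFindHits(q, genome, k = k))
    }
  }
})

test_that("circular search finds junction-spanning placements", {
  set.seed(12)
  g <- randomDNA(800)
  genome <- c(chrM = g)
  # last 10 nt + first 15 nt of the circle
  q <- paste0(substr(g, 791, 800), substr(g, 1, 15))
  hits <- findHits(q, genome, k = 0, circular = TRUE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 791L)  # length - 9
  expect_same_hits(hits, oracleFindHits(q, genome, k = 0,
                                        circular = TRUE))
  # also at k = 1 with a mutation inside the wrapped part
  q2 <- mutateAt(q, 13)
  expect_same_hits(findHits(q2, genome, k = 1, circular = TRUE),
                   oracleFindHits(q2, genome, k = 1, circular = TRUE))
})

test_that("only the minimal-mismatch stratum is reported, per genome", {
  set.seed(13)
  core <- randomDNA(30)
  g <- c(chr = paste0(randomDNA(50), core, randomDNA(40),
                      mutateAt(core, 12), randomDNA(50)))
  hits <- findHits(core, g, k = 1)
  expect_true(all(hits$mismatches == 0L))  # 1-mismatch copy suppressed
  expect_equal(nrow(hits), 1L)
  # a probe one mismatch away from both copies (different bases at the
  # same position) surfaces both placements in the 1-mismatch stratum
  chars <- strsplit(core, "")[[1]]
  other <- strsplit(mutateAt(core, 12), "")[[1]][12]
  chars[12] <- setdiff(c("A", "C", "G", "T"), c(chars[12], other))[1]
  probe <- paste(chars, collapse = "")
  hits2 <- findHits(probe, g, k = 1)
  expect_true(all(hits2$mismatches == 1L))
  expect_equal(nrow(hits2), 2L)
  expect_same_hits(hits2, oracleFindHits(probe, g, k = 1))
})

test_that("strand symmetry: reverse-complement queries flip strands only", {
  set.seed(14)
  genome <- c(chrA = randomDNA(1500))
  q <- mutateAt(substr(genome, 301, 330), 11)
  h1 <- findHits(q, genome, k = 1)
  h2 <- findHits(oracleRevcomp(q), genome, k = 1)
  expect_equal(nrow(h1), nrow(h2))
  expect_setequal(h1$mismatches, h2$mismatches)
  # covered forward intervals are identical
  iv <- function(h, L) ifelse(h$strand == "+", h$start, h$start - L + 1)
  expect_setequal(iv(h1, nchar(q)), iv(h2, nchar(q)))
  expect_setequal(h1$strand, chartr("+-", "-+", h2$strand))
})

test_that("classification is a partition driven by hit existence", {
  run <- tinyRun()
  cls <- genomeClasses(run$se)
  expect_false(any(is.na(cls)))
  expect_true(all(cls %in% c("NU", "MT", "NUMT", "UNMAPPED")))
  hits <- genomeHits(run$se)
  for (s in sample(seqStrings(run$se), 25)) {
    h <- hits[hits$sequence == s]
    lab <- cls[match(s, seqStrings(run$se))]
    hasN <- any(h$genome == "nuclear")
    hasM <- any(h$genome == "mito")
    expect_equal(lab, if (hasN && hasM) "NUMT" else if (hasM) "MT"
                 else if (hasN) "NU" else "UNMAPPED")
  }
  # decoy reference entries are absent from both genomes
  decoys <- setdiff(run$sim$plan$pirnaDb,
                    run$sim$plan$members$sequence)
  h <- findHits(decoys[1], run$sim$nuclear$contigs, k = 1)
  expect_equal(nrow(h), 0L)
})

test_that("parameter validation rejects bad queries", {
  g <- c(chr = randomDNA(100))
  expect_error(findHits("ACGT", g, k = 5), "between 0 and 3")
  expect_error(findHits("ACGN", g, k = 1), "A/C/G/T")
  expect_error(findHits(randomDNA(80), g, k = 1), "75")
})

test_that("coordinate spans use the 1-based inclusive convention", {
  expect_equal(unname(spanLength(16119, 16188)["linear"]), 70)
  expect_equal(unname(spanLength(16188, 16119)["linear"]), 70)
  expect_equal(unname(spanLength(5, 5)["linear"]), 1)
  expect_equal(unname(spanLength(16121, 16189)["linear"]), 69)
  sp <- spanLength(10, 30, circularLength = 100)
  expect_equal(unname(sp["circular"]), 81)
  expect_error(spanLength(0, 5), ">= 1")
})
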