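# Naive all-offsets Hamming scan: the independent oracle for bounded
# mismatch placement. Deliberately written as plain character loops,
# sharing no code with the package's matcher.

oracleRevcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

oracleScanOne <- function(qChars, sChars, k) {
  L <- length(qChars)
  n <- length(sChars) - L + 1L
  hits <- list()
  for (off in seq_len(max(n, 0L))) {
    mm <- sum(sChars[off:(off + L - 1L)] != qChars)
    if (mm <= k) hits[[length(hits) + 1L]] <- c(off, mm)
  }
  hits
}

# Same contract as findHits(): all minimal-stratum placements, both
# strands, 5'-anchored starts, circular genomes doubled by query length
# minus one, coordinates taken modulo the contig length.
oracleFindHits <- function(query, genome, k, circular = FALSE) {
  out <- data.frame(contig = character(0), strand = character(0),
                    start = integer(0), mismatches = integer(0),
                    stringsAsFactors = FALSE)
  L <- nchar(query)
  for (nm in names(genome)) {
    subj <- genome[[nm]]
    cl <- nchar(subj)
    if (L > cl) next
    if (circular && L > 1L) subj <- paste0(subj, substr(subj, 1L, L - 1L))
    sChars <- strsplit(subj, "")[[1]]
    for (str in c("+", "-")) {
      q <- if (str == "+") query else oracleRevcomp(query)
      for (h in oracleScanOne(strsplit(q, "")[[1]], sChars, k)) {
        p5 <- if (str == "+") h[1] else h[1] + L - 1L
        if (circular) p5 <- ((p5 - 1L) %% cl) + 1L
        out <- rbind(out, data.frame(contig = nm, strand = str,
                                     start = as.integer(p5),
                                     mismatches = as.integer(h[2]),
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out <- unique(out)
  if (nrow(out)) out <- out[out$mismatches == min(out$mismatches), ,
                            drop = FALSE]
  out[order(out$contig, out$strand, out$start), , drop = FALSE]
}

expect_same_hits <- function(a, b) {
  key <- function(h) sort(paste(h$contig, h$strand, h$start,
                                h$mismatches))
  expect_identical(key(a), key(b))
}
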