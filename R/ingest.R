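## Ingest: FASTA/FASTQ reading, per-sample collapsing of identical
## sequences, CPM computation and the >= 10 CPM retention rule.

.sniffFormat <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first)) return("fasta")
  if (startsWith(first, "@")) "fastq" else "fasta"
}

## Diagnostic scan used when a FASTQ file fails to parse: report the
## 1-based line number of the first malformed record.
.fastqErrorLine <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  i <- 1L
  while (i <= n) {
    if (!startsWith(lines[i], "@")) return(i)
    if (i + 3L > n) return(i)
    if (!startsWith(lines[i + 2L], "+")) return(i + 2L)
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) return(i + 3L)
    i <- i + 4L
  }
  NA_integer_
}

.readReadFile <- function(path) {
  fmt <- .sniffFormat(path)
  res <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) {
      if (fmt == "fastq") {
        ln <- .fastqErrorLine(path)
        if (!is.na(ln))
          .stopf("malformed FASTQ record in '%s' at line %d", path, ln)
      }
      .stopf("failed to parse '%s': %s", path, conditionMessage(e))
    })
  toupper(chartr("Uu", "Tt", as.character(res)))
}

#' Collapse reads into unique sequences with per-sample counts
#'
#' Reads one FASTA/FASTQ file per sample (gzip-transparent), maps RNA U to
#' DNA T, uppercases, discards reads containing ambiguity codes (tallied)
#' or falling outside 15-75 nt, and collapses identical sequences into one
#' record with per-sample counts. CPM values use the per-sample total of
#' reads entering collapse as denominator, so pre-filter CPM sums to 1e6
#' per sample.
#'
#' @param files named character vector of file paths (names become sample
#'   ids), or a named list of in-memory read character vectors.
#' @param sampleData optional data.frame of per-sample metadata with a
#'   \code{sample_id} column matching \code{names(files)}.
#' @return a \link{SmallRNAExperiment}; \code{metadata(x)$libraryStats}
#'   holds per-sample ingest statistics.
#' @export
#' @importFrom data.table data.table dcast.data.table setkey := .N as.data.table
#' @examples
#' reads <- list(s1 = c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT",
#'                      "ACGGACGTACGTACGTACGT"))
#' se <- collapseReads(reads)
#' assay(se, "counts")
collapseReads <- function(files, sampleData = NULL) {
  if (is.null(names(files)) || !all(nzchar(names(files))))
    names(files) <- if (is.character(files))
      sub("\\.(fastq|fq|fasta|fa)(\\.gz)?$", "", basename(files))
    else paste0("sample", seq_along(files))
  sampleIds <- names(files)
  perSample <- vector("list", length(files))
  stats <- data.frame(sample_id = sampleIds, total_reads = 0L,
                      reads_discarded_ambiguous = 0L,
                      reads_discarded_length = 0L,
                      sequences_pre_filter = 0L,
                      sequences_post_filter = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(files)) {
    reads <- if (is.character(files)) .readReadFile(files[[i]])
    else toupper(chartr("Uu", "Tt", as.character(files[[i]])))
    amb <- grepl("[^ACGT]", reads)
    lenBad <- !amb & (nchar(reads) < 15L | nchar(reads) > 75L)
    stats$reads_discarded_ambiguous[i] <- sum(amb)
    stats$reads_discarded_length[i] <- sum(lenBad)
    reads <- reads[!amb & !lenBad]
    stats$total_reads[i] <- length(reads)
    perSample[[i]] <- if (length(reads))
      data.table(sequence = reads, sample = sampleIds[i])
    else data.table(sequence = character(0), sample = character(0))
  }
  dt <- data.table::rbindlist(perSample)
  if (nrow(dt)) {
    agg <- dt[, list(n = .N), by = c("sequence", "sample")]
    wide <- dcast.data.table(agg, sequence ~ sample, value.var = "n",
                             fill = 0L)
    counts <- as.matrix(wide[, -1L, with = FALSE])
    rownames(counts) <- wide$sequence
    missing <- setdiff(sampleIds, colnames(counts))
    if (length(missing)) {
      counts <- cbind(counts, matrix(0L, nrow(counts), length(missing),
                                     dimnames = list(NULL, missing)))
    }
    counts <- counts[, sampleIds, drop = FALSE]
  } else {
    counts <- matrix(0L, 0L, length(sampleIds),
                     dimnames = list(character(0), sampleIds))
  }
  perSampleSeqs <- colSums(counts > 0L)
  stats$sequences_pre_filter <- as.integer(perSampleSeqs[sampleIds])
  if (is.null(sampleData))
    sampleData <- data.frame(sample_id = sampleIds,
                             stringsAsFactors = FALSE)
  else
    sampleData <- sampleData[match(sampleIds, sampleData$sample_id), ,
                             drop = FALSE]
  se <- SmallRNAExperiment(counts, sampleData,
                           librarySize = stats$total_reads)
  metadata(se)$libraryStats <- stats
  se
}

#' Apply the counts-per-million retention rule
#'
#' A sequence is retained if its CPM reaches \code{threshold} in at least
#' one sample ("under 10 CPM" is discarded, so a CPM of exactly 10 is
#' kept). Per-sample membership flags are stored in the
#' \code{retainedIn} assay so per-sample tallies can be reproduced; CPM
#' denominators are the pre-filter library sizes and are not recomputed.
#'
#' @param se a \link{SmallRNAExperiment} from \link{collapseReads}.
#' @param threshold CPM threshold (default 10).
#' @return the filtered \code{SmallRNAExperiment}.
#' @export
filterCPM <- function(se, threshold = 10) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    .stopf("threshold must be a single non-negative number")
  cpm <- assay(se, "cpm")
  retainedIn <- cpm >= threshold
  keep <- rowSums(retainedIn) > 0L
  out <- se[keep, ]
  assay(out, "retainedIn") <- retainedIn[keep, , drop = FALSE]
  stats <- metadata(out)$libraryStats
  if (!is.null(stats)) {
    post <- colSums(retainedIn[keep, , drop = FALSE])
    stats$sequences_post_filter <-
      as.integer(post[stats$sample_id])
    metadata(out)$libraryStats <- stats
  }
  metadata(out)$cpmThreshold <- threshold
  out
}

#' Clip a 3' adapter from read sequences
#'
#' Minimal plumbing for otherwise-untrimmed input: removes everything from
#' the first full occurrence of the adapter onwards, or a terminal prefix
#' of the adapter (down to \code{minOverlap} bases) at the 3' end.
#'
#' @param reads character vector of read sequences.
#' @param adapter adapter sequence.
#' @param minOverlap minimal adapter prefix length recognised at the read
#'   end.
#' @return character vector of clipped reads.
#' @export
clipAdapter <- function(reads, adapter = "AGATCGGAAGAGC",
                        minOverlap = 1L) {
  pos <- regexpr(adapter, reads, fixed = TRUE)
  out <- ifelse(pos > 0L, substr(reads, 1L, pos - 1L), reads)
  done <- pos > 0L
  for (k in rev(seq(minOverlap, nchar(adapter) - 1L))) {
    pre <- substr(adapter, 1L, k)
    hit <- !done & endsWith(out, pre)
    out[hit] <- substr(out[hit], 1L, nchar(out[hit]) - k)
    done <- done | hit
  }
  out
}
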