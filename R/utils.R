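## Internal helpers shared across modules.

#' @import methods
#' @importFrom stats rlnorm rmultinom rbinom runif setNames
#' @importFrom utils write.table read.table
#' @importFrom data.table fread rbindlist
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

## Deterministic sub-stream seed derived from a master seed and a stage name,
## so adding a stage never shifts another stage's draws.
.subSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) %% 65011 * 33013 + h * 7919) %% 2147483629L)
}

.withSeed <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.subSeed(seed, name))
  force(expr)
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.randDNA <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

## Hamming distances between a query and every length-matched window of a
## subject (both as plain strings). Returns an integer vector over offsets
## 1..(nchar(subject) - nchar(query) + 1). Vectorised over offsets.
.hammingScan <- function(query, subject) {
  L <- nchar(query)
  S <- nchar(subject)
  n <- S - L + 1L
  if (n < 1L) return(integer(0))
  q <- utf8ToInt(query)
  s <- utf8ToInt(subject)
  mism <- integer(n)
  for (j in seq_len(L)) {
    mism <- mism + (s[j:(j + n - 1L)] != q[j])
  }
  mism
}

## Minimum Hamming distance of `query` against subject windows on both
## strands (subject circularised when circular=TRUE). Used by the generator
## to certify that decoy/noise sequences are absent from the genomes; kept
## separate from the Biostrings-based mapper.
.minHammingBothStrands <- function(query, subject, circular = FALSE) {
  subj <- subject
  if (circular && nchar(query) > 1L) {
    subj <- paste0(subject, substr(subject, 1L, nchar(query) - 1L))
  }
  d1 <- .hammingScan(query, subj)
  d2 <- .hammingScan(.revcomp(query), subj)
  suppressWarnings(min(c(d1, d2, Inf)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## sample() guard: draw one element of x even when length(x) == 1.
.sampleOne <- function(x) x[sample.int(length(x), 1L)]

## permutation guard: shuffle x itself, never 1:x.
.shuffle <- function(x) x[sample.int(length(x))]

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "", ...)
}
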