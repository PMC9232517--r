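#' A set of 5'-anchored piRNA families
#'
#' A piRNA family groups sequences that share an identical 5' end and
#' differ only by 3' trimming, anchored at one genomic locus: typically a
#' long unprocessed precursor (pre-piRNA, absent from the piRNA reference
#' set) and its shorter mature forms (present in the reference set).
#' \code{familyTable(x)} has one row per family (representative sequence,
#' anchor locus, eligibility, inferred mito-nuclear communication
#' direction); \code{memberTable(x)} one row per member sequence (role,
#' genome class, reference-set ids).
#'
#' @param x a \code{PiRNAFamilySet}.
#' @slot families DataFrame, one row per family.
#' @slot members DataFrame, one row per member sequence.
#' @return \code{familyTable()} and \code{memberTable()} return the
#'   corresponding \code{DataFrame}s.
#' @aliases PiRNAFamilySet familyTable memberTable
#' @export PiRNAFamilySet
#' @exportClass PiRNAFamilySet
setClass("PiRNAFamilySet",
         representation(families = "DataFrame", members = "DataFrame"))

PiRNAFamilySet <- function(families, members) {
  new("PiRNAFamilySet", families = DataFrame(families),
      members = DataFrame(members))
}

setValidity("PiRNAFamilySet", function(object) {
  msg <- character(0)
  fneed <- c("family_id", "representative", "n_members", "eligible",
             "direction")
  if (!all(fneed %in% colnames(object@families)))
    msg <- c(msg, paste("families needs columns:",
                        paste(fneed, collapse = ", ")))
  mneed <- c("family_id", "sequence", "role", "genome_class")
  if (!all(mneed %in% colnames(object@members)))
    msg <- c(msg, paste("members needs columns:",
                        paste(mneed, collapse = ", ")))
  if (!length(msg) && anyDuplicated(object@members$sequence))
    msg <- c(msg, "a sequence cannot belong to two families")
  if (length(msg)) msg else TRUE
})

#' @rdname PiRNAFamilySet-class
#' @export
setMethod("familyTable", "PiRNAFamilySet", function(x) x@families)

#' @rdname PiRNAFamilySet-class
#' @export
setMethod("memberTable", "PiRNAFamilySet", function(x) x@members)

#' @rdname PiRNAFamilySet-class
#' @export
setMethod("length", "PiRNAFamilySet", function(x) nrow(x@families))

setMethod("show", "PiRNAFamilySet", function(object) {
  f <- object@families
  cat("PiRNAFamilySet: ", nrow(f), " families, ",
      nrow(object@members), " member sequences\n", sep = "")
  if (nrow(f)) {
    cat("  eligible: ", sum(f$eligible), "\n", sep = "")
    tb <- table(f$direction[f$eligible])
    if (length(tb))
      cat("  directions: ",
          paste(names(tb), tb, sep = "=", collapse = ", "), "\n", sep = "")
  }
})
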