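#' @rdname SmallRNAExperiment-class
#' @export
setGeneric("seqStrings", function(x) standardGeneric("seqStrings"))

#' @rdname SmallRNAExperiment-class
#' @export
setGeneric("genomeClasses", function(x) standardGeneric("genomeClasses"))

#' @rdname SmallRNAExperiment-class
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @rdname SmallRNAExperiment-class
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname SmallRNAExperiment-class
#' @export
setGeneric("genomeHits", function(x) standardGeneric("genomeHits"))

#' @rdname PiRNAFamilySet-class
#' @export
setGeneric("familyTable", function(x) standardGeneric("familyTable"))

#' @rdname PiRNAFamilySet-class
#' @export
setGeneric("memberTable", function(x) standardGeneric("memberTable"))

#' @rdname directionProportions
#' @export
setGeneric("directionProportions",
           function(x, ...) standardGeneric("directionProportions"))
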