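#' @rdname ErvPresence-class
#' @param x an object.
#' @export
setGeneric("presenceCounts", function(x) standardGeneric("presenceCounts"))

#' @rdname ErvPresence-class
#' @export
setGeneric("presenceBinary", function(x) standardGeneric("presenceBinary"))

#' @rdname ErvPresence-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname ErvSimulation-class
#' @param x an object.
#' @export
setGeneric("truthLoci", function(x) standardGeneric("truthLoci"))

#' @rdname ErvSimulation-class
#' @export
setGeneric("truthZygosity", function(x) standardGeneric("truthZygosity"))

#' @rdname ErvSimulation-class
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))
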