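## Constructors, accessors and show methods for the S4 classes.

#' Construct simulation parameters
#'
#' User-facing constructor for [SimulationParams-class] with defaults that
#' describe the study conditions the package emulates: a multi-species,
#' multi-island passerine cohort sequenced at 6--49x, a detection model with
#' an 8\% miss rate for homozygous loci, 45\% heterozygous sensitivity at 4x
#' rising linearly to saturation at 30x, and roughly 2.6\% of loci carried by
#' the reference assembly (698 of 26,964).
#'
#' @param nSpecies,islandsPerSpecies,individualsPerPopulation cohort layout.
#' @param nFixedLoci,nPolymorphicLoci,nFamilies truth-locus composition.
#' @param familyEnrichment named list (species -> named numeric family
#'   multipliers); biases carrier-species assignment of polymorphic loci.
#' @param homMissProb,hetSensitivityAt4x,hetSaturationCoverage detection
#'   model, see [detectionProbability()].
#' @param coverageRange uniform range for per-individual mean coverage.
#' @param chromLengths named chromosome lengths in bp.
#' @param endEnrichmentFactor,terminalFraction locus placement bias towards
#'   chromosome ends.
#' @param assemblyFraction,svFractionOfAssembly assembly-side locus makeup.
#' @param stringentPassProb probability an emitted call passes the stringent
#'   filter cascade.
#' @param rngSeed default seed.
#' @return a validated [SimulationParams-class] object.
#' @examples
#' p <- SimulationParams(nSpecies = 3L, nFixedLoci = 50L)
#' detectionProbability(1, 17, p)
#' @export
SimulationParams <- function(nSpecies = 5L,
                             islandsPerSpecies = 2L,
                             individualsPerPopulation = 10L,
                             nFixedLoci = 300L,
                             nPolymorphicLoci = 1500L,
                             nFamilies = 20L,
                             familyEnrichment = list(),
                             homMissProb = 0.08,
                             hetSensitivityAt4x = 0.45,
                             hetSaturationCoverage = 30,
                             coverageRange = c(6, 49),
                             chromLengths = c(CamParChr1 = 8e7,
                                              CamParChr1A = 4e7,
                                              CamParChr2 = 7.5e7,
                                              CamParChr3 = 6e7),
                             endEnrichmentFactor = 1,
                             terminalFraction = 0.1,
                             assemblyFraction = 698 / 26964,
                             svFractionOfAssembly = 491 / 698,
                             stringentPassProb = 0.9,
                             rngSeed = 1L) {
    new("SimulationParams",
        nSpecies = as.integer(nSpecies),
        islandsPerSpecies = as.integer(islandsPerSpecies),
        individualsPerPopulation = as.integer(individualsPerPopulation),
        nFixedLoci = as.integer(nFixedLoci),
        nPolymorphicLoci = as.integer(nPolymorphicLoci),
        nFamilies = as.integer(nFamilies),
        familyEnrichment = familyEnrichment,
        homMissProb = homMissProb,
        hetSensitivityAt4x = hetSensitivityAt4x,
        hetSaturationCoverage = hetSaturationCoverage,
        coverageRange = as.numeric(coverageRange),
        chromLengths = chromLengths,
        endEnrichmentFactor = endEnrichmentFactor,
        terminalFraction = terminalFraction,
        assemblyFraction = assemblyFraction,
        svFractionOfAssembly = svFractionOfAssembly,
        stringentPassProb = stringentPassProb,
        rngSeed = as.integer(rngSeed))
}

#' Construct an ErvPresence object
#'
#' @param counts integer matrix, loci x individuals.
#' @param loci `GRanges` with `locus_id`, `family`, `source` metadata.
#' @param samples sample metadata `data.frame` with one row per individual,
#'   ordered as the columns of `counts`.
#' @return an [ErvPresence-class] object.
#' @export
ErvPresence <- function(counts, loci, samples) {
    mode(counts) <- "integer"
    rownames(counts) <- mcols(loci)$locus_id
    colnames(counts) <- samples$individual_id
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = loci,
        colData = DataFrame(samples, row.names = samples$individual_id))
    new("ErvPresence", se)
}

#' @rdname ErvPresence-class
#' @export
setMethod("presenceCounts", "ErvPresence", function(x) assay(x, "counts"))

#' @rdname ErvPresence-class
#' @export
setMethod("presenceBinary", "ErvPresence", function(x) {
    b <- assay(x, "counts") >= 1L
    mode(b) <- "integer"
    b
})

#' @rdname ErvPresence-class
#' @export
setMethod("sampleInfo", "ErvPresence", function(x)
    as.data.frame(colData(x), optional = TRUE))

#' @rdname ErvSimulation-class
#' @export
setMethod("truthLoci", "ErvSimulation", function(x) x@truthLoci)

#' @rdname ErvSimulation-class
#' @export
setMethod("truthZygosity", "ErvSimulation", function(x) x@zygosity)

#' @rdname ErvSimulation-class
#' @export
setMethod("sampleInfo", "ErvSimulation", function(x) x@samples)

#' @rdname ErvSimulation-class
#' @export
setMethod("simParams", "ErvSimulation", function(x) x@params)

setMethod("show", "SimulationParams", function(object) {
    cat("SimulationParams:",
        object@nSpecies, "species x", object@islandsPerSpecies,
        "islands x", object@individualsPerPopulation, "individuals\n")
    cat("  loci:", object@nFixedLoci, "fixed +", object@nPolymorphicLoci,
        "polymorphic;", object@nFamilies, "families\n")
    cat(sprintf("  detection: hom miss %.2f; het %.2f at 4x -> 1.0 at %gx\n",
                object@homMissProb, object@hetSensitivityAt4x,
                object@hetSaturationCoverage))
    cat(sprintf("  coverage %g-%gx; assembly fraction %.3f\n",
                object@coverageRange[1], object@coverageRange[2],
                object@assemblyFraction))
})

setMethod("show", "ErvSimulation", function(object) {
    cat("ErvSimulation:", length(object@truthLoci), "truth loci x",
        nrow(object@samples), "individuals\n")
    src <- table(mcols(object@truthLoci)$source)
    cat("  sources:", paste(names(src), src, sep = "=", collapse = ", "), "\n")
    cat("  species:", length(unique(object@samples$species)), "\n")
})
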