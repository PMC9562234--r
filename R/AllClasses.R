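#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
NULL

#' Parameters for the synthetic ERV cohort generator
#'
#' Bundles the cohort layout (species x island x individuals), the truth-locus
#' composition (ancestrally fixed vs post-speciation polymorphic loci, ERV
#' family pool, optional per-species family enrichment) and the detection
#' model that maps true zygosity and sequencing coverage to the probability
#' that a caller reports the locus in an individual.
#'
#' The detection model has three regimes: loci absent from an individual are
#' never called; homozygous loci are called with constant probability
#' \code{1 - homMissProb} regardless of coverage; heterozygous loci are called
#' with a probability that rises linearly from \code{hetSensitivityAt4x} at
#' 4-fold coverage to 1.0 at \code{hetSaturationCoverage}, clamped to [0, 1]
#' and constant above saturation.
#'
#' @slot nSpecies number of species in the cohort.
#' @slot islandsPerSpecies island populations per species.
#' @slot individualsPerPopulation individuals per species-island population.
#' @slot nFixedLoci ancestrally fixed loci (homozygous in every individual).
#' @slot nPolymorphicLoci post-speciation loci segregating in a proper subset
#'   of species.
#' @slot nFamilies number of ERV families in the pool.
#' @slot familyEnrichment named list (species -> named numeric of family
#'   multipliers) biasing which species carry loci of a family; models
#'   lineage-restricted ERV expansion bursts.
#' @slot homMissProb per-call miss probability for homozygous loci.
#' @slot hetSensitivityAt4x detection probability of a heterozygous locus at
#'   4x coverage.
#' @slot hetSaturationCoverage fold-coverage at which heterozygous detection
#'   saturates at 1.0.
#' @slot coverageRange min/max individual mean fold-coverage (uniform draw).
#' @slot chromLengths named numeric, chromosome lengths in bp.
#' @slot endEnrichmentFactor relative density of locus placement inside the
#'   two terminal windows of each chromosome (1 = uniform).
#' @slot terminalFraction width of each terminal window as a fraction of
#'   chromosome length.
#' @slot assemblyFraction fraction of all loci represented as assembly-side
#'   (present in the reference, detected through deletions).
#' @slot svFractionOfAssembly fraction of assembly-side loci emitted in the
#'   split-read (sv) deletion dialect rather than the read-depth (cnv) one.
#' @slot stringentPassProb probability that an emitted insertion call carries
#'   filter fields passing the stringent cascade (all calls pass the relaxed
#'   one).
#' @slot rngSeed default random seed for simulation.
#'
#' @seealso [SimulationParams()] for the user constructor,
#'   [simulateCohort()], [detectionProbability()].
#' @export
setClass("SimulationParams", slots = c(
    nSpecies = "integer",
    islandsPerSpecies = "integer",
    individualsPerPopulation = "integer",
    nFixedLoci = "integer",
    nPolymorphicLoci = "integer",
    nFamilies = "integer",
    familyEnrichment = "list",
    homMissProb = "numeric",
    hetSensitivityAt4x = "numeric",
    hetSaturationCoverage = "numeric",
    coverageRange = "numeric",
    chromLengths = "numeric",
    endEnrichmentFactor = "numeric",
    terminalFraction = "numeric",
    assemblyFraction = "numeric",
    svFractionOfAssembly = "numeric",
    stringentPassProb = "numeric",
    rngSeed = "integer"))

setValidity("SimulationParams", function(object) {
    msg <- character()
    chkProb <- function(x, nm) {
        if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
            msg <<- c(msg, paste0(nm, " must be a single value in [0, 1]"))
    }
    chkCount <- function(x, nm, min = 1L) {
        if (length(x) != 1L || is.na(x) || x < min)
            msg <<- c(msg, paste0(nm, " must be a single integer >= ", min))
    }
    chkCount(object@nSpecies, "nSpecies")
    chkCount(object@islandsPerSpecies, "islandsPerSpecies")
    chkCount(object@individualsPerPopulation, "individualsPerPopulation")
    chkCount(object@nFixedLoci, "nFixedLoci", 0L)
    chkCount(object@nPolymorphicLoci, "nPolymorphicLoci", 0L)
    chkCount(object@nFamilies, "nFamilies")
    chkProb(object@homMissProb, "homMissProb")
    chkProb(object@hetSensitivityAt4x, "hetSensitivityAt4x")
    chkProb(object@assemblyFraction, "assemblyFraction")
    chkProb(object@svFractionOfAssembly, "svFractionOfAssembly")
    chkProb(object@stringentPassProb, "stringentPassProb")
    if (object@hetSaturationCoverage <= 4)
        msg <- c(msg, "hetSaturationCoverage must exceed 4 (the anchored coverage)")
    if (length(object@coverageRange) != 2L || any(object@coverageRange <= 0) ||
        diff(object@coverageRange) < 0)
        msg <- c(msg, "coverageRange must be two positive, non-decreasing values")
    if (length(object@chromLengths) < 1L || is.null(names(object@chromLengths)) ||
        any(!nzchar(names(object@chromLengths))) || any(object@chromLengths <= 0))
        msg <- c(msg, "chromLengths must be a named vector of positive lengths")
    if (object@endEnrichmentFactor < 1)
        msg <- c(msg, "endEnrichmentFactor must be >= 1")
    if (object@terminalFraction <= 0 || object@terminalFraction >= 0.5)
        msg <- c(msg, "terminalFraction must lie in (0, 0.5)")
    if (length(msg)) msg else TRUE
})

#' Synthetic cohort with known ERV truth
#'
#' Result of [simulateCohort()]: the true locus set (positions, family,
#' non-assembly vs assembly source), the per-individual true zygosity matrix
#' (0/1/2 copies) and the sample metadata. Caller-style tables are derived
#' from it with [emitCallTables()].
#'
#' @slot truthLoci `GRanges` of truth loci with metadata columns `locus_id`,
#'   `family`, `clade`, `source`, `dialect`, `fixed`.
#' @slot zygosity integer matrix, loci x individuals, values 0/1/2.
#' @slot samples `data.frame` of sample metadata (one row per individual).
#' @slot params the [SimulationParams-class] used.
#' @export
setClass("ErvSimulation", slots = c(
    truthLoci = "GRanges",
    zygosity = "matrix",
    samples = "data.frame",
    params = "SimulationParams"))

setValidity("ErvSimulation", function(object) {
    msg <- character()
    gr <- object@truthLoci
    z <- object@zygosity
    if (nrow(z) != length(gr))
        msg <- c(msg, "zygosity rows must match truthLoci length")
    if (ncol(z) != nrow(object@samples))
        msg <- c(msg, "zygosity columns must match number of samples")
    if (!all(z %in% 0:2))
        msg <- c(msg, "zygosity values must be 0, 1 or 2")
    need <- c("locus_id", "family", "source", "fixed")
    if (!all(need %in% names(mcols(gr))))
        msg <- c(msg, paste("truthLoci must carry metadata columns:",
                            paste(need, collapse = ", ")))
    else if (any(mcols(gr)$fixed) &&
             !all(z[mcols(gr)$fixed, , drop = FALSE] == 2L))
        msg <- c(msg, "fixed loci must be homozygous (2) in every individual")
    sl <- seqlengths(gr)
    if (!any(is.na(sl)) && length(gr) &&
        any(end(gr) > sl[as.character(seqnames(gr))]))
        msg <- c(msg, "loci must lie inside the declared chromosome lengths")
    if (length(msg)) msg else TRUE
})

#' Locus-by-individual ERV presence matrix
#'
#' A `RangedSummarizedExperiment` whose rows are ERV loci (as `GRanges` with
#' `locus_id`, `family` and `source` metadata), whose columns are individuals
#' (sample metadata in `colData`) and whose `"counts"` assay holds the number
#' of relaxed-filter identifications assigned to each locus in each
#' individual. For assembly-side loci the entry is a 0/1 presence indicator
#' derived from deletion evidence (deletion of the reference ERV implies
#' absence). `presenceBinary()` gives the thresholded 0/1 view used for
#' frequencies.
#'
#' @seealso [genotypePresence()], [presenceCounts()], [presenceBinary()]
#' @export
setClass("ErvPresence", contains = "RangedSummarizedExperiment")

setValidity("ErvPresence", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- assay(object, "counts")
        if (any(cnt < 0) || any(cnt != round(cnt)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    need <- c("locus_id", "family", "source")
    if (!all(need %in% names(mcols(rowRanges(object)))))
        msg <- c(msg, paste("rowRanges must carry metadata columns:",
                            paste(need, collapse = ", ")))
    if (!all(c("individual_id", "species") %in% names(colData(object))))
        msg <- c(msg, "colData must carry individual_id and species")
    if (length(msg)) msg else TRUE
})
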