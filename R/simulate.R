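## Synthetic cohort generator: truth loci with zygosity, species/island
## structure, and caller-style call tables produced through a coverage- and
## zygosity-dependent detection model.

#' Probability that a caller detects a locus in one individual
#'
#' Implements the three-regime detection model: absent loci (zygosity 0) are
#' never called; homozygous loci (zygosity 2) are called with constant
#' probability `1 - homMissProb`, independent of coverage; heterozygous loci
#' (zygosity 1) are called with probability interpolated linearly from
#' `hetSensitivityAt4x` at 4-fold coverage to 1.0 at `hetSaturationCoverage`,
#' clamped to [0, 1] and constant at 1.0 above saturation.
#'
#' @param zygosity integer vector of 0, 1 or 2 ERV copies.
#' @param coverage positive numeric, mean fold-coverage (recycled).
#' @param params a [SimulationParams-class] object.
#' @return numeric vector of detection probabilities.
#' @examples
#' p <- SimulationParams()
#' detectionProbability(1, 4, p)    # 0.45, i.e. 55% false-negative rate
#' detectionProbability(2, 12, p)   # 0.92 at any coverage
#' detectionProbability(1, 17, p)   # 0.725 by linear interpolation
#' @export
detectionProbability <- function(zygosity, coverage, params) {
    stopifnot(is(params, "SimulationParams"))
    if (any(!zygosity %in% 0:2))
        stop("zygosity must be 0, 1 or 2")
    if (any(!is.finite(coverage)) || any(coverage <= 0))
        stop("coverage must be positive")
    n <- max(length(zygosity), length(coverage))
    zygosity <- rep_len(zygosity, n)
    coverage <- rep_len(coverage, n)
    p <- numeric(n)
    p[zygosity == 2L] <- 1 - params@homMissProb
    het <- zygosity == 1L
    if (any(het)) {
        s4 <- params@hetSensitivityAt4x
        slope <- (1 - s4) / (params@hetSaturationCoverage - 4)
        p[het] <- pmin(1, pmax(0, s4 + (coverage[het] - 4) * slope))
    }
    p
}

## weighted draw of locus positions along one chromosome: a coarse grid keeps
## truth loci separated (so downstream merging cannot fuse two truth loci),
## jitter restores a continuous distribution.
.drawPositions <- function(n, chromLength, terminalFraction,
                           endEnrichmentFactor) {
    centers <- seq(500, chromLength - 500, by = 1000)
    if (n > length(centers))
        stop("more loci than available genome positions on a chromosome ",
             "of length ", chromLength)
    w <- ifelse(centers < terminalFraction * chromLength |
                centers > (1 - terminalFraction) * chromLength,
                endEnrichmentFactor, 1)
    pos <- sample(centers, n, prob = w) + round(stats::runif(n, -400, 400))
    sort(pmin(pmax(pos, 1), chromLength))
}

#' Simulate a multi-species, multi-island cohort with known ERV truth
#'
#' Generates sample metadata (species x island populations with uniform
#' per-individual coverage), a truth locus set and a per-individual zygosity
#' matrix. Ancestrally fixed loci are homozygous in every individual.
#' Polymorphic loci are assigned to a proper subset of species (post-dating
#' speciation), with a per-species base insertion frequency jittered per
#' island and genotypes drawn under Hardy-Weinberg proportions. A fraction of
#' polymorphic loci is represented assembly-side (present in the reference,
#' observable through deletion calls in non-carriers). Deterministic given
#' `seed`.
#'
#' @param params a [SimulationParams-class] object.
#' @param seed integer seed; defaults to `params@rngSeed`.
#' @return an [ErvSimulation-class] object.
#' @seealso [emitCallTables()] to derive caller-style tables.
#' @export
simulateCohort <- function(params, seed = params@rngSeed) {
    validObject(params)
    set.seed(seed)
    p <- params
    species <- sprintf("Species%02d", seq_len(p@nSpecies))
    islands <- sprintf("Island%s", LETTERS[seq_len(p@islandsPerSpecies)])

    samples <- expand.grid(island = islands, species = species,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    samples <- samples[rep(seq_len(nrow(samples)),
                           each = p@individualsPerPopulation),
                       c("species", "island")]
    samples$individual_id <- sprintf("%s.%s.%02d", samples$species,
                                     sub("Island", "", samples$island),
                                     seq_len(p@individualsPerPopulation))
    samples$is_hybrid <- FALSE
    samples$is_outgroup <- FALSE
    samples$mean_coverage <- stats::runif(nrow(samples),
                                          p@coverageRange[1],
                                          p@coverageRange[2])
    rownames(samples) <- NULL
    nInd <- nrow(samples)

    if (p@nFamilies > 850)
        stop("at most 850 distinct families supported")
    famNames <- sprintf("cPa%d", sample(100:950, p@nFamilies))
    famClades <- sample(c("AB1", "AB2", "GE", "S", "K", "E"),
                        p@nFamilies, replace = TRUE)
    famWeights <- stats::rgamma(p@nFamilies, shape = 0.7, rate = 1) + 1e-4

    nLoci <- p@nFixedLoci + p@nPolymorphicLoci
    chromProb <- p@chromLengths / sum(p@chromLengths)
    nPerChrom <- as.vector(stats::rmultinom(1, nLoci, chromProb))
    chrom <- rep(names(p@chromLengths), nPerChrom)
    pos <- unlist(lapply(seq_along(p@chromLengths), function(i)
        .drawPositions(nPerChrom[i], p@chromLengths[i],
                       p@terminalFraction, p@endEnrichmentFactor)),
        use.names = FALSE)

    famIdx <- sample(seq_len(p@nFamilies), nLoci, replace = TRUE,
                     prob = famWeights)
    fixed <- rep(FALSE, nLoci)
    fixed[sample(nLoci, p@nFixedLoci)] <- TRUE
    polyIdx <- which(!fixed)

    source <- rep("non_assembly", nLoci)
    dialect <- rep(NA_character_, nLoci)
    nAsm <- min(round(p@assemblyFraction * nLoci), length(polyIdx))
    if (nAsm > 0) {
        asmIdx <- sample(polyIdx, nAsm)
        source[asmIdx] <- "assembly"
        nSv <- round(p@svFractionOfAssembly * nAsm)
        svIdx <- if (nSv > 0) sample(asmIdx, nSv) else integer()
        dialect[asmIdx] <- "cnv"
        dialect[svIdx] <- "sv"
    }

    width <- rep(1L, nLoci)
    isAsm <- source == "assembly"
    width[isAsm] <- sample(200:3000, sum(isAsm), replace = TRUE)
    endPos <- pmin(pos + width - 1L, p@chromLengths[chrom])

    zyg <- matrix(0L, nrow = nLoci, ncol = nInd)
    zyg[fixed, ] <- 2L
    popIndex <- split(seq_len(nInd), paste(samples$species, samples$island))
    enrich <- function(sp, fam) {
        e <- p@familyEnrichment[[sp]]
        if (is.null(e)) 1 else (e[[fam]] %||% 1)
    }
    kmax <- max(1L, p@nSpecies - 1L)
    for (j in polyIdx) {
        fam <- famNames[famIdx[j]]
        wsp <- vapply(species, enrich, numeric(1), fam = fam)
        k <- min(1L + stats::rgeom(1, 0.6), kmax)
        carriers <- sample(species, k, prob = wsp)
        for (sp in carriers) {
            qs <- stats::runif(1, 0.1, 0.9)
            for (isl in islands) {
                q <- min(max(qs + stats::runif(1, -0.15, 0.15), 0.02), 0.98)
                idx <- popIndex[[paste(sp, isl)]]
                zyg[j, idx] <- stats::rbinom(length(idx), 2L, q)
            }
        }
    }
    colnames(zyg) <- samples$individual_id

    serial <- stats::ave(seq_len(nLoci), famIdx, FUN = seq_along)
    gr <- GRanges(chrom, IRanges(pos, endPos),
                  seqinfo = Seqinfo(names(p@chromLengths),
                                    seqlengths = p@chromLengths))
    mcols(gr) <- DataFrame(
        locus_id = sprintf("ERV-%s.%s.%d", famClades[famIdx],
                           famNames[famIdx], serial),
        family = famNames[famIdx],
        clade = famClades[famIdx],
        source = source,
        dialect = dialect,
        fixed = fixed)
    rownames(zyg) <- mcols(gr)$locus_id

    new("ErvSimulation", truthLoci = gr, zygosity = zyg,
        samples = samples, params = p)
}

#' Emit caller-style call tables from a simulated cohort
#'
#' For every individual and truly carried non-assembly locus, an insertion
#' call is emitted with probability [detectionProbability()]; emitted calls
#' carry filter fields that pass the stringent cascade with probability
#' `stringentPassProb` and always pass the relaxed one. Assembly-side loci
#' yield deletion calls in the read-depth (cnv) dialect for homozygous
#' non-carriers, or genotyped split-read (sv) deletion records (genotype 1 =
#' heterozygous deletion, 2 = homozygous deletion), plus matching
#' ERV-similarity blocks. Insertion calls include a `truth_locus_id` column
#' (simulation provenance, used to score sensitivity against truth; I/O
#' writers drop it).
#'
#' @param sim an [ErvSimulation-class] object.
#' @param seed integer seed; defaults to the simulation seed offset by 1000.
#' @return list with elements `insertions`, `cnv_deletions`, `sv_deletions`
#'   (data frames in the internal 1-based closed convention),
#'   `similarity_blocks` (`GRanges` with a `family` column) and `samples`.
#' @export
emitCallTables <- function(sim, seed = simParams(sim)@rngSeed + 1000L) {
    stopifnot(is(sim, "ErvSimulation"))
    set.seed(seed)
    p <- simParams(sim)
    gr <- truthLoci(sim)
    zyg <- truthZygosity(sim)
    samples <- sampleInfo(sim)
    nInd <- nrow(samples)
    cov <- samples$mean_coverage

    naIdx <- which(mcols(gr)$source == "non_assembly")
    ins <- data.frame(individual_id = character(), chrom = character(),
                      pos = integer(), family = character(),
                      filter_level = integer(), genotype_quality = numeric(),
                      clip5 = integer(), clip3 = integer(),
                      support_reads = integer(),
                      truth_locus_id = character())
    if (length(naIdx)) {
        Z <- zyg[naIdx, , drop = FALSE]
        P <- matrix(0, nrow(Z), ncol(Z))
        P[Z == 2L] <- 1 - p@homMissProb
        het <- Z == 1L
        if (any(het)) {
            covm <- matrix(cov, nrow(Z), ncol(Z), byrow = TRUE)
            P[het] <- detectionProbability(1L, covm[het], p)
        }
        det <- which(matrix(stats::runif(length(P)), nrow(P)) < P,
                     arr.ind = TRUE)
        if (nrow(det)) {
            li <- naIdx[det[, 1L]]
            ii <- det[, 2L]
            n <- length(li)
            stringent <- stats::runif(n) < p@stringentPassProb
            ins <- data.frame(
                individual_id = samples$individual_id[ii],
                chrom = as.character(seqnames(gr))[li],
                pos = pmax(1L, start(gr)[li] +
                               sample(-10:10, n, replace = TRUE)),
                family = mcols(gr)$family[li],
                filter_level = ifelse(stringent, 8L,
                                      sample(5:7, n, replace = TRUE)),
                genotype_quality = round(ifelse(stringent,
                                                stats::runif(n, 10, 200),
                                                stats::runif(n, 1, 250)), 2),
                clip5 = ifelse(stringent, 2L, sample(0:2, n, replace = TRUE)),
                clip3 = ifelse(stringent, 2L, sample(0:2, n, replace = TRUE)),
                support_reads = ifelse(stringent,
                                       sample(5:30, n, replace = TRUE),
                                       sample(1:4, n, replace = TRUE)),
                truth_locus_id = mcols(gr)$locus_id[li])
        }
    }

    emitDeletions <- function(dialectName) {
        idx <- which(mcols(gr)$source == "assembly" &
                     mcols(gr)$dialect == dialectName)
        rows <- list()
        for (j in idx) {
            carriers0 <- if (dialectName == "cnv") which(zyg[j, ] == 0L)
                         else which(zyg[j, ] %in% c(0L, 1L))
            if (!length(carriers0)) next
            n <- length(carriers0)
            L <- seqlengths(gr)[as.character(seqnames(gr)[j])]
            st <- pmax(1L, start(gr)[j] - sample(0:50, n, replace = TRUE))
            en <- pmin(L, end(gr)[j] + sample(0:50, n, replace = TRUE))
            stringent <- stats::runif(n) < p@stringentPassProb
            rows[[length(rows) + 1L]] <- data.frame(
                individual_id = samples$individual_id[carriers0],
                chrom = as.character(seqnames(gr)[j]),
                start = st, end = en,
                dialect = dialectName,
                eval1 = if (dialectName == "cnv")
                            round(ifelse(stringent,
                                         stats::runif(n, 0, 0.05),
                                         stats::runif(n, 0.06, 1)), 5)
                        else NA_real_,
                eval2 = if (dialectName == "cnv")
                            round(stats::runif(n, 0, 0.05), 5)
                        else NA_real_,
                support_reads = if (dialectName == "sv")
                                    sample(2:20, n, replace = TRUE)
                                else NA_integer_,
                genotype = if (dialectName == "sv")
                               ifelse(zyg[j, carriers0] == 0L, 2L, 1L)
                           else NA_integer_,
                truth_locus_id = mcols(gr)$locus_id[j])
        }
        if (length(rows)) do.call(rbind, rows)
        else data.frame(individual_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        dialect = character(), eval1 = numeric(),
                        eval2 = numeric(), support_reads = integer(),
                        genotype = integer(), truth_locus_id = character())
    }

    asm <- gr[mcols(gr)$source == "assembly"]
    blocks <- GRanges(seqnames(asm),
                      IRanges(pmax(1L, start(asm) - 100L),
                              pmin(seqlengths(asm)[as.character(seqnames(asm))],
                                   end(asm) + 100L)))
    mcols(blocks)$family <- mcols(asm)$family

    list(insertions = ins,
         cnv_deletions = emitDeletions("cnv"),
         sv_deletions = emitDeletions("sv"),
         similarity_blocks = blocks,
         samples = samples)
}
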