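## Independent oracles and fixture builders used across the suite.
suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

## O(n^2) pairwise interval union (closed intervals, >= 1 shared position):
## repeatedly merge any overlapping pair until a fixed point.
bruteUnion <- function(starts, ends) {
    st <- as.numeric(starts)
    en <- as.numeric(ends)
    repeat {
        merged <- FALSE
        n <- length(st)
        for (i in seq_len(n - 1L)) {
            for (j in (i + 1L):n) {
                if (max(st[i], st[j]) <= min(en[i], en[j])) {
                    st[i] <- min(st[i], st[j])
                    en[i] <- max(en[i], en[j])
                    st <- st[-j]; en <- en[-j]
                    merged <- TRUE
                    break
                }
            }
            if (merged) break
        }
        if (!merged) break
    }
    ord <- order(st)
    cbind(start = st[ord], end = en[ord])
}

## textbook Welch statistic with Satterthwaite degrees of freedom
welchOracle <- function(x, y) {
    vx <- var(x) / length(x)
    vy <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## direct between/within mean-square computation
anovaOracle <- function(groups) {
    N <- sum(lengths(groups))
    k <- length(groups)
    gm <- mean(unlist(groups))
    ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - gm)^2)
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
    F <- (ssb / (k - 1)) / (ssw / (N - k))
    list(F = F, df1 = k - 1, df2 = N - k,
         p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

## random insertion-call table spanning pass/fail space of both cascades
randomCalls <- function(n) {
    data.frame(
        individual_id = sample(sprintf("bird%02d", 1:6), n, replace = TRUE),
        chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
        pos = sample(1:50000, n, replace = TRUE),
        family = sample(c("cPa1", "cPa2", "cPa3"), n, replace = TRUE),
        filter_level = sample(1:8, n, replace = TRUE),
        genotype_quality = round(runif(n, 0, 250), 1),
        clip5 = sample(0:3, n, replace = TRUE),
        clip3 = sample(0:3, n, replace = TRUE),
        support_reads = sample(0:12, n, replace = TRUE))
}

## minimal insertion-call row with stringent-passing defaults
insCall <- function(individual_id = "bird1", chrom = "chr1", pos = 1000,
                    family = "cPa1", filter_level = 8L,
                    genotype_quality = 50, clip5 = 2L, clip3 = 2L,
                    support_reads = 5L) {
    data.frame(individual_id, chrom, pos, family, filter_level,
               genotype_quality, clip5, clip3, support_reads)
}

delCall <- function(individual_id = "bird1", chrom = "chr1", start = 1000L,
                    end = 2000L, dialect = "cnv", eval1 = 0.01,
                    eval2 = 0.01, support_reads = NA_integer_,
                    genotype = NA_integer_) {
    data.frame(individual_id, chrom, start, end, dialect, eval1, eval2,
               support_reads, genotype)
}

## hand-built simulation: one species, every individual heterozygous (or as
## given) at regularly spaced loci; bypasses the cohort generator so the
## detection model can be probed in isolation
makeManualSim <- function(zyg, coverage, params = SimulationParams()) {
    nLoci <- nrow(zyg)
    nInd <- ncol(zyg)
    chromLen <- max(nLoci * 1000 + 2000, 1e6)
    params@chromLengths <- c(chrT = chromLen)
    gr <- GRanges("chrT", IRanges(seq_len(nLoci) * 1000, width = 1),
                  seqinfo = Seqinfo("chrT", chromLen))
    mcols(gr) <- S4Vectors::DataFrame(
        locus_id = sprintf("ERV-T.cPaT.%d", seq_len(nLoci)),
        family = "cPaT", clade = "T", source = "non_assembly",
        dialect = NA_character_, fixed = FALSE)
    samples <- data.frame(
        individual_id = sprintf("m%03d", seq_len(nInd)),
        species = "SpeciesM", island = "IslandA",
        is_hybrid = FALSE, is_outgroup = FALSE,
        mean_coverage = rep_len(coverage, nInd))
    dimnames(zyg) <- list(mcols(gr)$locus_id, samples$individual_id)
    new("ErvSimulation", truthLoci = gr, zygosity = zyg,
        samples = samples, params = params)
}

## full pipeline from emitted tables to an ErvPresence object
runPipeline <- function(tables, params, extensionBp = 50L) {
    ins_s <- filterInsertionsStringent(tables$insertions)
    ins_r <- filterInsertionsRelaxed(tables$insertions)
    nonAsm <- mergeInsertionLoci(ins_s, extensionBp = extensionBp,
                                 chromLengths = params@chromLengths)
    dels <- rbind(tables$cnv_deletions, tables$sv_deletions)
    dels$truth_locus_id <- NULL
    asm <- NULL
    if (nrow(dels)) {
        ann_s <- annotateWithSimilarity(filterDeletions(dels, "stringent"),
                                        tables$similarity_blocks)
        if (nrow(ann_s)) asm <- buildAssemblyLoci(ann_s)
    }
    loci <- unifyLocusFrame(nonAsm, asm)
    dels_r <- annotateWithSimilarity(filterDeletions(dels, "relaxed"),
                                     tables$similarity_blocks)
    pres <- genotypePresence(loci, ins_r, dels_r, tables$samples,
                             extensionBp = extensionBp)
    pres
}
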