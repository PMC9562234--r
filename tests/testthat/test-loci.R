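test_that("insertion calls extend to 101-bp windows and union transitively", {
    two <- rbind(insCall(pos = 100), insCall(pos = 180))
    loci <- mergeInsertionLoci(two)
    expect_equal(length(loci), 1L)          # [50,150] and [130,230] overlap
    expect_equal(start(loci), 50L)
    expect_equal(end(loci), 230L)

    single <- mergeInsertionLoci(insCall(pos = 100))
    expect_equal(width(single), 101L)
    expect_equal(c(start(single), end(single)), c(50L, 150L))

    twoFar <- rbind(insCall(pos = 100), insCall(pos = 300))
    expect_equal(length(mergeInsertionLoci(twoFar)), 2L)

    ## touching, non-overlapping windows stay apart
    touching <- rbind(insCall(pos = 100), insCall(pos = 201))
    expect_equal(length(mergeInsertionLoci(touching)), 2L)

    clamped <- mergeInsertionLoci(insCall(pos = 10))
    expect_equal(start(clamped), 1L)        # clamp at chromosome start
    expect_equal(end(clamped), 60L)
})

test_that("locus family is the majority call family with deterministic ties", {
    calls <- rbind(insCall(pos = 100, family = "cPaB"),
                   insCall(pos = 120, family = "cPaA"),
                   insCall(pos = 140, family = "cPaA"))
    expect_identical(mcols(mergeInsertionLoci(calls))$family, "cPaA")

    tied <- rbind(insCall(pos = 120, family = "cPaZ"),
                  insCall(pos = 100, family = "cPaB"))
    ## tie broken by earliest call position
    expect_identical(mcols(mergeInsertionLoci(tied))$family, "cPaB")
})

test_that("interval union equals the O(n^2) brute-force oracle", {
    set.seed(404)
    for (rep in 1:200) {
        n <- sample(2:12, 1)
        pos <- sample(1:3000, n, replace = TRUE)
        calls <- insCall(pos = 1)[rep(1, n), ]
        calls$pos <- pos
        loci <- mergeInsertionLoci(calls)
        oracle <- bruteUnion(pmax(1, pos - 50), pos + 50)
        expect_equal(start(loci), as.integer(oracle[, "start"]))
        expect_equal(end(loci), as.integer(oracle[, "end"]))
    }
})

test_that("locus construction is invariant to call order", {
    set.seed(505)
    calls <- randomCalls(100)
    a <- mergeInsertionLoci(calls)
    b <- mergeInsertionLoci(calls[sample(nrow(calls)), ])
    expect_equal(granges(a), granges(b))
    expect_identical(mcols(a)$family, mcols(b)$family)
})

test_that("assembly loci union deletions per dialect and counts add", {
    dels <- rbind(delCall(individual_id = "b1", start = 101L, end = 400L),
                  delCall(individual_id = "b2", start = 351L, end = 600L))
    dels$family <- "cPa9"
    loci <- buildAssemblyLoci(dels)
    expect_equal(length(loci), 1L)
    expect_equal(c(start(loci), end(loci)), c(101L, 600L))
    expect_identical(mcols(loci)$source, "assembly")

    one <- delCall(start = 500L, end = 900L)
    one$family <- "cPa9"
    lone <- buildAssemblyLoci(one)
    expect_equal(c(start(lone), end(lone)), c(500L, 900L))

    svRow <- delCall(individual_id = "b3", start = 5000L, end = 5400L,
                     dialect = "sv", support_reads = 4L, genotype = 2L)
    svRow$family <- "cPa7"
    mixed <- rbind(dels, svRow)
    both <- buildAssemblyLoci(mixed)
    cnvOnly <- buildAssemblyLoci(mixed[mixed$dialect == "cnv", ])
    svOnly <- buildAssemblyLoci(mixed[mixed$dialect == "sv", ])
    expect_equal(length(both), length(cnvOnly) + length(svOnly))
})

test_that("unified locus frame concatenates sources with stable unique ids", {
    na <- GRanges("chr1", IRanges(c(1, 500, 900), width = 101))
    mcols(na)$family <- c("cPa1", "cPa1", "cPa2")
    mcols(na)$source <- "non_assembly"
    asm <- GRanges("chr1", IRanges(c(2000, 3000), width = 300))
    mcols(asm)$family <- c("cPa2", "cPa3")
    mcols(asm)$source <- "assembly"
    mcols(asm)$dialect <- c("cnv", "sv")

    uni <- unifyLocusFrame(na, asm)
    expect_equal(length(uni), 5L)
    expect_equal(anyDuplicated(mcols(uni)$locus_id), 0L)
    expect_equal(sum(mcols(uni)$source == "assembly"), 2L)
    expect_match(mcols(uni)$locus_id, "^ERV-[A-Za-z0-9]+\\.cPa\\d+\\.\\d+$",
                 all = TRUE)

    alone <- unifyLocusFrame(na, NULL)
    expect_equal(length(alone), 3L)

    dup <- na
    mcols(dup)$locus_id <- c("X", "X", "Y")
    expect_error(unifyLocusFrame(dup, NULL), "collision")
})

test_that("presence counting follows relaxed calls and deletion genotypes", {
    loci <- GRanges("chr1", IRanges(c(50, 5000), c(150, 5400)))
    mcols(loci) <- S4Vectors::DataFrame(
        locus_id = c("L1", "A1"), family = c("cPa1", "cPa9"),
        source = c("non_assembly", "assembly"),
        dialect = c(NA, "sv"))
    samples <- data.frame(
        individual_id = c("bird1", "bird2", "bird3", "bird4"),
        species = "A", island = "x", is_hybrid = FALSE,
        is_outgroup = FALSE, mean_coverage = 20)

    ins <- rbind(insCall(individual_id = "bird1", pos = 95),
                 insCall(individual_id = "bird1", pos = 105))
    dels <- rbind(
        delCall(individual_id = "bird3", start = 5100L, end = 5300L,
                dialect = "sv", support_reads = 5L, genotype = 2L),
        delCall(individual_id = "bird4", start = 5100L, end = 5300L,
                dialect = "sv", support_reads = 5L, genotype = 1L))
    pres <- genotypePresence(loci, ins, dels, samples)
    cnt <- presenceCounts(pres)
    expect_equal(cnt["L1", "bird1"], 2L)    # two relaxed hits
    expect_equal(cnt["L1", "bird2"], 0L)
    expect_equal(presenceBinary(pres)["L1", "bird1"], 1L)
    ## sv genotype truth table: 0 (no record) and 1 carry, 2 does not
    expect_equal(cnt["A1", "bird1"], 1L)
    expect_equal(cnt["A1", "bird3"], 0L)    # homozygous deletion
    expect_equal(cnt["A1", "bird4"], 1L)    # het deletion keeps one copy
    ## cnv deletion marks absence regardless of genotype
    delsCnv <- delCall(individual_id = "bird2", start = 5100L, end = 5300L)
    mcols(loci)$dialect[2] <- "cnv"
    pres2 <- genotypePresence(loci, ins, delsCnv, samples)
    expect_equal(presenceCounts(pres2)["A1", "bird2"], 0L)

    bad <- insCall(individual_id = "ghost", pos = 95)
    expect_error(genotypePresence(loci, bad, NULL, samples), "ghost")
})

test_that("perfect detection recovers the truth carrier matrix exactly", {
    p <- SimulationParams(nSpecies = 3L, islandsPerSpecies = 2L,
                          individualsPerPopulation = 5L, nFixedLoci = 40L,
                          nPolymorphicLoci = 160L, homMissProb = 0,
                          hetSensitivityAt4x = 1, stringentPassProb = 1,
                          rngSeed = 31L)
    sim <- simulateCohort(p)
    tb <- emitCallTables(sim)
    pres <- runPipeline(tb, p)

    truth <- truthLoci(sim)
    built <- rowRanges(pres)
    hits <- findOverlaps(built, truth)
    ## every built locus maps to exactly one truth locus
    expect_equal(length(hits), length(built))
    carrier <- (truthZygosity(sim) > 0) * 1L
    b <- presenceBinary(pres)
    expect_equal(unname(b[queryHits(hits), ]),
                 unname(carrier[subjectHits(hits), ]))
    ## and every carried truth locus was built
    carried <- rowSums(carrier) > 0
    expect_equal(length(built), sum(carried))
    ## species frequencies equal truth frequencies exactly
    freq <- speciesFrequency(pres)
    sp <- factor(sampleInfo(sim)$species)
    truthFreq <- t(rowsum(t(carrier), sp)) /
        matrix(table(sp), nrow(carrier), nlevels(sp), byrow = TRUE)
    expect_equal(unname(freq[queryHits(hits), ]),
                 unname(truthFreq[subjectHits(hits), ]))
})
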