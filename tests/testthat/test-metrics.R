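## small hand-built presence object shared by the metric tests
makeTinyPresence <- function(counts, families, species,
                             island = NULL, hybrid = NULL, outgroup = NULL,
                             coverage = NULL, source = NULL) {
    n <- nrow(counts)
    loci <- GRanges("chr1", IRanges(seq_len(n) * 1000, width = 101))
    mcols(loci) <- S4Vectors::DataFrame(
        locus_id = sprintf("L%02d", seq_len(n)),
        family = families,
        source = source %||% rep("non_assembly", n),
        dialect = NA_character_)
    m <- ncol(counts)
    samples <- data.frame(
        individual_id = sprintf("b%02d", seq_len(m)),
        species = species,
        island = island %||% rep("x", m),
        is_hybrid = hybrid %||% rep(FALSE, m),
        is_outgroup = outgroup %||% rep(FALSE, m),
        mean_coverage = coverage %||% rep(20, m))
    ErvPresence(counts, loci, samples)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("group frequency is the detected fraction of individuals", {
    cnt <- matrix(c(1L, 1L, 1L, 0L,
                    0L, 0L, 0L, 0L), nrow = 2, byrow = TRUE)
    pres <- makeTinyPresence(cnt, c("cPa1", "cPa1"), rep("A", 4))
    freq <- speciesFrequency(pres)
    expect_equal(unname(freq[, "A"]), c(0.75, 0))

    cntAll <- matrix(1L, 3, 6)
    presAll <- makeTinyPresence(cntAll, rep("cPa1", 3),
                                rep(c("A", "B"), each = 3))
    expect_true(all(speciesFrequency(presAll) == 1))
})

test_that("fixed-locus calibration turns mean frequency into an FN rate", {
    ## arithmetic: mean fixed frequency 0.92 -> false-negative rate 0.08
    freq <- matrix(c(0.92, 0.92, 0.92,
                     0.95, 0.89, 0.92,
                     0.00, 0.50, 0.70), nrow = 3, byrow = TRUE,
                   dimnames = list(c("L1", "L2", "L3"), c("A", "B", "C")))
    samples <- data.frame(individual_id = sprintf("b%d", 1:3),
                          species = c("A", "B", "C"),
                          is_hybrid = FALSE, is_outgroup = FALSE)
    cal <- fixedLocusCalibration(freq, samples)
    expect_setequal(cal$fixed_locus_ids, c("L1", "L2"))
    expect_equal(cal$mean_fixed_frequency, 0.92)
    expect_equal(cal$false_negative_rate, 0.08)

    ## hybrids are outside the default scope, outgroups inside
    freqH <- cbind(freq, H = c(0, 0, 0))
    samplesH <- rbind(samples,
                      data.frame(individual_id = "b4", species = "H",
                                 is_hybrid = TRUE, is_outgroup = FALSE))
    calH <- fixedLocusCalibration(freqH, samplesH)
    expect_setequal(calH$groups, c("A", "B", "C"))
    calOnly <- fixedLocusCalibration(
        freqH, transform(samplesH, is_outgroup = species == "C"),
        scope = "species_only")
    expect_setequal(calOnly$groups, c("A", "B"))

    ## no candidates -> undefined rate, empty id set
    none <- fixedLocusCalibration(
        matrix(c(0, 1), 1, 2, dimnames = list("L1", c("A", "B"))), samples)
    expect_length(none$fixed_locus_ids, 0)
    expect_true(is.na(none$false_negative_rate))
})

test_that("calibration is exact under perfect detection", {
    p <- SimulationParams(nSpecies = 3L, individualsPerPopulation = 4L,
                          nFixedLoci = 30L, nPolymorphicLoci = 100L,
                          homMissProb = 0, hetSensitivityAt4x = 1,
                          stringentPassProb = 1, rngSeed = 77L)
    sim <- simulateCohort(p)
    pres <- runPipeline(emitCallTables(sim), p)
    cal <- fixedLocusCalibration(speciesFrequency(pres), sampleInfo(sim))
    expect_equal(cal$false_negative_rate, 0)
    expect_equal(length(cal$fixed_locus_ids), 30L)
})

test_that("relative abundance normalises per individual", {
    cnt <- matrix(c(3L, 2L,
                    1L, 0L), nrow = 2, byrow = TRUE)
    pres <- makeTinyPresence(cnt, c("famA", "famB"), c("A", "A"))
    ab <- relativeAbundance(pres)
    expect_equal(unname(ab["b01", c("famA", "famB")]), c(0.75, 0.25))
    expect_equal(unname(ab["b02", "famA"]), 1)

    ## rows sum to one on random count matrices
    set.seed(606)
    for (rep in 1:10) {
        cntR <- matrix(rpois(8 * 5, 2), 8, 5)
        cntR[, 1] <- cntR[, 1] + 1L   # guard a non-zero first individual
        presR <- makeTinyPresence(cntR, sample(c("f1", "f2", "f3"), 8,
                                               replace = TRUE),
                                  rep("A", 5))
        abR <- relativeAbundance(presR)
        ok <- !is.na(abR[, 1])
        expect_equal(unname(rowSums(abR[ok, , drop = FALSE])),
                     rep(1, sum(ok)))
    }

    zero <- makeTinyPresence(matrix(c(1L, 0L), 1, 2), "famA", c("A", "A"))
    expect_warning(abZ <- relativeAbundance(zero), "b02")
    expect_true(is.na(abZ["b02", "famA"]))
})

test_that("MIR identities hold and ratios are computed from medians", {
    ## a single group is its own reference pool: MIR is exactly 1
    cnt <- matrix(rpois(6 * 8, 3) + 1L, 6, 8)
    pres <- makeTinyPresence(cnt, rep(c("f1", "f2"), 3), rep("A", 8))
    ab <- relativeAbundance(pres)
    mir <- computeMIR(ab, sampleInfo(pres))
    expect_equal(unname(mir[, "A"]), rep(1, 2))

    ## direct ratio of medians: 0.08 / 0.053
    abM <- matrix(c(0.08, 0.92,
                    0.08, 0.92,
                    0.053, 0.947,
                    0.05, 0.95,
                    0.04, 0.96), ncol = 2, byrow = TRUE,
                  dimnames = list(sprintf("b%02d", 1:5), c("fX", "fY")))
    sm <- data.frame(individual_id = sprintf("b%02d", 1:5),
                     species = c("G", "G", "O", "O", "O"),
                     island = "x")
    mir2 <- computeMIR(abM, sm)
    expect_equal(unname(mir2["fX", "G"]), 0.08 / 0.053, tolerance = 1e-12)
    expect_equal(round(unname(mir2["fX", "G"]), 2), 1.51)

    ## modified MIR: a species with a single island is exactly 1
    smIsl <- data.frame(individual_id = sprintf("b%02d", 1:5),
                        species = c("G", "G", "O", "O", "O"),
                        island = c("i1", "i1", "i2", "i2", "i2"))
    mmir <- computeMIR(abM, smIsl, grouping = "species_island")
    expect_equal(unname(mmir[, "G|i1"]), rep(1, 2))
    expect_equal(unname(mmir[, "O|i2"]), rep(1, 2))

    ## zero reference median -> missing entry
    abZ <- matrix(c(0, 0, 0.5, 0.4), ncol = 1,
                  dimnames = list(sprintf("b%02d", 1:4), "fZ"))
    smZ <- data.frame(individual_id = sprintf("b%02d", 1:4),
                      species = c("A", "A", "B", "B"), island = "x")
    mirZ <- computeMIR(abZ, smZ)
    expect_true(is.na(mirZ["fZ", "A"]) || mirZ["fZ", "A"] == 0)
})

test_that("MIR is invariant to individual ordering", {
    set.seed(707)
    ab <- matrix(runif(12 * 3), 12, 3,
                 dimnames = list(sprintf("b%02d", 1:12), c("f1", "f2", "f3")))
    ab <- ab / rowSums(ab)
    sm <- data.frame(individual_id = sprintf("b%02d", 1:12),
                     species = rep(c("A", "B", "C"), each = 4),
                     island = rep(c("i", "j"), 6))
    perm <- sample(12)
    expect_equal(computeMIR(ab, sm), computeMIR(ab[perm, ], sm))
    expect_equal(computeMIR(ab, sm, "species_island"),
                 computeMIR(ab[perm, ], sm, "species_island"))
})

test_that("family regression recovers exact and noisy correlations", {
    ## families on an exact line y = 2x -> r^2 = 1
    nLociPerFam <- c(f1 = 2L, f2 = 4L, f3 = 6L, f4 = 8L)
    fams <- rep(names(nLociPerFam), nLociPerFam)
    cnt <- matrix(2L, length(fams), 1)   # every locus contributes 2 calls
    pres <- makeTinyPresence(cnt, fams, "A")
    fit <- lociVsIdentificationsFit(pres)
    expect_equal(fit$r_squared, 1)
    expect_equal(fit$slope, 2)

    ## bivariate normal with rho = 0.9 -> r^2 near 0.81
    set.seed(808)
    n <- 500
    x <- rnorm(n)
    y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n)
    s <- summary(lm(y ~ x))
    ## Fisher-z 3-s.e. band for the correlation at n = 500
    zse <- 3 / sqrt(n - 3)
    lo <- tanh(atanh(0.9) - zse)^2
    hi <- tanh(atanh(0.9) + zse)^2
    expect_gt(s$r.squared, lo)
    expect_lt(s$r.squared, hi)

    twoFam <- makeTinyPresence(matrix(c(1L, 2L, 2L), 3, 1),
                               c("f1", "f2", "f2"), "A")
    expect_warning(fit2 <- lociVsIdentificationsFit(twoFam), "degenerate")
    expect_equal(fit2$r_squared, 1)
})

test_that("coverage regression flags coverage-limited detection", {
    ## coverage-linear het model: more calls in higher-coverage individuals
    p <- SimulationParams(nSpecies = 2L, islandsPerSpecies = 1L,
                          individualsPerPopulation = 100L,
                          nFixedLoci = 0L, nPolymorphicLoci = 400L,
                          coverageRange = c(4, 30), rngSeed = 13L)
    sim <- simulateCohort(p)
    pres <- runPipeline(emitCallTables(sim), p)
    fit <- detectionVsCoverageFit(pres, character(), use = "total_calls")
    expect_gt(fit$slope, 0)
    expect_lt(fit$p_value, 0.01)

    ## no coverage effect under perfect detection at fixed loci
    pPerf <- SimulationParams(nSpecies = 2L, islandsPerSpecies = 1L,
                              individualsPerPopulation = 10L,
                              nFixedLoci = 50L, nPolymorphicLoci = 50L,
                              homMissProb = 0, hetSensitivityAt4x = 1,
                              stringentPassProb = 1, rngSeed = 19L)
    simP <- simulateCohort(pPerf)
    presP <- runPipeline(emitCallTables(simP), pPerf)
    cal <- fixedLocusCalibration(speciesFrequency(presP), sampleInfo(simP))
    fitP <- detectionVsCoverageFit(presP, cal$fixed_locus_ids)
    expect_lt(abs(fitP$slope), 1e-12)

    same <- makeTinyPresence(matrix(1L, 2, 4), c("f1", "f1"),
                             rep("A", 4), coverage = rep(10, 4))
    expect_error(detectionVsCoverageFit(same, "L01"), "variance")
})
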