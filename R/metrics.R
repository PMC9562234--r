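## Population metrics: per-group locus detection frequencies, fixed-locus
## false-negative calibration, per-individual relative family abundance,
## median identification ratios (MIR), and the two diagnostic regressions.

#' Per-group locus detection frequency
#'
#' Frequency is the individual-level detection frequency: the fraction of a
#' group's individuals with binary presence 1 at the locus (not an allele
#' frequency -- presence calls carry no zygosity).
#'
#' @param presence an [ErvPresence-class] object.
#' @param by `"species"` or `"species_island"` (groups formed as
#'   `species|island`).
#' @return numeric matrix, loci x groups, values in [0, 1].
#' @export
speciesFrequency <- function(presence, by = c("species", "species_island")) {
    by <- match.arg(by)
    s <- sampleInfo(presence)
    groups <- switch(by,
                     species = s$species,
                     species_island = paste(s$species, s$island, sep = "|"))
    if (any(is.na(groups) | !nzchar(groups)))
        stop("every individual must be mapped to a non-empty group")
    fg <- factor(groups)
    b <- presenceBinary(presence)
    sums <- t(rowsum(t(b), fg))
    sizes <- as.integer(table(fg))
    freq <- sweep(sums, 2, sizes, "/")
    dimnames(freq) <- list(rownames(b), levels(fg))
    freq
}

#' Calibrate the detection false-negative rate from fixed loci
#'
#' Loci detected at least once in every in-scope group are taken as
#' ancestrally fixed candidates (expected homozygous in every individual, so
#' their expected detection frequency is 1.0). The shortfall of their mean
#' observed frequency from 1.0 estimates the false-negative rate of the
#' detection method for homozygous loci: `FN = 1 - mean fixed frequency`,
#' where the mean is the grand mean over candidate loci of the per-group
#' frequencies.
#'
#' @param freq frequency matrix from [speciesFrequency()] (grouped by
#'   species).
#' @param samples sample metadata with `species`, `is_hybrid`,
#'   `is_outgroup` columns, used to resolve the scope.
#' @param scope which groups count towards "present in all":
#'   `"species_plus_outgroups"` (default; hybrid groups excluded),
#'   `"species_only"`, or `"all_groups"`.
#' @return object of class `ervCalibration`: list with `fixed_locus_ids`,
#'   `mean_fixed_frequency`, `false_negative_rate`, `groups`.
#' @export
fixedLocusCalibration <- function(freq, samples,
                                  scope = c("species_plus_outgroups",
                                            "species_only", "all_groups")) {
    scope <- match.arg(scope)
    hyb <- tapply(samples$is_hybrid, samples$species, any)
    outg <- tapply(samples$is_outgroup %||% FALSE, samples$species, any)
    keep <- switch(scope,
                   all_groups = names(hyb),
                   species_plus_outgroups = names(hyb)[!hyb],
                   species_only = names(hyb)[!hyb & !outg])
    inscope <- intersect(colnames(freq), keep)
    if (!length(inscope))
        stop("no group in the frequency table matches scope '", scope, "'")
    sub <- freq[, inscope, drop = FALSE]
    cand <- rownames(sub)[rowSums(sub > 0) == length(inscope)]
    if (!length(cand)) {
        res <- list(fixed_locus_ids = character(),
                    mean_fixed_frequency = NA_real_,
                    false_negative_rate = NA_real_,
                    groups = inscope)
    } else {
        mf <- mean(rowMeans(sub[cand, , drop = FALSE]))
        res <- list(fixed_locus_ids = cand,
                    mean_fixed_frequency = mf,
                    false_negative_rate = 1 - mf,
                    groups = inscope)
    }
    class(res) <- "ervCalibration"
    res
}

#' @export
print.ervCalibration <- function(x, ...) {
    cat("Fixed-locus calibration over", length(x$groups), "groups\n")
    cat("  fixed candidates:", length(x$fixed_locus_ids), "\n")
    if (is.na(x$false_negative_rate)) {
        cat("  no fixed candidates; rate undefined\n")
    } else {
        cat(sprintf("  mean fixed frequency: %.4f\n",
                    x$mean_fixed_frequency))
        cat(sprintf("  false-negative rate:  %.4f\n",
                    x$false_negative_rate))
    }
    invisible(x)
}

#' Per-individual relative ERV family abundance
#'
#' For each individual, the number of identifications of each family
#' (summed identification counts over that family's loci) divided by the
#' individual's total identifications; rows sum to 1. Individuals with zero
#' total identifications get a missing row with a warning.
#'
#' @param presence an [ErvPresence-class] object.
#' @param use `"counts"` (identification counts, default) or `"binary"`
#'   (presence indicators) as the numerator material.
#' @return numeric matrix, individuals x families.
#' @export
relativeAbundance <- function(presence, use = c("counts", "binary")) {
    use <- match.arg(use)
    m <- if (use == "counts") presenceCounts(presence)
         else presenceBinary(presence)
    fam <- as.character(mcols(rowRanges(presence))$family)
    fc <- rowsum(m, fam)                       # families x individuals
    tot <- colSums(fc)
    if (any(tot == 0))
        warning("zero total identifications for: ",
                paste(colnames(m)[tot == 0], collapse = ", "))
    r <- sweep(fc, 2, tot, "/")
    r[, tot == 0] <- NA_real_
    t(r)
}

#' Median identification ratio (MIR) per family and group
#'
#' The median of a family's relative abundance within a group divided by the
#' median across the reference pool. With `grouping = "species"` the
#' reference pool is all individuals; the modified variant
#' (`grouping = "species_island"`) forms island populations and divides each
#' island median by the median over that island's entire species, so a
#' species with a single island has MIR exactly 1 everywhere. Entries are
#' missing where the reference median is zero. MIR > 1 marks a family making
#' up a larger share of identifications in the group than in its reference
#' pool.
#'
#' @param abundance matrix from [relativeAbundance()] (individuals x
#'   families).
#' @param samples sample metadata (rows matched to abundance by
#'   `individual_id`).
#' @param grouping `"species"` or `"species_island"`.
#' @return numeric matrix, families x groups.
#' @export
computeMIR <- function(abundance, samples,
                       grouping = c("species", "species_island")) {
    grouping <- match.arg(grouping)
    idx <- match(rownames(abundance), samples$individual_id)
    if (any(is.na(idx)))
        stop("abundance rows missing from sample metadata")
    sp <- samples$species[idx]
    colMed <- function(rows) apply(abundance[rows, , drop = FALSE], 2,
                                   stats::median, na.rm = TRUE)
    if (grouping == "species") {
        groups <- sort(unique(sp))
        ref <- replicate(length(groups), colMed(seq_len(nrow(abundance))))
        num <- vapply(groups, function(g) colMed(which(sp == g)),
                      numeric(ncol(abundance)))
    } else {
        isl <- samples$island[idx]
        grp <- paste(sp, isl, sep = "|")
        groups <- sort(unique(grp))
        num <- vapply(groups, function(g) colMed(which(grp == g)),
                      numeric(ncol(abundance)))
        ref <- vapply(groups, function(g) {
            colMed(which(sp == sub("\\|.*$", "", g)))
        }, numeric(ncol(abundance)))
    }
    num <- matrix(num, ncol = length(groups),
                  dimnames = list(colnames(abundance), groups))
    ref <- matrix(ref, ncol = length(groups),
                  dimnames = dimnames(num))
    mir <- ifelse(!is.na(ref) & ref > 0, num / ref, NA_real_)
    mir
}

.olsSummary <- function(x, y, labelX, labelY) {
    fit <- stats::lm(y ~ x)
    ## summary.lm warns on residual-free fits; an exact fit is a valid input
    s <- withCallingHandlers(
        summary(fit),
        warning = function(w) {
            if (grepl("essentially perfect fit", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    co <- stats::coef(s)
    list(slope = unname(co[2L, 1L]),
         intercept = unname(co[1L, 1L]),
         slope_se = unname(co[2L, 2L]),
         r_squared = s$r.squared,
         p_value = unname(co[2L, 4L]),
         n = length(x),
         predictor = labelX, response = labelY)
}

#' Regress total identifications on locus count across families
#'
#' Ordinary least squares of per-family total identification counts on
#' per-family locus counts; the squared Pearson correlation is reported as
#' r-squared.
#'
#' @param presence an [ErvPresence-class] object.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
lociVsIdentificationsFit <- function(presence) {
    fam <- as.character(mcols(rowRanges(presence))$family)
    nLoc <- as.vector(table(fam))
    names(nLoc) <- names(table(fam))
    nId <- rowsum(rowSums(presenceCounts(presence)), fam)[, 1L]
    nId <- nId[names(nLoc)]
    if (length(nLoc) < 2L)
        stop("at least two families required")
    if (length(nLoc) == 2L)
        warning("degenerate two-point fit: r-squared is 1 by construction")
    if (stats::var(nLoc) == 0)
        stop("zero variance in per-family locus counts")
    .olsSummary(as.numeric(nLoc), as.numeric(nId),
                "loci_per_family", "identifications_per_family")
}

#' Regress per-individual fixed-locus detection rate on coverage
#'
#' The per-individual detection rate over the calibrated fixed loci (or,
#' with `use = "total_calls"`, the individual's total identification count)
#' is regressed on mean sequencing coverage. A positive slope indicates
#' coverage-limited sensitivity.
#'
#' @param presence an [ErvPresence-class] object.
#' @param fixedLocusIds locus ids from [fixedLocusCalibration()].
#' @param use `"fixed_rate"` (default) or `"total_calls"`.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
detectionVsCoverageFit <- function(presence, fixedLocusIds,
                                   use = c("fixed_rate", "total_calls")) {
    use <- match.arg(use)
    s <- sampleInfo(presence)
    if (nrow(s) < 3L)
        stop("at least three individuals required")
    if (stats::var(s$mean_coverage) == 0)
        stop("zero variance in mean coverage")
    y <- if (use == "fixed_rate") {
        if (!length(fixedLocusIds))
            stop("no fixed loci supplied")
        colMeans(presenceBinary(presence)[fixedLocusIds, , drop = FALSE])
    } else {
        colSums(presenceCounts(presence))
    }
    .olsSummary(s$mean_coverage, as.numeric(y), "mean_coverage", use)
}
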