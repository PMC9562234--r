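## Sharing classification across species, chromosomal density profiles, the
## differentiated-region frequency-contrast screen, and the group-comparison
## statistics used alongside them.

#' Classify locus sharing across groups
#'
#' Counts, per locus, the groups where the detection frequency exceeds zero
#' and assigns a class: `all_species` (every group), `private` (at most
#' one group) or `multi_species` (in between). The classes partition the
#' locus set; the summary percentage is rounded to one decimal.
#'
#' @param freq frequency matrix from [speciesFrequency()].
#' @return list with `table` (per-locus data.frame), `n_all_species`,
#'   `total`, `percent_all_species` and `percent_segregating` (formatted
#'   strings, e.g. `"1.2%"`), `summary` (one formatted line).
#' @export
classifySharing <- function(freq) {
    G <- ncol(freq)
    n <- rowSums(freq > 0)
    cls <- ifelse(n == G, "all_species",
                  ifelse(n <= 1L, "private", "multi_species"))
    tab <- data.frame(locus_id = rownames(freq), n_groups = as.integer(n),
                      class = factor(cls, levels = c("all_species",
                                                     "multi_species",
                                                     "private")),
                      row.names = NULL)
    nAll <- sum(cls == "all_species")
    total <- nrow(freq)
    pctAll <- sprintf("%.1f%%", 100 * nAll / total)
    pctSeg <- sprintf("%.1f%%", 100 * (total - nAll) / total)
    list(table = tab,
         n_all_species = nAll,
         total = total,
         percent_all_species = pctAll,
         percent_segregating = pctSeg,
         summary = sprintf(
             "%d of %d loci (%s) detected in all groups; segregating loci: %s",
             nAll, total, pctAll, pctSeg))
}

#' Chromosomal ERV density and end-enrichment profile
#'
#' Per chromosome: locus density (loci per Mbp), a binned positional profile
#' of locus midpoints (`bins` equal-width bins; counts sum to the
#' chromosome's locus total), and the end-enrichment ratio -- mean density
#' inside the two terminal windows of width `terminalFraction * L` divided
#' by mean density elsewhere. Pairwise relative density differences between
#' chromosomes are `|d_i - d_j| / min(d_i, d_j)`.
#'
#' @param loci `GRanges` locus frame.
#' @param chromLengths named vector of chromosome lengths in bp; loci on
#'   undeclared chromosomes are an error, as are non-positive lengths.
#' @param bins number of profile bins per chromosome.
#' @param terminalFraction terminal window width as a fraction of length.
#' @return list with `per_chromosome`, `profile` and `pairwise` data frames.
#' @export
chromosomeDensity <- function(loci, chromLengths, bins = 20L,
                              terminalFraction = 0.1) {
    if (any(chromLengths <= 0))
        stop("zero or negative chromosome length declared")
    .checkChroms(seqnames(loci), chromLengths)
    mid <- (start(loci) + end(loci)) / 2
    chrom <- as.character(seqnames(loci))
    perChrom <- lapply(names(chromLengths), function(cn) {
        L <- chromLengths[[cn]]
        m <- mid[chrom == cn]
        nc <- length(m)
        term <- m < terminalFraction * L | m > (1 - terminalFraction) * L
        dTerm <- sum(term) / (2 * terminalFraction * L / 1e6)
        dMid <- (nc - sum(term)) / ((1 - 2 * terminalFraction) * L / 1e6)
        data.frame(chrom = cn, n_loci = nc, length_bp = L,
                   density_per_mbp = nc / (L / 1e6),
                   end_enrichment_ratio =
                       if (nc == 0) NA_real_ else dTerm / dMid)
    })
    perChrom <- do.call(rbind, perChrom)
    profile <- do.call(rbind, lapply(names(chromLengths), function(cn) {
        L <- chromLengths[[cn]]
        brk <- seq(0, L, length.out = bins + 1L)
        cnt <- table(cut(mid[chrom == cn], breaks = brk,
                         include.lowest = TRUE))
        data.frame(chrom = cn, bin = seq_len(bins),
                   bin_start = brk[-length(brk)], bin_end = brk[-1L],
                   count = as.integer(cnt))
    }))
    pairwise <- if (nrow(perChrom) >= 2L) {
        cmb <- utils::combn(nrow(perChrom), 2L)
        d <- perChrom$density_per_mbp
        data.frame(chrom_i = perChrom$chrom[cmb[1L, ]],
                   chrom_j = perChrom$chrom[cmb[2L, ]],
                   relative_difference =
                       abs(d[cmb[1L, ]] - d[cmb[2L, ]]) /
                       pmin(d[cmb[1L, ]], d[cmb[2L, ]]))
    } else {
        data.frame(chrom_i = character(), chrom_j = character(),
                   relative_difference = numeric())
    }
    list(per_chromosome = perChrom, profile = profile, pairwise = pairwise,
         bins = as.integer(bins), terminal_fraction = terminalFraction)
}

#' Screen differentiated regions for between-species frequency contrasts
#'
#' Intersects loci with the differentiated-region intervals (any overlap of
#' at least 1 bp) and reports every in-region locus whose frequency
#' difference `delta = f_high - f_low` between the configured ordered
#' species pair reaches `minDelta` in magnitude, sorted by delta descending.
#' The optional mid-species frequency is reported for inspection but never
#' filtered on. Swapping the species pair flips delta signs but selects the
#' same loci.
#'
#' @param freq frequency matrix (loci x species groups).
#' @param loci `GRanges` aligned with `freq` rows via the `locus_id`
#'   metadata column.
#' @param regions `GRanges` with a `region_id` metadata column.
#' @param speciesHigh,speciesLow the ordered species pair (columns of
#'   `freq`); absence from the table is an error.
#' @param speciesMid optional intermediate species to report.
#' @param minDelta minimum |delta| to report (default 0.4).
#' @return data.frame with columns `locus_id`, `region_id`, `chrom`,
#'   `position`, `f_high`, `f_low`, `f_mid`, `delta`.
#' @export
regionContrastScreen <- function(freq, loci, regions, speciesHigh,
                                 speciesLow, speciesMid = NULL,
                                 minDelta = 0.4) {
    need <- c(speciesHigh, speciesLow, speciesMid)
    absent <- setdiff(need, colnames(freq))
    if (length(absent))
        stop("species absent from the frequency table: ",
             paste(absent, collapse = ", "))
    ids <- mcols(loci)$locus_id
    if (is.null(ids) || !all(rownames(freq) %in% ids))
        stop("loci must carry locus_id metadata matching the frequency rows")
    loci <- loci[match(rownames(freq), ids)]
    hits <- findOverlaps(loci, regions)
    if (!length(hits))
        return(data.frame(locus_id = character(), region_id = character(),
                          chrom = character(), position = integer(),
                          f_high = numeric(), f_low = numeric(),
                          f_mid = numeric(), delta = numeric()))
    ## one row per locus; ties across regions resolved to the left-most region
    ord <- order(queryHits(hits), start(regions)[subjectHits(hits)])
    first <- !duplicated(queryHits(hits)[ord])
    q <- queryHits(hits)[ord][first]
    r <- subjectHits(hits)[ord][first]
    fH <- freq[q, speciesHigh]
    fL <- freq[q, speciesLow]
    delta <- fH - fL
    keep <- abs(delta) >= minDelta - 1e-12
    out <- data.frame(
        locus_id = rownames(freq)[q],
        region_id = as.character(mcols(regions)$region_id[r]),
        chrom = as.character(seqnames(loci))[q],
        position = start(loci)[q],
        f_high = unname(fH),
        f_low = unname(fL),
        f_mid = if (is.null(speciesMid)) NA_real_
                else unname(freq[q, speciesMid]),
        delta = unname(delta))[keep, , drop = FALSE]
    out <- out[order(-out$delta), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Welch's two-sample t-test
#'
#' Two-tailed Welch statistic with Satterthwaite degrees of freedom, via
#' [stats::t.test()]. Both groups constant is an error.
#'
#' @param x,y numeric vectors, each of length at least 2.
#' @return list with `t`, `df`, `p_value`.
#' @export
welchT <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least two values")
    if (stats::var(x) == 0 && stats::var(y) == 0)
        stop("zero variance in both groups")
    ht <- stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F ratio with (k - 1, N - k) degrees
#' of freedom, via [stats::oneway.test()] with equal variances assumed.
#' When the pooled data are constant the ratio is defined as 0 with p = 1.
#'
#' @param groups list of at least two numeric vectors, each of length at
#'   least 2; an empty group is an error.
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @export
oneWayAnova <- function(groups) {
    if (length(groups) < 2L)
        stop("at least two groups required")
    if (any(lengths(groups) == 0L))
        stop("empty group supplied")
    v <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    df1 <- length(groups) - 1L
    df2 <- length(v) - length(groups)
    if (stats::var(v) == 0)
        return(list(F = 0, df1 = df1, df2 = df2, p_value = 1))
    res <- stats::oneway.test(v ~ g, var.equal = TRUE)
    list(F = unname(res$statistic),
         df1 = unname(res$parameter[1L]),
         df2 = unname(res$parameter[2L]),
         p_value = res$p.value)
}
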