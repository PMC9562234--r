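## Locus construction: extend insertion calls, reduce overlapping intervals
## into loci, unify non-assembly and assembly locus sets, and genotype a
## presence/count matrix from relaxed-filter evidence.

## reduce with revmap, merging on >= 1 shared bp only (touching closed
## intervals, i.e. half-open adjacency, do NOT merge)
.reduceStrict <- function(gr) {
    GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
}

.annotateReduced <- function(red, labels, positions) {
    fam <- vapply(as.list(mcols(red)$revmap), function(i)
        .majorityLabel(labels[i], positions[i]), character(1))
    mcols(red)$revmap <- NULL
    mcols(red)$family <- fam
    red
}

#' Merge stringent insertion calls into non-assembly loci
#'
#' Each call position `p` becomes the closed interval
#' `[p - extensionBp, p + extensionBp]` (a 101-bp window at the default 50),
#' clamped at the chromosome start; per chromosome, overlapping intervals are
#' unioned transitively into loci. Touching-but-not-overlapping intervals are
#' kept apart. Each locus is annotated with the majority family among its
#' constituent calls (ties broken by earliest call position, then
#' lexicographically). Locus coordinates mark the empty pre-integration site:
#' the reference assembly carries no ERV there.
#'
#' @param calls stringent-filtered insertion calls (columns `chrom`, `pos`,
#'   `family`).
#' @param extensionBp one-sided extension in bp (default 50).
#' @param chromLengths optional named vector declaring the sequence
#'   dictionary; used to clamp and validate.
#' @return `GRanges` of loci sorted by (chromosome, start) with metadata
#'   `family` and `source = "non_assembly"`.
#' @export
mergeInsertionLoci <- function(calls, extensionBp = 50L, chromLengths = NULL) {
    .assertColumns(calls, c("chrom", "pos", "family"), "calls")
    .checkChroms(calls$chrom, chromLengths)
    if (!nrow(calls)) {
        gr <- GRanges()
        mcols(gr)$family <- character(0)
        mcols(gr)$source <- character(0)
        return(gr)
    }
    st <- pmax(1L, as.integer(calls$pos) - as.integer(extensionBp))
    en <- as.integer(calls$pos) + as.integer(extensionBp)
    if (!is.null(chromLengths))
        en <- pmin(en, as.integer(chromLengths[as.character(calls$chrom)]))
    gr <- GRanges(calls$chrom, IRanges(st, en))
    red <- .annotateReduced(.reduceStrict(gr),
                            as.character(calls$family), calls$pos)
    mcols(red)$source <- "non_assembly"
    sort(red)
}

#' Build assembly-side loci from similarity-annotated deletions
#'
#' Overlapping deletion intervals across individuals are unioned (same
#' overlap rule as [mergeInsertionLoci()], no extension) per dialect, then
#' concatenated, so per-dialect locus counts add. Family comes from the
#' similarity annotation by majority vote.
#'
#' @param deletions stringent-filtered, similarity-annotated deletion calls
#'   (columns `chrom`, `start`, `end`, `dialect`, `family`).
#' @return `GRanges` of loci with metadata `family`, `source = "assembly"`
#'   and `dialect`.
#' @export
buildAssemblyLoci <- function(deletions) {
    .assertColumns(deletions, c("chrom", "start", "end", "dialect", "family"),
                   "deletions")
    allChroms <- unique(as.character(deletions$chrom))
    pieces <- lapply(split(deletions, deletions$dialect), function(d) {
        gr <- GRanges(factor(as.character(d$chrom), levels = allChroms),
                      IRanges(d$start, d$end))
        red <- .annotateReduced(.reduceStrict(gr),
                                as.character(d$family), d$start)
        mcols(red)$dialect <- d$dialect[1L]
        sort(red)
    })
    out <- if (length(pieces)) do.call(c, unname(pieces)) else {
        gr <- GRanges()
        mcols(gr)$family <- character(0)
        mcols(gr)$dialect <- character(0)
        gr
    }
    mcols(out)$source <- "assembly"
    out[, c("family", "source", "dialect")]
}

#' Unify non-assembly and assembly loci into one locus frame
#'
#' Concatenates both collections, preserves sources, sorts by position and
#' assigns stable locus identifiers of the form
#' `ERV-<clade>.<family>.<serial>` (serial within family). Total row count is
#' the sum of the inputs. Pre-existing non-duplicated `locus_id` columns are
#' preserved; a collision is an error.
#'
#' @param nonAssembly,assembly `GRanges` as returned by
#'   [mergeInsertionLoci()] and [buildAssemblyLoci()].
#' @param clades optional named vector mapping family to clade label for
#'   identifier construction (default clade `"U"`).
#' @return `GRanges` locus frame with metadata `locus_id`, `family`,
#'   `source`, `dialect`.
#' @export
unifyLocusFrame <- function(nonAssembly, assembly = NULL, clades = NULL) {
    if (is.null(mcols(nonAssembly)$dialect))
        mcols(nonAssembly)$dialect <- rep(NA_character_, length(nonAssembly))
    if (is.null(assembly) || !length(assembly)) {
        all <- nonAssembly
    } else {
        keep <- intersect(c("locus_id", "family", "source", "dialect"),
                          intersect(names(mcols(nonAssembly)),
                                    names(mcols(assembly))))
        lv <- union(seqlevels(nonAssembly), seqlevels(assembly))
        seqlevels(nonAssembly) <- lv
        seqlevels(assembly) <- lv
        all <- c(nonAssembly[, keep], assembly[, keep])
    }
    all <- sort(all)
    if (!is.null(mcols(all)$locus_id)) {
        if (anyDuplicated(mcols(all)$locus_id))
            stop("locus id collision: ",
                 paste(unique(mcols(all)$locus_id[
                     duplicated(mcols(all)$locus_id)]), collapse = ", "))
        return(all)
    }
    fam <- as.character(mcols(all)$family)
    clade <- if (is.null(clades)) rep("U", length(all))
             else ifelse(is.na(clades[fam]), "U", clades[fam])
    serial <- stats::ave(seq_along(fam), fam, FUN = seq_along)
    id <- sprintf("ERV-%s.%s.%d", clade, fam, serial)
    if (anyDuplicated(id))
        stop("locus id collision: ",
             paste(unique(id[duplicated(id)]), collapse = ", "))
    mcols(all)$locus_id <- id
    names(all) <- id
    all[, c("locus_id", "family", "source", "dialect")]
}

#' Genotype a presence/count matrix over the unified locus frame
#'
#' Non-assembly entries count the relaxed-filter insertion calls whose
#' extended interval (`pos` +/- `extensionBp`) overlaps the locus.
#' Assembly-side loci encode deletion logic: every individual starts as
#' ERV-present (the reference carries the ERV) and is set absent when a
#' passing deletion call covers the locus -- any read-depth (cnv) deletion,
#' or a split-read (sv) record with homozygous-deletion genotype 2; a
#' heterozygous deletion (genotype 1) leaves the individual as a carrier,
#' since one haplotype retains the ERV.
#'
#' @param loci unified locus frame from [unifyLocusFrame()].
#' @param insertions relaxed-filtered insertion calls.
#' @param deletions relaxed-filtered deletion calls (both dialects), or NULL.
#' @param samples sample metadata `data.frame` (one row per individual).
#' @param extensionBp extension applied to insertion calls (default 50).
#' @return an [ErvPresence-class] object.
#' @export
genotypePresence <- function(loci, insertions, deletions = NULL, samples,
                             extensionBp = 50L) {
    inCalls <- unique(c(insertions$individual_id, deletions$individual_id))
    unknown <- setdiff(inCalls, samples$individual_id)
    if (length(unknown))
        stop("individual(s) present in calls but not in sample metadata: ",
             paste(unknown, collapse = ", "))
    nLoci <- length(loci)
    nInd <- nrow(samples)
    counts <- matrix(0L, nLoci, nInd)

    naIdx <- which(mcols(loci)$source == "non_assembly")
    if (length(naIdx) && nrow(insertions)) {
        gi <- GRanges(insertions$chrom,
                      IRanges(pmax(1L, insertions$pos - extensionBp),
                              insertions$pos + extensionBp))
        hits <- findOverlaps(gi, loci[naIdx])
        if (length(hits)) {
            li <- naIdx[subjectHits(hits)]
            ii <- match(insertions$individual_id[queryHits(hits)],
                        samples$individual_id)
            key <- (ii - 1L) * nLoci + li
            tt <- table(key)
            counts[as.integer(names(tt))] <- as.integer(tt)
        }
    }

    asmIdx <- which(mcols(loci)$source == "assembly")
    if (length(asmIdx)) {
        counts[asmIdx, ] <- 1L
        if (!is.null(deletions) && nrow(deletions)) {
            absent <- deletions$dialect == "cnv" |
                (deletions$dialect == "sv" & !is.na(deletions$genotype) &
                 deletions$genotype == 2L)
            d <- deletions[which(absent), , drop = FALSE]
            if (nrow(d)) {
                dgr <- GRanges(d$chrom, IRanges(d$start, d$end))
                hits <- findOverlaps(dgr, loci[asmIdx])
                if (length(hits)) {
                    li <- asmIdx[subjectHits(hits)]
                    ii <- match(d$individual_id[queryHits(hits)],
                                samples$individual_id)
                    counts[cbind(li, ii)] <- 0L
                }
            }
        }
    }
    ErvPresence(counts, loci, samples)
}
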