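## Stringent and relaxed filter cascades for insertion calls and the two
## deletion-call dialects, plus ERV-similarity annotation of deletions.
## All printed thresholds are treated as inclusive.

#' Stringent insertion-call filter
#'
#' Keeps calls with at least `minReads` supporting reads, filter level (an
#' ordinal caller confidence tier, 8 = highest) at least `minFL`, genotype
#' quality inside `gqRange` (inclusive on both ends) and both soft-clip
#' supports at least `minClip`. Defaults reproduce the locus-defining
#' cascade: 5 reads, FL 8, GQ 10--200, clip3/clip5 of 2.
#'
#' @param calls insertion-call `data.frame` with columns `support_reads`,
#'   `filter_level`, `genotype_quality`, `clip3`, `clip5`.
#' @param minReads,minFL,gqRange,minClip3,minClip5 thresholds (inclusive).
#' @return the surviving rows.
#' @export
filterInsertionsStringent <- function(calls, minReads = 5L, minFL = 8L,
                                      gqRange = c(10, 200),
                                      minClip3 = 2L, minClip5 = 2L) {
    .assertColumns(calls, c("support_reads", "filter_level",
                            "genotype_quality", "clip3", "clip5"), "calls")
    keep <- calls$support_reads >= minReads &
        calls$filter_level >= minFL &
        calls$genotype_quality >= gqRange[1] &
        calls$genotype_quality <= gqRange[2] &
        calls$clip3 >= minClip3 &
        calls$clip5 >= minClip5
    calls[which(keep), , drop = FALSE]
}

#' Relaxed insertion-call filter
#'
#' The counting cascade: a single supporting read and filter level at least
#' `minFL` (default 5). Its survivors are a superset of the stringent
#' survivors on any input.
#'
#' @inheritParams filterInsertionsStringent
#' @return the surviving rows.
#' @export
filterInsertionsRelaxed <- function(calls, minReads = 1L, minFL = 5L) {
    .assertColumns(calls, c("support_reads", "filter_level"), "calls")
    keep <- calls$support_reads >= minReads & calls$filter_level >= minFL
    calls[which(keep), , drop = FALSE]
}

#' Filter deletion calls per dialect
#'
#' Read-depth (`cnv`) dialect: stringent keeps `eval1 <= 0.05`,
#' `eval2 <= 0.05` and length at most 20,000 bp; relaxed keeps
#' `eval1 <= 1` and `eval2 <= 1` with no length cap. Split-read (`sv`)
#' dialect (both modes): length between 90 and 20,000 bp and at least two
#' supporting reads. Mixed inputs are handled by applying each record's own
#' dialect rule. Lengths are bp spanned by the deletion interval.
#'
#' @param calls deletion-call `data.frame` with columns `chrom`, `start`,
#'   `end` (1-based closed), `dialect` ("cnv"/"sv"), `eval1`, `eval2`,
#'   `support_reads`.
#' @param mode `"stringent"` or `"relaxed"`.
#' @return the surviving rows.
#' @export
filterDeletions <- function(calls, mode = c("stringent", "relaxed")) {
    mode <- match.arg(mode)
    .assertColumns(calls, c("start", "end", "dialect"), "calls")
    len <- calls$end - calls$start + 1L
    keep <- logical(nrow(calls))
    cnv <- calls$dialect == "cnv"
    sv <- calls$dialect == "sv"
    if (any(cnv)) {
        keep[cnv] <- if (mode == "stringent")
            calls$eval1[cnv] <= 0.05 & calls$eval2[cnv] <= 0.05 &
                len[cnv] <= 20000
        else
            calls$eval1[cnv] <= 1 & calls$eval2[cnv] <= 1
    }
    if (any(sv))
        keep[sv] <- len[sv] >= 90 & len[sv] <= 20000 &
            calls$support_reads[sv] >= 2L
    calls[which(keep), , drop = FALSE]
}

#' Annotate deletions with the ERV family of overlapping similarity blocks
#'
#' A deletion is kept iff its interval overlaps at least one ERV-similarity
#' block by one or more base pairs; it is annotated with the family of the
#' maximally overlapping block. Ties on overlap width are broken by lower
#' block start coordinate, then lexicographic family, so outputs are
#' deterministic.
#'
#' @param deletions deletion-call `data.frame` (columns `chrom`, `start`,
#'   `end`, 1-based closed).
#' @param blocks `GRanges` of similarity blocks with a `family` metadata
#'   column.
#' @return the overlapping deletion rows with an added `family` column.
#' @export
annotateWithSimilarity <- function(deletions, blocks) {
    .assertColumns(deletions, c("chrom", "start", "end"), "deletions")
    if (is.null(mcols(blocks)$family))
        stop("similarity blocks must carry a 'family' metadata column")
    if (!nrow(deletions)) {
        deletions$family <- character(0)
        return(deletions)
    }
    dgr <- GRanges(deletions$chrom, IRanges(deletions$start, deletions$end))
    hits <- findOverlaps(dgr, blocks)
    if (!length(hits)) {
        out <- deletions[integer(), , drop = FALSE]
        out$family <- character(0)
        return(out)
    }
    ov <- width(pintersect(dgr[queryHits(hits)], blocks[subjectHits(hits)]))
    fam <- as.character(mcols(blocks)$family[subjectHits(hits)])
    bStart <- start(blocks)[subjectHits(hits)]
    ord <- order(queryHits(hits), -ov, bStart, fam)
    best <- !duplicated(queryHits(hits)[ord])
    q <- queryHits(hits)[ord][best]
    out <- deletions[q, , drop = FALSE]
    out$family <- fam[ord][best]
    out[order(q), , drop = FALSE]
}
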