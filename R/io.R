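## Readers and writers for the pipeline's table dialects. Internal genomic
## convention is the Bioconductor one (1-based, closed); BED files are
## 0-based half-open and converted at the boundary by rtracklayer; TSV
## readers accept either convention through `coords=`. All numeric output is
## written with a dot decimal separator; the frequency-table reader also
## accepts comma decimals.

.shiftCoords <- function(x, coords, what = "pos") {
    if (coords == "zero_based") {
        if (what == "pos") x + 1L else if (what == "start") x + 1L else x
    } else x
}

.parseCoordColumn <- function(x, path, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
        stop("malformed coordinate in '", path, "', column '", col,
             "', line ", bad[1L] + 1L, call. = FALSE)
    as.integer(v)
}

#' Read a sample metadata table
#'
#' Tab-separated with header columns `individual_id`, `species`, `island`,
#' `is_hybrid`, `mean_coverage` and optionally `is_outgroup`. Labels are
#' stripped of surrounding whitespace; a missing island becomes the empty
#' string.
#'
#' @param path file path.
#' @return `data.frame` of sample metadata.
#' @export
readSampleTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    .assertColumns(df, c("individual_id", "species", "island", "is_hybrid",
                         "mean_coverage"), path)
    for (col in c("individual_id", "species", "island"))
        df[[col]] <- trimws(ifelse(is.na(df[[col]]), "", df[[col]]))
    dup <- unique(df$individual_id[duplicated(df$individual_id)])
    if (length(dup))
        stop("duplicate individual_id: ", paste(dup, collapse = ", "),
             call. = FALSE)
    df$mean_coverage <- suppressWarnings(as.numeric(df$mean_coverage))
    bad <- df$individual_id[!is.finite(df$mean_coverage) |
                            df$mean_coverage <= 0]
    if (length(bad))
        stop("non-positive or missing mean_coverage for: ",
             paste(bad, collapse = ", "), call. = FALSE)
    df$is_hybrid <- .asLogicalFlag(df$is_hybrid)
    df$is_outgroup <- if ("is_outgroup" %in% names(df))
        .asLogicalFlag(df$is_outgroup) else FALSE
    df
}

#' Read insertion calls
#'
#' Tab-separated with header columns `individual_id`, `chrom`, `pos`,
#' `family`, `filter_level`, `genotype_quality`, `clip5`, `clip3`,
#' `support_reads`. `coords = "zero_based"` declares 0-based input positions
#' (shifted to the internal 1-based convention).
#'
#' @param path file path.
#' @param coords `"one_based"` (default) or `"zero_based"`.
#' @param chromLengths optional named sequence dictionary; unknown
#'   chromosome names are an error.
#' @return insertion-call `data.frame`.
#' @export
readInsertionCalls <- function(path, coords = c("one_based", "zero_based"),
                               chromLengths = NULL) {
    coords <- match.arg(coords)
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    .assertColumns(df, c("individual_id", "chrom", "pos", "family",
                         "filter_level", "genotype_quality", "clip5",
                         "clip3", "support_reads"), path)
    .checkChroms(df$chrom, chromLengths)
    df$pos <- .shiftCoords(.parseCoordColumn(df$pos, path, "pos"), coords)
    for (col in c("filter_level", "clip5", "clip3", "support_reads"))
        df[[col]] <- as.integer(df[[col]])
    df$genotype_quality <- as.numeric(df$genotype_quality)
    df
}

#' Read read-depth (cnv dialect) deletion calls
#'
#' Tab-separated with header columns `individual_id`, `chrom`, `start`,
#' `end`, `eval1`, `eval2`. With `coords = "zero_based"` intervals are
#' half-open and shifted to 1-based closed.
#'
#' @inheritParams readInsertionCalls
#' @return deletion-call `data.frame` with `dialect = "cnv"`.
#' @export
readCnvDeletions <- function(path, coords = c("one_based", "zero_based"),
                             chromLengths = NULL) {
    coords <- match.arg(coords)
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    .assertColumns(df, c("individual_id", "chrom", "start", "end",
                         "eval1", "eval2"), path)
    .checkChroms(df$chrom, chromLengths)
    df$start <- .shiftCoords(.parseCoordColumn(df$start, path, "start"),
                             coords, "start")
    df$end <- .parseCoordColumn(df$end, path, "end")
    if (any(df$end < df$start))
        stop("deletion end before start in '", path, "', line ",
             which(df$end < df$start)[1L] + 1L, call. = FALSE)
    df$eval1 <- as.numeric(df$eval1)
    df$eval2 <- as.numeric(df$eval2)
    df$dialect <- "cnv"
    df$support_reads <- NA_integer_
    df$genotype <- NA_integer_
    df[c("individual_id", "chrom", "start", "end", "dialect", "eval1",
         "eval2", "support_reads", "genotype")]
}

#' Read split-read (sv dialect) deletion calls from TSV or VCF
#'
#' TSV inputs carry header columns `individual_id`, `chrom`, `start`, `end`,
#' `support_reads`, `genotype` (0/1/2 deletion-allele copies). A `.vcf` path
#' is parsed with VariantAnnotation: one record per sample with a
#' non-reference GT is emitted, the deletion interval from POS/END, the
#' supporting-read count from the `DV` FORMAT field.
#'
#' @inheritParams readInsertionCalls
#' @return deletion-call `data.frame` with `dialect = "sv"`.
#' @export
readSvDeletions <- function(path, coords = c("one_based", "zero_based"),
                            chromLengths = NULL) {
    coords <- match.arg(coords)
    if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
        return(.readSvDeletionsVcf(path, chromLengths))
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    .assertColumns(df, c("individual_id", "chrom", "start", "end",
                         "support_reads", "genotype"), path)
    .checkChroms(df$chrom, chromLengths)
    df$start <- .shiftCoords(.parseCoordColumn(df$start, path, "start"),
                             coords, "start")
    df$end <- .parseCoordColumn(df$end, path, "end")
    if (any(df$end < df$start))
        stop("deletion end before start in '", path, "', line ",
             which(df$end < df$start)[1L] + 1L, call. = FALSE)
    df$support_reads <- as.integer(df$support_reads)
    df$genotype <- as.integer(df$genotype)
    df$dialect <- "sv"
    df$eval1 <- NA_real_
    df$eval2 <- NA_real_
    df[c("individual_id", "chrom", "start", "end", "dialect", "eval1",
         "eval2", "support_reads", "genotype")]
}

.readSvDeletionsVcf <- function(path, chromLengths = NULL) {
    vcf <- tryCatch(
        VariantAnnotation::readVcf(path, genome = "unknown"),
        error = function(e)
            stop("malformed deletion VCF '", path, "': ",
                 conditionMessage(e), call. = FALSE))
    rr <- SummarizedExperiment::rowRanges(vcf)
    delStart <- start(rr)
    delEnd <- VariantAnnotation::info(vcf)$END
    if (is.null(delEnd)) delEnd <- end(rr)
    delEnd <- ifelse(is.na(delEnd), end(rr), delEnd)
    if (any(delEnd < delStart))
        stop("deletion END before POS in '", path, "'", call. = FALSE)
    .checkChroms(as.character(seqnames(rr)), chromLengths)
    gt <- VariantAnnotation::geno(vcf)$GT
    dv <- VariantAnnotation::geno(vcf)$DV
    if (is.null(gt))
        stop("sv VCF must carry a GT FORMAT field", call. = FALSE)
    if (is.null(dv))
        stop("sv VCF must carry a DV (supporting reads) FORMAT field",
             call. = FALSE)
    codeGt <- function(g) {
        alleles <- strsplit(gsub("\\|", "/", g), "/")[[1L]]
        sum(alleles == "1")
    }
    rows <- list()
    for (s in colnames(gt)) {
        code <- vapply(gt[, s], codeGt, integer(1))
        keep <- which(code > 0L)
        if (!length(keep)) next
        rows[[s]] <- data.frame(
            individual_id = s,
            chrom = as.character(seqnames(rr))[keep],
            start = delStart[keep],
            end = as.integer(delEnd)[keep],
            dialect = "sv",
            eval1 = NA_real_, eval2 = NA_real_,
            support_reads = as.integer(dv[keep, s]),
            genotype = code[keep])
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(individual_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           dialect = character(), eval1 = numeric(),
                           eval2 = numeric(), support_reads = integer(),
                           genotype = integer())
    rownames(out) <- NULL
    out
}

#' Read ERV-similarity blocks from BED
#'
#' The BED name column carries the ERV family.
#'
#' @param path BED file path.
#' @return `GRanges` with a `family` metadata column.
#' @export
readSimilarityBlocks <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(mcols(gr)$name) || any(is.na(mcols(gr)$name)))
        stop("similarity-block BED must name the ERV family in column 4",
             call. = FALSE)
    mcols(gr) <- DataFrame(family = as.character(mcols(gr)$name))
    gr
}

#' Read differentiated-region intervals from BED
#'
#' Region ids are taken from the BED name column, or auto-numbered when
#' absent. Zero-length intervals are dropped with a warning; duplicated ids
#' are kept with a warning.
#'
#' @param path BED file path.
#' @return `GRanges` with a `region_id` metadata column.
#' @export
readRegions <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (any(width(gr) < 1L)) {
        warning("dropping ", sum(width(gr) < 1L),
                " zero-length region interval(s)")
        gr <- gr[width(gr) >= 1L]
    }
    ids <- mcols(gr)$name
    if (is.null(ids) || any(is.na(ids)) || !all(nzchar(ids)))
        ids <- sprintf("region%02d", seq_along(gr))
    if (anyDuplicated(ids))
        warning("duplicate region id(s) kept: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
    mcols(gr) <- DataFrame(region_id = as.character(ids))
    gr
}

#' Write a locus frame as BED
#'
#' BED is 0-based half-open; the name column carries the locus identifier
#' (which embeds the ERV family). Reading the file back with
#' [readLoci()] restores identical coordinates.
#'
#' @param loci `GRanges` with a `locus_id` metadata column.
#' @param path output path.
#' @export
writeLoci <- function(loci, path) {
    out <- granges(loci)
    mcols(out)$name <- mcols(loci)$locus_id
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' @rdname writeLoci
#' @return `readLoci`: `GRanges` with `locus_id` metadata.
#' @export
readLoci <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    mcols(gr) <- DataFrame(locus_id = as.character(mcols(gr)$name))
    gr
}

#' Write and read plain TSV result tables
#'
#' Dot decimal separator, no quoting, tab separation; a write/read round
#' trip returns identical values.
#'
#' @param df data.frame.
#' @param path file path.
#' @export
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, dec = ".")
    invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a presence matrix as TSV
#'
#' Loci as rows (first column `locus_id`), individuals as columns.
#'
#' @param presence an [ErvPresence-class] object or integer matrix with
#'   locus rownames.
#' @param path file path.
#' @export
writePresenceMatrix <- function(presence, path) {
    m <- if (is(presence, "ErvPresence")) presenceCounts(presence)
         else presence
    df <- data.frame(locus_id = rownames(m), m, check.names = FALSE)
    writeTsv(df, path)
}

#' @rdname writePresenceMatrix
#' @return `readPresenceMatrix`: integer matrix, loci x individuals.
#' @export
readPresenceMatrix <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    mode(m) <- "integer"
    rownames(m) <- df[[1L]]
    m
}

#' Read a locus frequency table with species columns
#'
#' Tab-separated with columns `locus_id`, `chrom`, `position` followed by one
#' column per species group. Frequencies may use either a dot or a comma as
#' the decimal separator (the comma dialect appears in published tables).
#'
#' @param path file path.
#' @return list with `loci` (`GRanges`, width-1 at the reported position)
#'   and `freq` (numeric matrix, loci x groups).
#' @export
readFrequencyTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    .assertColumns(df, c("locus_id", "chrom", "position"), path)
    pos <- .parseCoordColumn(df$position, path, "position")
    grpCols <- setdiff(names(df), c("locus_id", "chrom", "position"))
    freq <- vapply(grpCols, function(cl) .parseDecimal(df[[cl]]),
                   numeric(nrow(df)))
    freq <- matrix(freq, nrow = nrow(df),
                   dimnames = list(df$locus_id, grpCols))
    loci <- GRanges(df$chrom, IRanges(pos, width = 1L))
    mcols(loci)$locus_id <- df$locus_id
    names(loci) <- df$locus_id
    list(loci = loci, freq = freq)
}

#' Write the simulated caller tables in their on-disk dialects
#'
#' Emits `insertions.tsv`, `cnv_deletions.tsv`, `sv_deletions.tsv` (1-based
#' TSV), `similarity_blocks.bed` and `samples.tsv` into a directory; the
#' simulation-provenance column `truth_locus_id` is dropped. The files are
#' exactly what the `read*` functions consume.
#'
#' @param tables list as returned by [emitCallTables()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCallTables <- function(tables, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    drop <- function(df) df[, setdiff(names(df), "truth_locus_id"),
                            drop = FALSE]
    writeTsv(drop(tables$insertions), file.path(dir, "insertions.tsv"))
    cnv <- drop(tables$cnv_deletions)
    writeTsv(cnv[c("individual_id", "chrom", "start", "end",
                   "eval1", "eval2")],
             file.path(dir, "cnv_deletions.tsv"))
    sv <- drop(tables$sv_deletions)
    writeTsv(sv[c("individual_id", "chrom", "start", "end",
                  "support_reads", "genotype")],
             file.path(dir, "sv_deletions.tsv"))
    blocks <- granges(tables$similarity_blocks)
    mcols(blocks)$name <- mcols(tables$similarity_blocks)$family
    rtracklayer::export(blocks, file.path(dir, "similarity_blocks.bed"),
                        format = "BED")
    if (!is.null(tables$samples))
        writeTsv(tables$samples, file.path(dir, "samples.tsv"))
    invisible(dir)
}

#' @rdname writeCallTables
#' @param chromLengths optional sequence dictionary for validation.
#' @return `readCallTables`: list with `insertions`, `cnv_deletions`,
#'   `sv_deletions`, `similarity_blocks`, `samples`.
#' @export
readCallTables <- function(dir, chromLengths = NULL) {
    list(insertions = readInsertionCalls(file.path(dir, "insertions.tsv"),
                                         chromLengths = chromLengths),
         cnv_deletions = readCnvDeletions(file.path(dir,
                                                    "cnv_deletions.tsv"),
                                          chromLengths = chromLengths),
         sv_deletions = readSvDeletions(file.path(dir, "sv_deletions.tsv"),
                                        chromLengths = chromLengths),
         similarity_blocks = readSimilarityBlocks(
             file.path(dir, "similarity_blocks.bed")),
         samples = if (file.exists(file.path(dir, "samples.tsv")))
             readSampleTable(file.path(dir, "samples.tsv")) else NULL)
}
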