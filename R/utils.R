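## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertColumns <- function(df, cols, path) {
    missing <- setdiff(cols, names(df))
    if (length(missing))
        stop("missing required column(s) in '", path, "': ",
             paste(missing, collapse = ", "), call. = FALSE)
    invisible(df)
}

.asLogicalFlag <- function(x) {
    if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
    tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes", "y")
}

.checkChroms <- function(chroms, chromLengths) {
    if (is.null(chromLengths)) return(invisible(NULL))
    unknown <- setdiff(unique(as.character(chroms)), names(chromLengths))
    if (length(unknown))
        stop("unknown chromosome name(s) not in the declared sequence ",
             "dictionary: ", paste(unknown, collapse = ", "), call. = FALSE)
    invisible(NULL)
}

## majority vote with deterministic ties: earliest position, then lexicographic
.majorityLabel <- function(labels, positions) {
    tt <- table(labels)
    top <- names(tt)[tt == max(tt)]
    if (length(top) > 1L) {
        firstPos <- vapply(top, function(f) min(positions[labels == f]),
                           numeric(1))
        top <- top[order(firstPos, top)]
    }
    top[[1L]]
}

## parse numbers written with either '.' or ',' as decimal separator
.parseDecimal <- function(x) {
    as.numeric(gsub(",", ".", trimws(as.character(x)), fixed = TRUE))
}
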