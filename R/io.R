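# Readers/writers for the plain-text formats every stage touches: TSV count
# matrices (first column feature id, optional second column feature class),
# Broad-dialect GMT gene sets, clinical survival tables, binary mutation
# matrices and tf/target/mode regulon tables. All readers are strict:
# malformed input raises an error rather than a silently truncated object.

#' Read a gene x sample count matrix from TSV
#'
#' Expects a header row; the first column holds feature ids, an optional
#' second column named \code{featureClass} holds \code{coding}/\code{lncRNA}
#' labels, and the remaining columns are samples. Counts must be
#' non-negative integers; \code{NA} is not permitted.
#'
#' @param path file path
#' @return integer matrix with feature rownames and sample colnames; the
#'   per-feature class labels (if present) are attached as
#'   \code{attr(, "featureClass")}.
#' @export
readCounts <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("count table needs a feature column and >= 1 sample")
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids))
        stop("duplicate feature id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    cols <- colnames(tab)[-1]      # subsetting a data.frame repairs
    tab <- tab[, -1, drop = FALSE] # duplicated names, so keep the originals
    colnames(tab) <- cols
    fclass <- NULL
    if (colnames(tab)[1] == "featureClass") {
        fclass <- as.character(tab[[1]])
        cols <- cols[-1]
        tab <- tab[, -1, drop = FALSE]
        colnames(tab) <- cols
    }
    if (anyDuplicated(colnames(tab)))
        stop("duplicate sample column(s): ",
             paste(unique(colnames(tab)[duplicated(colnames(tab))]),
                   collapse = ", "))
    m <- as.matrix(tab)
    if (!is.numeric(m) || anyNA(m))
        stop("counts must be numeric with no NA")
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("invalid count at (%s, %s): %s", ids[bad[1, 1]],
                     colnames(m)[bad[1, 2]], m[bad[1, 1], bad[1, 2]]))
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    if (!is.null(fclass)) attr(m, "featureClass") <- stats::setNames(fclass, ids)
    m
}

#' Write a count matrix to TSV
#'
#' @param counts integer matrix (rownames = features, colnames = samples)
#' @param path output path
#' @param featureClass optional per-feature class labels; defaults to the
#'   \code{"featureClass"} attribute of \code{counts} if present
#' @return \code{path}, invisibly
#' @export
writeCounts <- function(counts, path, featureClass = attr(counts, "featureClass")) {
    df <- data.frame(feature = rownames(counts), check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!is.null(featureClass)) df$featureClass <- unname(featureClass[rownames(counts)])
    df <- cbind(df, as.data.frame(counts, check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read/write gene set collections in GMT format
#'
#' GMT dialect: one set per line, \code{name TAB description TAB member...}.
#' Duplicate members within a line are dropped with a warning; a set with no
#' members is a format error. An empty file yields an empty collection.
#'
#' @param path file path
#' @return named list of character vectors; per-set descriptions in
#'   \code{attr(, "description")}
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- list()
    desc <- character(0)
    for (ln in lines) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3)
            stop("GMT set '", parts[1], "' has zero members")
        nm <- parts[1]
        members <- parts[-(1:2)]
        members <- members[nzchar(members)]
        if (!length(members)) stop("GMT set '", nm, "' has zero members")
        if (anyDuplicated(members)) {
            warning("duplicate members in GMT set '", nm, "' deduplicated")
            members <- unique(members)
        }
        if (nm %in% names(out)) stop("duplicate GMT set name '", nm, "'")
        out[[nm]] <- members
        desc[nm] <- parts[2]
    }
    attr(out, "description") <- desc
    out
}

#' @rdname readGMT
#' @param sets named list of character vectors
#' @param description optional named character vector of set descriptions
#' @export
writeGMT <- function(sets, path, description = attr(sets, "description")) {
    stopifnot(!is.null(names(sets)), !anyDuplicated(names(sets)))
    if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
    lines <- vapply(names(sets), function(nm) {
        d <- if (!is.null(description) && nm %in% names(description))
            description[[nm]] else "na"
        paste(c(nm, d, sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a clinical survival table
#'
#' TSV with header; required columns \code{sample}, \code{time} (days,
#' non-negative) and \code{event} (0 = censored, 1 = event). Additional
#' covariate columns are carried through.
#'
#' @param path file path
#' @return data.frame with one row per sample
#' @export
readClinical <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample", "time", "event")
    if (!all(need %in% colnames(tab)))
        stop("clinical table must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$sample)) stop("duplicate sample id in clinical table")
    if (anyNA(tab$time) || any(tab$time < 0)) stop("time must be >= 0")
    if (!all(tab$event %in% c(0, 1)))
        stop("event must be 0/1; offending sample(s): ",
             paste(tab$sample[!tab$event %in% c(0, 1)], collapse = ", "))
    tab
}

#' Read a binary feature x sample matrix (e.g. mutation calls)
#'
#' @param path file path; TSV, first column feature id, header row
#' @return integer 0/1 matrix
#' @export
readBinaryMatrix <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids)) stop("duplicate feature id in binary matrix")
    m <- as.matrix(tab[, -1, drop = FALSE])
    bad <- which(!(m %in% c(0, 1)))
    if (length(bad)) {
        rc <- arrayInd(bad[1], dim(m))
        stop(sprintf("non-binary value at (%s, %s): %s", ids[rc[1]],
                     colnames(m)[rc[2]], m[bad[1]]))
    }
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    m
}

#' Read a regulon table
#'
#' TSV with header columns \code{tf}, \code{target}, \code{mode}; mode must
#' be +1 or -1 and targets must be unique within a TF.
#'
#' @param path file path
#' @return data.frame with columns \code{tf}, \code{target}, \code{mode}
#' @export
readRegulons <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("tf", "target", "mode")
    if (!all(need %in% colnames(tab)))
        stop("regulon table must have columns: ", paste(need, collapse = ", "))
    if (!all(tab$mode %in% c(-1, 1)))
        stop("regulon mode must be +1 or -1")
    if (any(duplicated(tab[, c("tf", "target")])))
        stop("duplicate target within a TF regulon")
    tab$mode <- as.integer(tab$mode)
    tab[, need]
}

#' Intersect tables on shared samples
#'
#' Aligns any set of matrices (samples in columns) and/or data.frames with a
#' \code{sample} column on their common samples, preserving the sample order
#' of the first object.
#'
#' @param ... matrices and/or data.frames
#' @return list of the same objects restricted to shared samples, in shared
#'   order
#' @export
alignSamples <- function(...) {
    objs <- list(...)
    getSamples <- function(o)
        if (is.data.frame(o)) as.character(o$sample) else colnames(o)
    shared <- Reduce(intersect, lapply(objs, getSamples))
    if (!length(shared)) stop("no shared samples")
    lapply(objs, function(o) {
        if (is.data.frame(o)) o[match(shared, o$sample), , drop = FALSE]
        else o[, shared, drop = FALSE]
    })
}
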