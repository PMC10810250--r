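.as_read_chars <- function(reads) {
    if (is(reads, "XStringSet")) {
        nm <- names(reads)
        reads <- as.character(reads)
        names(reads) <- nm
    }
    if (!is.character(reads)) stop("reads must be a character vector or DNAStringSet")
    nm <- names(reads)
    if (is.null(nm) || any(!nzchar(nm))) nm <- paste0("read_", seq_along(reads))
    list(seqs = unname(toupper(reads)), names = nm)
}

#' Pseudoalign reads against an index
#'
#' Maps each read to the set of reference ids supported by its k-mers,
#' without base-level alignment. All modes first locate the read's k-mers by
#' streaming dictionary lookup (or by the skipping walk) and then combine the
#' colors of the distinct unitigs hit:
#'
#' \itemize{
#' \item \code{"full-intersection"}: references containing every positive
#'   k-mer -- a leapfrog intersection of the distinct colors, driven by
#'   NextGEQ.
#' \item \code{"threshold-union"}: references covered by at least
#'   ceiling(s * tau) k-mers, where s is the number of positive k-mers
#'   (\code{sMode = "positive"}) or of all k-mers (\code{sMode = "all"}).
#'   Per-color scores (k-mers supporting that color) are summed down a
#'   min-value merge of the color iterators.
#' \item \code{"skip-kallisto-like"} and \code{"skip-backoff-like"}: as
#'   full-intersection, but instead of querying every k-mer the walk jumps
#'   from a hit to the position where its unitig must end (computed from the
#'   offset and orientation). The kallisto-like preset re-anchors immediately
#'   on an unexpected unitig and moves on after a miss; the backoff-like
#'   preset halves the jump distance (up to \code{backOffLimit} times,
#'   default 4) after either event. Skipped k-mers are assumed, not
#'   verified, so results may differ from full-intersection on reads with
#'   errors; every reported diagnostic position in \code{confirmed} was
#'   actually queried and found.
#' }
#'
#' With \code{twoPass = TRUE} (full-intersection only), reads are first
#' scanned to their sorted distinct color-id lists, identical lists are
#' collated, each distinct non-empty list is intersected exactly once, and
#' results fan back out; the output is identical to the one-pass mode and
#' \code{metadata()$intersections} records the number of intersections
#' performed.
#'
#' @param x a \code{CcdbgIndex}.
#' @param reads character vector or \code{DNAStringSet}.
#' @param mode one of \code{"full-intersection"}, \code{"threshold-union"},
#'   \code{"skip-kallisto-like"}, \code{"skip-backoff-like"}.
#' @param tau threshold in (0, 1] for threshold-union (default 0.8).
#' @param sMode \code{"positive"} (default) or \code{"all"}; see above.
#' @param twoPass collate identical color-id lists (full-intersection only).
#' @param backOffLimit maximum halvings per jump for the backoff-like preset.
#' @return a \code{DataFrame} with one row per read: \code{read} (name),
#'   \code{refs} (an \code{IntegerList} of 1-based reference ids, sorted),
#'   \code{mapped}, \code{nKmers}; non-skip modes add \code{positives} and
#'   \code{nColors}, skip modes add \code{queries} and \code{confirmed}
#'   (an \code{IntegerList} of 0-based confirmed k-mer positions). Query
#'   parameters are stored in \code{metadata()}.
#' @examples
#' idx <- buildIndex(c(a = "ACGTACGTACG", b = "ACGTACGTACG"), k = 5, w = 3)
#' pseudoalign(idx, c(r1 = "ACGTACG"), mode = "full-intersection")
#' @export
pseudoalign <- function(x, reads,
                        mode = c("full-intersection", "threshold-union",
                                 "skip-kallisto-like", "skip-backoff-like"),
                        tau = 0.8, sMode = c("positive", "all"),
                        twoPass = FALSE, backOffLimit = 4L) {
    stopifnot(is(x, "CcdbgIndex"))
    mode <- match.arg(mode)
    sMode <- match.arg(sMode)
    rr <- .as_read_chars(reads)
    meta <- list(mode = mode)

    if (mode == "full-intersection") {
        res <- if (twoPass) .query_two_pass_cpp(x@ptr, rr$seqs)
               else .query_full_cpp(x@ptr, rr$seqs)
        if (twoPass) meta$intersections <- res$intersections
        meta$twoPass <- twoPass
        df <- S4Vectors::DataFrame(
            read = rr$names,
            refs = IRanges::IntegerList(res$refs),
            mapped = lengths(res$refs) > 0L,
            nKmers = res$nKmers, positives = res$positives,
            nColors = res$nColors)
    } else if (mode == "threshold-union") {
        if (twoPass) stop("twoPass collation applies to full-intersection only")
        res <- .query_threshold_cpp(x@ptr, rr$seqs, tau, sMode == "positive")
        meta$tau <- tau
        meta$sMode <- sMode
        df <- S4Vectors::DataFrame(
            read = rr$names,
            refs = IRanges::IntegerList(res$refs),
            mapped = lengths(res$refs) > 0L,
            nKmers = res$nKmers, positives = res$positives,
            nColors = res$nColors)
    } else {
        if (twoPass) stop("twoPass collation applies to full-intersection only")
        if (mode == "skip-kallisto-like") {
            on_miss <- 0L; on_unexpected <- 2L
            meta$onMiss <- "query-next"; meta$onUnexpected <- "aggressive-jump"
        } else {
            on_miss <- 1L; on_unexpected <- 1L
            meta$onMiss <- "back-off"; meta$onUnexpected <- "back-off"
            meta$backOffLimit <- as.integer(backOffLimit)
        }
        res <- .query_skip_cpp(x@ptr, rr$seqs, on_miss, on_unexpected,
                               as.integer(backOffLimit))
        df <- S4Vectors::DataFrame(
            read = rr$names,
            refs = IRanges::IntegerList(res$refs),
            mapped = lengths(res$refs) > 0L,
            nKmers = res$nKmers, queries = res$queries,
            confirmed = IRanges::IntegerList(res$confirmed))
    }
    S4Vectors::metadata(df) <- meta
    df
}

#' Write pseudoalignment results as TSV
#'
#' One row per read: the read name, the number of mapped references, and the
#' reference list separated by tabs. References are written as 0-based ids
#' (or as names with \code{useNames = TRUE}). Commented header lines record
#' the query mode and its parameters so the file is self-describing.
#'
#' @param result a \code{DataFrame} from \code{\link{pseudoalign}}.
#' @param file output path.
#' @param useNames write reference names instead of 0-based ids (requires
#'   \code{index}).
#' @param index the \code{CcdbgIndex} queried (only needed for
#'   \code{useNames}).
#' @return the path, invisibly.
#' @examples
#' idx <- buildIndex(c(a = "ACGTACGTACG"), k = 5, w = 3)
#' res <- pseudoalign(idx, c(r1 = "ACGTACG"))
#' f <- tempfile(fileext = ".tsv")
#' writeMappings(res, f)
#' readLines(f)
#' @export
writeMappings <- function(result, file, useNames = FALSE, index = NULL) {
    meta <- S4Vectors::metadata(result)
    hdr <- sprintf("# mode: %s", meta$mode)
    if (!is.null(meta$tau)) hdr <- c(hdr, sprintf("# tau: %s", format(meta$tau)))
    if (!is.null(meta$sMode)) hdr <- c(hdr, sprintf("# s_mode: %s", meta$sMode))
    if (!is.null(meta$onMiss))
        hdr <- c(hdr, sprintf("# on_miss: %s", meta$onMiss),
                 sprintf("# on_unexpected: %s", meta$onUnexpected))
    if (!is.null(meta$backOffLimit))
        hdr <- c(hdr, sprintf("# back_off_limit: %d", meta$backOffLimit))
    refs <- as.list(result$refs)
    body <- vapply(seq_len(nrow(result)), function(i) {
        r <- refs[[i]]
        lab <- if (useNames) {
            if (is.null(index)) stop("useNames = TRUE requires the index")
            referenceNames(index)[r]
        } else as.character(r - 1L)
        paste(c(result$read[i], length(r), lab), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), file)
    invisible(file)
}
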