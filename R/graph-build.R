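.as_ref_chars <- function(refs) {
    if (is(refs, "XStringSet")) {
        nm <- names(refs)
        refs <- as.character(refs)
        names(refs) <- nm
    }
    if (!is.character(refs)) stop("references must be a character vector or DNAStringSet")
    if (length(refs) == 0L) stop("need at least one reference sequence")
    nm <- names(refs)
    if (is.null(nm) || any(!nzchar(nm)))
        nm <- paste0("ref_", seq_along(refs))
    list(seqs = unname(toupper(refs)), names = nm)
}

#' Canonical form of a k-mer
#'
#' The canonical form of a k-mer x is the lexicographic minimum of x and its
#' reverse complement. With the order-preserving 2-bit encoding
#' (A=0, C=1, G=2, T=3) this coincides with the integer minimum of the two
#' encodings, which is how it is computed internally.
#'
#' @param kmers character vector of k-mers (ACGT only, odd length <= 31;
#'   all the same length).
#' @return a \code{DataFrame} with columns \code{canonical} (character) and
#'   \code{forward} (logical; TRUE when the k-mer itself is canonical).
#' @examples
#' canonicalizeKmer(c("ACG", "CGT"))
#' @export
canonicalizeKmer <- function(kmers) {
    res <- .canonicalize_cpp(as.character(kmers))
    S4Vectors::DataFrame(canonical = res$canonical, forward = res$forward)
}

#' Map every distinct canonical k-mer to its color
#'
#' Scans the reference collection and returns, for each distinct canonical
#' k-mer, its color: the strictly increasing list of ids of the references
#' containing it (on either strand). This is the raw k-mer-to-color relation
#' that the graph compacts.
#'
#' Non-ACGT characters split a reference into fragments; k-mers never span
#' a fragment boundary.
#'
#' @param refs character vector or \code{DNAStringSet} of references.
#' @param k k-mer length (odd, 3..31).
#' @return a named list: canonical k-mer -> integer vector of reference ids,
#'   keys in lexicographic order.
#' @examples
#' extractKmerColors(c("ACGTT", "ACGTT"), k = 3)
#' @export
extractKmerColors <- function(refs, k = 31L) {
    rr <- .as_ref_chars(refs)
    .extract_kmer_colors_cpp(rr$seqs, as.integer(k))
}

#' Build the colored compacted de Bruijn graph
#'
#' Computes the maximal monochromatic unitigs of the reference collection:
#' every distinct canonical k-mer belongs to exactly one unitig position, all
#' k-mers of a unitig share one color, and each reference is a tiling of
#' unitig occurrences glued with (k-1)-overlaps. K-mers occurring at a
#' reference (or fragment) boundary terminate their unitig on that side, so
#' tilings never need partial unitig occurrences.
#'
#' Colors are assigned ids 1..M sorted by (cardinality, content) and unitigs
#' ids 1..m sorted by (color id, canonical spelling), giving the color-sorted
#' layout the downstream index relies on. The construction is deterministic.
#'
#' @param refs character vector or \code{DNAStringSet} of references; names
#'   are kept as reference names (defaults \code{ref_i}).
#' @param k k-mer length (odd, 3..31).
#' @return a \code{\link{CcdbgGraph}}.
#' @examples
#' g <- buildCcdbg(c(x = "ACGTACGTACG", y = "ACGTACGTACG"), k = 5)
#' g
#' @export
buildCcdbg <- function(refs, k = 31L) {
    rr <- .as_ref_chars(refs)
    k <- as.integer(k)
    res <- .ccdbg_build_cpp(rr$seqs, k)
    if (isTRUE(res$empty))
        warning("reference collection contains no valid k-mer at k = ", k)
    new("CcdbgGraph",
        unitigs = Biostrings::DNAStringSet(res$unitigs),
        colorIds = as.integer(res$colorIds),
        colorSets = lapply(res$colors, as.integer),
        tilings = res$tilings,
        nKmers = as.numeric(res$n),
        k = k,
        refNames = rr$names)
}

#' @rdname ccdbg-accessors
setMethod("nReferences", "CcdbgGraph", function(x) length(x@refNames))
#' @rdname ccdbg-accessors
setMethod("nUnitigs", "CcdbgGraph", function(x) length(x@unitigs))
#' @rdname ccdbg-accessors
setMethod("nColors", "CcdbgGraph", function(x) length(x@colorSets))
#' @rdname ccdbg-accessors
setMethod("nKmers", "CcdbgGraph", function(x) x@nKmers)
#' @rdname ccdbg-accessors
setMethod("kmerLength", "CcdbgGraph", function(x) x@k)
#' @rdname ccdbg-accessors
setMethod("referenceNames", "CcdbgGraph", function(x) x@refNames)
#' @rdname ccdbg-accessors
setMethod("unitigSequences", "CcdbgGraph", function(x) x@unitigs)
#' @rdname ccdbg-accessors
setMethod("colorSet", "CcdbgGraph", function(x, j) {
    j <- as.integer(j)
    if (length(j) != 1L || is.na(j) || j < 1L || j > length(x@colorSets))
        stop("color id out of range [1..M]")
    x@colorSets[[j]]
})
#' @rdname ccdbg-accessors
setMethod("colorId", "CcdbgGraph", function(x, i) {
    i <- as.integer(i)
    if (any(is.na(i)) || any(i < 1L) || any(i > length(x@colorIds)))
        stop("unitig id out of range [1..m]")
    x@colorIds[i]
})

#' Per-reference tilings of a graph
#'
#' @param x a \code{CcdbgGraph}.
#' @return a list (one element per reference) of lists (one per fragment) of
#'   integer matrices with columns \code{unitig} and \code{forward}.
#' @examples
#' g <- buildCcdbg(c("ACGTACGTACG"), k = 5)
#' tilings(g)[[1]]
#' @export
tilings <- function(x) {
    stopifnot(is(x, "CcdbgGraph"))
    x@tilings
}

.revcomp_chr <- function(s) {
    vapply(s, function(x) {
        paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

#' Re-spell references from their tilings
#'
#' Glues each reference's tiling of unitig occurrences with (k-1)-overlaps:
#' the first occurrence contributes its full spelling (reverse-complemented
#' when the occurrence is on the reverse strand), each following occurrence
#' contributes all but its first k-1 characters. This is the round-trip
#' check that the tilings are lossless.
#'
#' @param x a \code{CcdbgGraph}.
#' @return a list (per reference) of character vectors (one spelling per
#'   fragment). For references without non-ACGT characters each vector has
#'   length one and equals the uppercased input.
#' @examples
#' g <- buildCcdbg(c(r = "ACGTACGTACG"), k = 5)
#' spellTilings(g)[["r"]]
#' @export
spellTilings <- function(x) {
    stopifnot(is(x, "CcdbgGraph"))
    u <- as.character(x@unitigs)
    k <- x@k
    out <- lapply(x@tilings, function(frags) {
        vapply(frags, function(mat) {
            parts <- character(nrow(mat))
            for (o in seq_len(nrow(mat))) {
                s <- u[mat[o, "unitig"]]
                if (!mat[o, "forward"]) s <- .revcomp_chr(s)
                parts[o] <- if (o == 1L) s else substring(s, k)
            }
            paste(parts, collapse = "")
        }, character(1))
    })
    names(out) <- x@refNames
    out
}

#' Write unitigs as FASTA (debug output)
#'
#' One record per unitig in layout order; headers carry the unitig id, its
#' color id, and the color content, e.g. \code{>unitig_4 color=2 refs=1,3}.
#'
#' @param x a \code{CcdbgGraph} or \code{CcdbgIndex}.
#' @param file output path.
#' @return the path, invisibly.
#' @examples
#' g <- buildCcdbg(c("ACGTACGTACG"), k = 5)
#' f <- tempfile(fileext = ".fa")
#' writeUnitigs(g, f)
#' @export
writeUnitigs <- function(x, file) {
    u <- as.character(unitigSequences(x))
    ids <- colorId(x, seq_along(u))
    hdr <- vapply(seq_along(u), function(i) {
        sprintf(">unitig_%d color=%d refs=%s", i, ids[i],
                paste(colorSet(x, ids[i]), collapse = ","))
    }, character(1))
    writeLines(as.vector(rbind(hdr, u)), file)
    invisible(file)
}

setMethod("show", "CcdbgGraph", function(object) {
    cat(sprintf("CcdbgGraph: k=%d | %d reference(s), %d unitig(s), %d color(s), %.0f k-mer(s)\n",
                object@k, nReferences(object), nUnitigs(object),
                nColors(object), object@nKmers))
    m <- nUnitigs(object)
    show_n <- min(m, 5L)
    if (show_n > 0L) {
        u <- as.character(object@unitigs)
        for (i in seq_len(show_n)) {
            s <- u[i]
            if (nchar(s) > 40L) s <- paste0(substring(s, 1L, 40L), "...")
            cat(sprintf("  unitig %d (color %d): %s\n", i, object@colorIds[i], s))
        }
        if (m > show_n) cat(sprintf("  ... and %d more\n", m - show_n))
    }
    invisible(NULL)
})
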