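#' Build the composed k-mer-to-color index
#'
#' Composes the three parts of the index over a colored compacted de Bruijn
#' graph: the order-preserving dictionary mapping each canonical k-mer to its
#' (unitig, offset, orientation) in the color-sorted layout, the rank
#' bit-vector B mapping unitig ids to color ids (Rank1(i, B) + 1), and the
#' hybrid compressed color store. Exact membership is guaranteed because
#' every minimizer-bucket candidate is verified by direct sequence
#' comparison against the stored unitig.
#'
#' @param x a \code{CcdbgGraph}, or references (character vector /
#'   \code{DNAStringSet}) from which the graph is built first.
#' @param k k-mer length (only used when \code{x} is not already a graph).
#' @param w minimizer length, \code{1 <= w < k}.
#' @return a \code{\link{CcdbgIndex}}.
#' @examples
#' idx <- buildIndex(c("ACGTACGTACG", "ACGTACGTACG"), k = 5, w = 3)
#' idx
#' @export
buildIndex <- function(x, k = 31L, w = 15L) {
    if (!is(x, "CcdbgGraph")) x <- buildCcdbg(x, k = k)
    w <- as.integer(w)
    ptr <- .idx_build_cpp(as.character(x@unitigs), x@colorIds, x@colorSets,
                          nReferences(x), x@k, w, x@refNames)
    new("CcdbgIndex", ptr = ptr)
}

.idx_info <- function(x) .idx_info_cpp(x@ptr)

#' @rdname ccdbg-accessors
setMethod("nReferences", "CcdbgIndex", function(x) .idx_info(x)$N)
#' @rdname ccdbg-accessors
setMethod("nUnitigs", "CcdbgIndex", function(x) .idx_info(x)$m)
#' @rdname ccdbg-accessors
setMethod("nColors", "CcdbgIndex", function(x) .idx_info(x)$M)
#' @rdname ccdbg-accessors
setMethod("nKmers", "CcdbgIndex", function(x) .idx_info(x)$n)
#' @rdname ccdbg-accessors
setMethod("kmerLength", "CcdbgIndex", function(x) .idx_info(x)$k)
#' @rdname ccdbg-accessors
setMethod("referenceNames", "CcdbgIndex", function(x) .idx_info(x)$refNames)
#' @rdname ccdbg-accessors
setMethod("unitigSequences", "CcdbgIndex",
    function(x) Biostrings::DNAStringSet(.idx_unitigs_cpp(x@ptr)))
#' @rdname ccdbg-accessors
setMethod("colorSet", "CcdbgIndex", function(x, j) {
    j <- as.integer(j)
    if (length(j) != 1L || is.na(j) || j < 1L || j > nColors(x))
        stop("color id out of range [1..M]")
    .idx_color_set_cpp(x@ptr, j)
})
#' @rdname ccdbg-accessors
setMethod("colorId", "CcdbgIndex", function(x, i) .idx_color_id_cpp(x@ptr, as.integer(i)))

#' Minimizer length of an index
#' @param x a \code{CcdbgIndex}.
#' @return the minimizer length w used by the dictionary.
#' @examples
#' idx <- buildIndex("ACGTACGTACG", k = 5, w = 3)
#' minimizerLength(idx)
#' @export
minimizerLength <- function(x) {
    stopifnot(is(x, "CcdbgIndex"))
    .idx_info(x)$w
}

#' @rdname colorRank
#' @export
setMethod("bitVector", "CcdbgIndex", function(x) .idx_bits_cpp(x@ptr))

#' Save / load an index
#'
#' Single-file binary serialization: magic, format version, bit-order flag,
#' then little-endian sections (header, reference names, dictionary,
#' rank bit-vector, color store) each followed by a checksum. Loading
#' verifies magic, version, and every checksum, and refuses corrupted input;
#' the minimizer index and rank directory are rebuilt in memory.
#'
#' @param x a \code{CcdbgIndex}.
#' @param path file path.
#' @return \code{saveIndex} returns \code{path} invisibly; \code{loadIndex}
#'   returns the restored \code{CcdbgIndex}.
#' @examples
#' idx <- buildIndex("ACGTACGTACG", k = 5, w = 3)
#' f <- tempfile(fileext = ".ccxi")
#' saveIndex(idx, f)
#' idx2 <- loadIndex(f)
#' @export
saveIndex <- function(x, path) {
    stopifnot(is(x, "CcdbgIndex"))
    .idx_save_cpp(x@ptr, path.expand(path))
    invisible(path)
}

#' @rdname saveIndex
#' @export
loadIndex <- function(path) {
    if (!file.exists(path)) stop("no such index file: ", path)
    new("CcdbgIndex", ptr = .idx_load_cpp(path.expand(path)))
}

#' Exact single k-mer lookup
#'
#' Looks up the canonical form of each k-mer in the dictionary. A hit returns
#' the unitig id, the 0-based offset of the canonical k-mer inside the
#' canonical unitig spelling, and whether the queried k-mer matched in
#' forward orientation; a miss returns NA in all three columns (the
#' dictionary has no false positives).
#'
#' @param x a \code{CcdbgIndex}.
#' @param kmers character vector of k-mers of length k.
#' @return a \code{DataFrame} with columns \code{unitig}, \code{offset},
#'   \code{forward}.
#' @examples
#' idx <- buildIndex("ACGTACGTACG", k = 5, w = 3)
#' lookupKmer(idx, c("ACGTA", "AAAAA"))
#' @export
lookupKmer <- function(x, kmers) {
    stopifnot(is(x, "CcdbgIndex"))
    res <- .idx_lookup_cpp(x@ptr, as.character(kmers))
    S4Vectors::DataFrame(unitig = res$unitig, offset = res$offset,
                         forward = res$forward)
}

#' Streaming lookup over a query sequence
#'
#' Looks up all consecutive k-mers of \code{sequence} left to right,
#' exploiting locality twice: if the previous k-mer hit at (unitig, offset),
#' the next one is first checked at the adjacent offset (a position-cache
#' hit, no search); otherwise, if the minimizer is unchanged, the cached
#' bucket is rescanned without recomputing the bucket lookup. A miss clears
#' the position cache only.
#'
#' @param x a \code{CcdbgIndex}.
#' @param sequence a single query string.
#' @return a list with \code{hits} (a \code{DataFrame} of \code{unitig},
#'   \code{offset}, \code{forward}, one row per k-mer position, NA on miss),
#'   counters \code{cacheHits}, \code{bucketReuse}, \code{searches}, and
#'   \code{tooShort} (TRUE when \code{nchar(sequence) < k}).
#' @examples
#' idx <- buildIndex("ACGTACGTACG", k = 5, w = 3)
#' streamingLookup(idx, "ACGTACG")$cacheHits
#' @export
streamingLookup <- function(x, sequence) {
    stopifnot(is(x, "CcdbgIndex"), length(sequence) == 1L)
    res <- .idx_streaming_lookup_cpp(x@ptr, as.character(sequence))
    list(hits = S4Vectors::DataFrame(unitig = res$unitig, offset = res$offset,
                                     forward = res$forward),
         cacheHits = res$cacheHits, bucketReuse = res$bucketReuse,
         searches = res$searches, tooShort = res$tooShort)
}

#' Color of a k-mer
#'
#' The full composition: dictionary lookup, unitig-to-color-id rank, color
#' decode. Absent k-mers map to the empty color.
#'
#' @param x a \code{CcdbgIndex}.
#' @param kmers character vector of k-mers of length k.
#' @return a list of integer vectors (reference ids), one per k-mer.
#' @examples
#' idx <- buildIndex(c("ACGTACGTACG", "ACGTACGTACG"), k = 5, w = 3)
#' kmerColor(idx, "ACGTA")
#' @export
kmerColor <- function(x, kmers) {
    stopifnot(is(x, "CcdbgIndex"))
    .idx_kmer_color_cpp(x@ptr, as.character(kmers))
}

setMethod("show", "CcdbgIndex", function(object) {
    info <- .idx_info(object)
    cat(sprintf("CcdbgIndex: k=%d, w=%d | N=%d reference(s), m=%d unitig(s), M=%d color(s), n=%.0f k-mer(s)\n",
                info$k, info$w, info$N, info$m, info$M, info$n))
    st <- .idx_color_stats_cpp(object@ptr)
    tags <- factor(st$tag, levels = 0:2,
                   labels = c("sparse", "bitvector", "dense-complement"))
    tt <- table(tags)
    cat("  color encodings:", paste(sprintf("%s=%d", names(tt), as.integer(tt)),
                                    collapse = ", "), "\n")
    cat(sprintf("  color store: %.0f bits sequences + %.0f bits offsets\n",
                st$sequencesBits, st$offsetsBits))
    invisible(NULL)
})
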