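#' CcdbgGraph: a colored compacted de Bruijn graph
#'
#' The set of maximal monochromatic unitigs of a reference collection,
#' laid out in color-sorted order (all unitigs sharing a color are
#' contiguous, ordered by canonical spelling within a color group), the
#' distinct colors, and the per-reference tilings.
#'
#' Unitigs satisfy three properties: every distinct canonical k-mer of the
#' collection occurs at exactly one (unitig, offset); all k-mers of a unitig
#' share one color (monochromaticity, which requires that k-mers at reference
#' boundaries terminate their unitig); and gluing each reference's tiling of
#' unitig occurrences with (k-1)-overlaps re-spells the reference.
#'
#' @slot unitigs \code{DNAStringSet} of canonical unitig spellings, color-sorted.
#' @slot colorIds integer vector, \code{colorIds[i]} is the color id of unitig i
#'   (non-decreasing over the layout).
#' @slot colorSets list of strictly increasing integer vectors; the M distinct
#'   colors, ids assigned by (cardinality, then content).
#' @slot tilings per reference, a list of per-fragment integer matrices with
#'   columns \code{unitig} and \code{forward} (fragments arise from splitting
#'   at non-ACGT runs).
#' @slot nKmers number of distinct canonical k-mers n.
#' @slot k the k-mer length (odd, <= 31).
#' @slot refNames reference names in input order (ids are 1..N).
#' @aliases CcdbgGraph
#' @export
setClass("CcdbgGraph",
    representation(
        unitigs = "DNAStringSet",
        colorIds = "integer",
        colorSets = "list",
        tilings = "list",
        nKmers = "numeric",
        k = "integer",
        refNames = "character"
    )
)

setValidity("CcdbgGraph", function(object) {
    msg <- character()
    m <- length(object@unitigs)
    if (length(object@colorIds) != m)
        msg <- c(msg, "colorIds must have one entry per unitig")
    if (m > 0 && is.unsorted(object@colorIds))
        msg <- c(msg, "unitigs must be grouped by non-decreasing color id")
    M <- length(object@colorSets)
    if (m > 0 && (min(object@colorIds) < 1L || max(object@colorIds) > M))
        msg <- c(msg, "color ids must lie in 1..M")
    for (cs in object@colorSets) {
        if (length(cs) == 0L || is.unsorted(cs, strictly = TRUE) ||
            cs[1L] < 1L || cs[length(cs)] > length(object@refNames)) {
            msg <- c(msg, "each color must be strictly increasing within [1..N]")
            break
        }
    }
    if (length(object@tilings) != length(object@refNames))
        msg <- c(msg, "tilings must have one entry per reference")
    if (length(msg)) msg else TRUE
})

#' CcdbgIndex: the composed k-mer-to-color index
#'
#' Wraps the native index: the order-preserving k-mer dictionary over
#' color-sorted unitigs (minimizer-bucketed, verification by direct sequence
#' comparison), the rank bit-vector mapping unitig ids to color ids, and the
#' hybrid compressed color store with its Elias-Fano offset directory.
#'
#' The native handle is not preserved by R serialization (\code{saveRDS});
#' use \code{\link{saveIndex}} / \code{\link{loadIndex}} instead.
#'
#' @slot ptr external pointer to the native index.
#' @aliases CcdbgIndex
#' @export
setClass("CcdbgIndex", representation(ptr = "externalptr"))

setValidity("CcdbgIndex", function(object) {
    info <- tryCatch(.idx_info_cpp(object@ptr), error = function(e) NULL)
    if (is.null(info)) "invalid native index handle (rebuild or loadIndex())" else TRUE
})

#' ColorRank: unitig-to-color-id map in 1 + o(1) bits per unitig
#'
#' A bit-vector B[1..m] over the color-sorted unitig layout with
#' B[i] = 1 iff unitig i is the last of its color group (and B[m] = 1),
#' plus a superblock rank directory. The color id of unitig i is
#' Rank1(i, B) + 1, where Rank1 counts ones in the half-open prefix B[1, i).
#'
#' @slot words raw vector, the packed bit-vector (64-bit words).
#' @slot m number of unitigs (bits).
#' @slot M number of distinct colors (set bits).
#' @slot super numeric vector of absolute rank counts per 512-bit superblock.
#' @aliases ColorRank
#' @export
setClass("ColorRank",
    representation(words = "raw", m = "integer", M = "integer", super = "numeric"))

setValidity("ColorRank", function(object) {
    msg <- character()
    if (object@m < 1L) msg <- c(msg, "m must be positive")
    if (length(object@words) * 8L < object@m %/% 8L)
        msg <- c(msg, "bit payload shorter than m bits")
    b <- .cr_bits_cpp(object@words, object@m)
    if (sum(b) != object@M) msg <- c(msg, "popcount(B) must equal M")
    if (!b[object@m]) msg <- c(msg, "B[m] must be set")
    if (length(msg)) msg else TRUE
})

#' ColorStore: the compressed inverted index over distinct colors
#'
#' M colors encoded by the density-routed hybrid scheme (sparse delta-gap /
#' characteristic bit-vector / complemented delta-gap), concatenated into a
#' single bit stream delimited by an Elias-Fano offset directory. Iterators
#' over the stored colors support Value/Next/Next-GEQ with the N+1 sentinel.
#'
#' @slot ptr external pointer to the native store.
#' @aliases ColorStore
#' @export
setClass("ColorStore", representation(ptr = "externalptr"))

#' EliasFano: quasi-succinct encoding of a monotone integer sequence
#'
#' @slot ptr external pointer to the native structure.
#' @slot n number of stored values.
#' @slot u universe bound (all values < u).
#' @aliases EliasFano
#' @export
setClass("EliasFano", representation(ptr = "externalptr", n = "numeric", u = "numeric"))
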