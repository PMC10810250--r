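#' Unitig-to-color-id mapping via a rank bit-vector
#'
#' @description Builds the succinct map from unitig ids to color ids over a
#' color-sorted unitig layout. The layout is summarized by a bit-vector
#' B[1..m] with B[i] = 1 iff unitig i is the last of its color group
#' (B[m] = 1 always, and popcount(B) = M). The color id of unitig i is then
#' \code{colorId(x, i) = rank1(x, i) + 1}, where \code{rank1(x, i)} counts
#' the ones in the half-open prefix B[1, i). Rank is answered from a
#' directory of absolute counts per 512-bit superblock plus a word popcount,
#' in constant time.
#'
#' @param colorIds non-decreasing integer vector: the color id of each unitig
#'   in layout order (an error is raised if not grouped).
#' @param x a \code{ColorRank} (or for \code{bitVector} also a
#'   \code{CcdbgIndex}).
#' @param i for \code{rank1}, positions in 1..m+1 (half-open prefixes); for
#'   \code{colorId}, unitig ids in 1..m.
#' @return \code{buildColorRank} returns a \code{\link{ColorRank}};
#'   \code{rank1} and \code{colorId} integer vectors parallel to \code{i};
#'   \code{bitVector} the logical vector B.
#' @examples
#' cr <- buildColorRank(c(1, 1, 1, 2, 3, 3, 3))
#' bitVector(cr)        # 0 0 1 1 0 0 1
#' colorId(cr, 6)       # 3
#' @name colorRank
NULL

#' @rdname colorRank
#' @export
buildColorRank <- function(colorIds) {
    res <- .cr_build_cpp(as.integer(colorIds))
    new("ColorRank", words = res$words, m = as.integer(res$m),
        M = as.integer(res$M), super = res$super)
}

#' @rdname colorRank
setMethod("rank1", "ColorRank", function(x, i) .cr_rank1_cpp(x@words, x@m, as.integer(i)))

#' @rdname colorRank
setMethod("bitVector", "ColorRank", function(x) .cr_bits_cpp(x@words, x@m))

#' @rdname colorRank
setMethod("colorId", "ColorRank", function(x, i) {
    i <- as.integer(i)
    if (any(is.na(i)) || any(i < 1L) || any(i > x@m))
        stop("unitig id out of range [1..m]")
    .cr_rank1_cpp(x@words, x@m, i) + 1L
})

setMethod("show", "ColorRank", function(object) {
    cat(sprintf("ColorRank: m=%d unitig(s), M=%d color(s), %d payload bit(s) + %d superblock count(s)\n",
                object@m, object@M, length(object@words) * 8L, length(object@super)))
    invisible(NULL)
})
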