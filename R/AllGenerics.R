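#' @name ccdbg-accessors
#' @title Accessors shared by CcdbgGraph and CcdbgIndex
#'
#' @description Size and content accessors: \code{nReferences} (N),
#' \code{nUnitigs} (m), \code{nColors} (M), \code{nKmers} (n, distinct
#' canonical k-mers), \code{kmerLength} (k), \code{referenceNames},
#' \code{unitigSequences} (color-sorted \code{DNAStringSet}),
#' \code{colorSet(x, j)} (the j-th distinct color, a strictly increasing
#' vector of reference ids), and \code{colorId(x, i)} (color id of unitig i;
#' on an index this is computed as Rank1(i, B) + 1).
#'
#' @param x a \code{CcdbgGraph}, \code{CcdbgIndex}, or (for \code{colorId})
#'   a \code{ColorRank}.
#' @param i unitig id(s) in 1..m.
#' @param j color id in 1..M.
#' @return \code{colorSet} returns an integer vector; \code{colorId} an
#'   integer vector parallel to \code{i}; the others scalars (or a character
#'   vector for \code{referenceNames}, a \code{DNAStringSet} for
#'   \code{unitigSequences}).
#' @examples
#' g <- buildCcdbg(c(a = "ACGTACGTACG", b = "ACGTACGTACG"), k = 5)
#' nReferences(g); nColors(g); colorSet(g, 1)
NULL

#' @rdname ccdbg-accessors
#' @export
setGeneric("nReferences", function(x) standardGeneric("nReferences"))

#' @rdname ccdbg-accessors
#' @export
setGeneric("nUnitigs", function(x) standardGeneric("nUnitigs"))

#' @rdname ccdbg-accessors
#' @export
setGeneric("nColors", function(x) standardGeneric("nColors"))

#' @rdname ccdbg-accessors
#' @export
setGeneric("nKmers", function(x) standardGeneric("nKmers"))

#' @rdname ccdbg-accessors
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))

#' @rdname ccdbg-accessors
#' @export
setGeneric("referenceNames", function(x) standardGeneric("referenceNames"))

#' @rdname ccdbg-accessors
#' @export
setGeneric("unitigSequences", function(x) standardGeneric("unitigSequences"))

#' @rdname ccdbg-accessors
#' @export
setGeneric("colorSet", function(x, j) standardGeneric("colorSet"))

#' @rdname ccdbg-accessors
#' @export
setGeneric("colorId", function(x, i) standardGeneric("colorId"))

#' @rdname colorRank
#' @export
setGeneric("rank1", function(x, i) standardGeneric("rank1"))

#' @rdname colorRank
#' @export
setGeneric("bitVector", function(x) standardGeneric("bitVector"))
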