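.TAG_LABELS <- c("sparse", "bitvector", "dense-complement")

#' Elias-delta codes for positive integers
#'
#' \code{eliasDelta} concatenates the Elias-delta codes of a vector of
#' positive integers into a bit stream (MSB-first within each byte);
#' \code{eliasDeltaDecode} reads them back. delta(1) = "1",
#' delta(2) = "0100".
#'
#' @param v positive integers (doubles accepted up to 2^53).
#' @param enc a list as returned by \code{eliasDelta}.
#' @param n how many values to decode (default: all that were encoded).
#' @return \code{eliasDelta}: a list with \code{bits} (raw), \code{nbits},
#'   \code{n}. \code{eliasDeltaDecode}: a numeric vector.
#' @examples
#' enc <- eliasDelta(c(1, 2, 17))
#' eliasDeltaDecode(enc)
#' @export
eliasDelta <- function(v) {
    res <- .delta_encode_cpp(as.numeric(v))
    list(bits = res$bits, nbits = res$nbits, n = length(v))
}

#' @rdname eliasDelta
#' @export
eliasDeltaDecode <- function(enc, n = enc$n) {
    .delta_decode_cpp(enc$bits, enc$nbits, n)
}

#' Elias-Fano encoding of a monotone sequence
#'
#' Encodes a non-decreasing sequence of n non-negative integers below a
#' universe bound u in about n(2 + log2(u/n)) bits, with constant-time
#' random access to the j-th value. Used as the offset directory delimiting
#' the concatenated color encodings.
#'
#' @param S non-decreasing non-negative integers.
#' @param u universe bound, \code{u > max(S)} (default \code{max(S) + 1}).
#' @param x an \code{EliasFano}.
#' @param j 1-based position(s).
#' @return \code{eliasFano}: an \code{\link{EliasFano}}. \code{efAccess}:
#'   the decoded value(s). \code{efSizeBits}: total encoded size in bits.
#' @examples
#' ef <- eliasFano(c(0, 3, 3, 10, 250))
#' efAccess(ef, 4)
#' @export
eliasFano <- function(S, u = if (length(S)) max(S) + 1 else 1) {
    S <- as.numeric(S)
    if (length(S) && is.unsorted(S)) stop("Elias-Fano requires a non-decreasing sequence")
    if (length(S) && u <= max(S)) stop("universe bound must exceed the largest value")
    new("EliasFano", ptr = .ef_build_cpp(S, as.numeric(u)),
        n = length(S), u = as.numeric(u))
}

#' @rdname eliasFano
#' @export
efAccess <- function(x, j) {
    stopifnot(is(x, "EliasFano"))
    .ef_access_cpp(x@ptr, as.numeric(j))
}

#' @rdname eliasFano
#' @export
efSizeBits <- function(x) {
    stopifnot(is(x, "EliasFano"))
    .ef_info_cpp(x@ptr)$sizeBits
}

setMethod("show", "EliasFano", function(object) {
    info <- .ef_info_cpp(object@ptr)
    cat(sprintf("EliasFano: n=%.0f value(s), universe %.0f, %d low bit(s)/value, %.0f bits total\n",
                info$n, info$u, info$lowBits, info$sizeBits))
    invisible(NULL)
})

#' Hybrid single-color codec
#'
#' Encodes one color (a strictly increasing set of reference ids in [1..N])
#' with the density-routed scheme. Let d = |C|/N: if d < 1/4 (strictly) the
#' set is stored sparse, as the Elias-delta code of its first value followed
#' by delta codes of the gaps; if d > 3/4 (strictly) its complement is
#' stored the same way (dense-complement); otherwise a characteristic
#' bit-vector of N bits is stored. A 2-bit tag and the delta-coded
#' cardinality precede the payload, so each color is self-describing.
#'
#' @param C strictly increasing integers in [1..N].
#' @param N number of references.
#' @param enc a list as returned by \code{encodeColor}.
#' @return \code{encodeColor}: a list with \code{tag} (one of
#'   \code{"sparse"}, \code{"bitvector"}, \code{"dense-complement"}),
#'   \code{bits} (raw), \code{nbits}, \code{N}. \code{decodeColor}: the
#'   integer set.
#' @examples
#' encodeColor(c(2, 5), N = 16)$tag
#' decodeColor(encodeColor(c(2, 5), N = 16))
#' @export
encodeColor <- function(C, N) {
    C <- as.integer(C)
    N <- as.integer(N)
    if (length(C) == 0L) stop("a color is non-empty by construction")
    if (is.unsorted(C, strictly = TRUE) || C[1L] < 1L || C[length(C)] > N)
        stop("a color must be strictly increasing within [1..N]")
    res <- .encode_color_cpp(C, N)
    list(tag = .TAG_LABELS[res$tag + 1L], bits = res$bits, nbits = res$nbits, N = N)
}

#' @rdname encodeColor
#' @export
decodeColor <- function(enc, N = enc$N) {
    .decode_color_cpp(enc$bits, enc$nbits, as.integer(N))
}

#' Build a compressed color store
#'
#' Encodes M colors with the hybrid codec (see \code{\link{encodeColor}}),
#' concatenates the encodings into one bit stream, and delimits them with an
#' Elias-Fano directory of M+1 bit offsets, so color j occupies the bit
#' range [offset(j), offset(j+1)).
#'
#' @param colors list of strictly increasing integer vectors in [1..N].
#' @param N number of references.
#' @return a \code{\link{ColorStore}}.
#' @examples
#' cs <- ColorStore(list(c(1, 3), 1:4), N = 4)
#' colorValues(cs, 2)
#' @export
ColorStore <- function(colors, N) {
    N <- as.integer(N)
    colors <- lapply(colors, as.integer)
    for (C in colors) {
        if (length(C) == 0L || is.unsorted(C, strictly = TRUE) ||
            C[1L] < 1L || C[length(C)] > N)
            stop("every color must be a non-empty strictly increasing set within [1..N]")
    }
    new("ColorStore", ptr = .cs_new_cpp(colors, N))
}

#' Iterate and combine stored colors
#'
#' @description Thin views over a \code{\link{ColorStore}}'s iterators.
#' \code{colorValues(x, j)} decodes color j in full by repeated
#' Value()/Next() calls. \code{colorStream(x, j, ncalls)} returns the first
#' \code{ncalls} Value() observations without stopping at exhaustion, making
#' the N+1 sentinel visible. \code{colorNextGEQ(x, j, v)} evaluates
#' NextGEQ(v) on a fresh iterator for each probe (smallest element >= v, or
#' N+1). \code{intersectColors(x, ids)} intersects the given colors with the
#' leapfrog algorithm driven by NextGEQ, never decoding a color in full
#' unless required.
#'
#' @param x a \code{ColorStore}.
#' @param j color id in 1..M.
#' @param ncalls how many Value() observations to record.
#' @param v probe value(s), non-negative.
#' @param ids color ids to intersect (at least one).
#' @return integer vectors; see the per-function descriptions.
#' @examples
#' cs <- ColorStore(list(c(1, 3), c(3, 4)), N = 4)
#' colorNextGEQ(cs, 1, c(2, 4))  # 3, then the sentinel 5
#' intersectColors(cs, c(1, 2))
#' @export
colorValues <- function(x, j) {
    stopifnot(is(x, "ColorStore"))
    .cs_decode_cpp(x@ptr, as.integer(j))
}

#' @rdname colorValues
#' @export
colorStream <- function(x, j, ncalls) {
    stopifnot(is(x, "ColorStore"))
    .cs_stream_cpp(x@ptr, as.integer(j), as.integer(ncalls))
}

#' @rdname colorValues
#' @export
colorNextGEQ <- function(x, j, v) {
    stopifnot(is(x, "ColorStore"))
    .cs_next_geq_cpp(x@ptr, as.integer(j), as.integer(v))
}

#' @rdname colorValues
#' @export
intersectColors <- function(x, ids) {
    stopifnot(is(x, "ColorStore"))
    .cs_intersect_cpp(x@ptr, as.integer(ids))
}

#' Per-color encoding statistics
#'
#' @param x a \code{ColorStore} or \code{CcdbgIndex}.
#' @return a data.frame with one row per color: \code{colorId},
#'   \code{tag}, \code{cardinality}, \code{density}, \code{bits}; attributes
#'   \code{offsetsBits} and \code{sequencesBits} carry the directory and
#'   stream totals.
#' @examples
#' cs <- ColorStore(list(c(1, 3), 1:4), N = 4)
#' colorStats(cs)
#' @export
colorStats <- function(x) {
    if (is(x, "ColorStore")) {
        st <- .cs_tag_cpp(x@ptr)
        info <- .cs_info_cpp(x@ptr)
        N <- info$N
        offb <- info$offsetsBits
        seqb <- info$sequencesBits
    } else if (is(x, "CcdbgIndex")) {
        st <- .idx_color_stats_cpp(x@ptr)
        N <- nReferences(x)
        offb <- st$offsetsBits
        seqb <- st$sequencesBits
    } else stop("colorStats needs a ColorStore or CcdbgIndex")
    out <- data.frame(colorId = seq_along(st$tag),
                      tag = .TAG_LABELS[st$tag + 1L],
                      cardinality = st$cardinality,
                      density = st$cardinality / N,
                      bits = st$bits,
                      stringsAsFactors = FALSE)
    attr(out, "offsetsBits") <- offb
    attr(out, "sequencesBits") <- seqb
    out
}

setMethod("show", "ColorStore", function(object) {
    info <- .cs_info_cpp(object@ptr)
    cat(sprintf("ColorStore: M=%d color(s) over N=%d reference(s), %.0f bits sequences + %.0f bits offsets\n",
                info$M, info$N, info$sequencesBits, info$offsetsBits))
    invisible(NULL)
})
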