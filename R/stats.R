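#' Compression workbench report
#'
#' Summarizes how the color store spends its space, bucketing the M colors
#' by density decile (|C|/N in (0, 0.1], (0.1, 0.2], ..., (0.9, 1]). For
#' each decile it reports the number and percentage of colors, how many use
#' each encoding (sparse / bitvector / dense-complement), the number and
#' percentage of stored integers, the encoded bits, and bits per integer.
#' The closing \code{"total"} row is comprehensive: its bits include the
#' Elias-Fano offset directory on top of the encoded lists, so its
#' bits-per-integer figure is the true storage cost per stored reference id.
#'
#' @param x a \code{CcdbgIndex} or \code{ColorStore}.
#' @return a data.frame with one row per non-empty decile plus the
#'   \code{"total"} row; attributes \code{sequencesBits} and
#'   \code{offsetsBits} carry the two components of the total.
#' @examples
#' idx <- buildIndex(c("ACGTACGTACG", "ACGTACGTACG"), k = 5, w = 3)
#' statsReport(idx)
#' @export
statsReport <- function(x) {
    st <- colorStats(x)
    seqb <- attr(st, "sequencesBits")
    offb <- attr(st, "offsetsBits")
    tot_int <- sum(st$cardinality)
    dec <- pmin(10L, pmax(1L, ceiling(st$density * 10)))
    row_of <- function(label, sel, bits) {
        data.frame(decile = label,
                   colors = nrow(sel),
                   pctColors = 100 * nrow(sel) / nrow(st),
                   sparse = sum(sel$tag == "sparse"),
                   bitvector = sum(sel$tag == "bitvector"),
                   denseComplement = sum(sel$tag == "dense-complement"),
                   integers = sum(sel$cardinality),
                   pctIntegers = 100 * sum(sel$cardinality) / tot_int,
                   bits = bits,
                   bitsPerInt = bits / sum(sel$cardinality),
                   stringsAsFactors = FALSE)
    }
    rows <- lapply(sort(unique(dec)), function(d) {
        sel <- st[dec == d, ]
        row_of(sprintf("(%.1f,%.1f]", (d - 1) / 10, d / 10), sel, sum(sel$bits))
    })
    out <- rbind(do.call(rbind, rows), row_of("total", st, seqb + offb))
    rownames(out) <- NULL
    attr(out, "sequencesBits") <- seqb
    attr(out, "offsetsBits") <- offb
    out
}

#' Mapping accuracy against a read-simulation truth table
#'
#' Scores a pseudoalignment result against the ground truth emitted by
#' \code{\link{simulateReads}}. A positive read counts as a true positive
#' when its reference of origin appears in the reported set; a negative read
#' counts as a false positive when it is mapped at all.
#'
#' @param result a \code{DataFrame} from \code{\link{pseudoalign}}, queried
#'   with the simulated reads in order.
#' @param truth the \code{truth} data.frame from \code{\link{simulateReads}}.
#' @return a list with \code{tpr}, \code{fpr}, \code{nPositive},
#'   \code{nNegative}.
#' @examples
#' refs <- generatePangenome(n = 3, length = 400, seed = 2)
#' idx <- buildIndex(refs, k = 15, w = 7)
#' rs <- simulateReads(refs, k = 15, readLength = 60, nReads = 40, seed = 4)
#' mappingMetrics(pseudoalign(idx, rs$reads), rs$truth)
#' @export
mappingMetrics <- function(result, truth) {
    stopifnot(nrow(result) == nrow(truth),
              identical(result$read, truth$name))
    pos <- truth$origin > 0
    tp <- sum(mapply(function(refs, o) o %in% refs,
                     as.list(result$refs[pos]), truth$origin[pos]))
    fp <- sum(result$mapped[!pos])
    list(tpr = if (any(pos)) tp / sum(pos) else NA_real_,
         fpr = if (any(!pos)) fp / sum(!pos) else NA_real_,
         nPositive = sum(pos), nNegative = sum(!pos))
}
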