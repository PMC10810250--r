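#' Generate a synthetic bacterial-style pangenome
#'
#' Derives N haplotypes from one random base genome through a shared pool of
#' variants (SNPs, insertions, deletions). Each variant gets a population
#' frequency drawn uniformly on (0, 1), and each reference carries each
#' variant independently with that probability. Because allele frequencies
#' span (0, 1), the resulting color densities cover the whole spectrum: rare
#' variants yield sparse colors, common ones mid-density colors, and the
#' conserved backbone yields colors containing (nearly) all references --
#' the dense regime the complemented encoding targets. With
#' \code{mutationRate = 0} and \code{indelRate = 0} all references are
#' identical and the graph has the single color [1..N].
#'
#' The generator is fully deterministic given \code{seed} and independent of
#' R's RNG state.
#'
#' @param n number of references.
#' @param length base genome length in bp.
#' @param mutationRate per-base SNP probability in the variant pool.
#' @param indelRate per-base indel probability; lengths are geometric with
#'   mean \code{indelMeanLength}.
#' @param indelMeanLength mean indel length.
#' @param seed integer seed.
#' @return a named \code{DNAStringSet} (\code{ref_001}, ...);
#'   \code{metadata()$variants} is a data.frame describing the pool
#'   (1-based \code{pos} on the base genome, \code{type}, \code{length},
#'   \code{freq}).
#' @examples
#' refs <- generatePangenome(n = 4, length = 300, seed = 7)
#' width(refs)
#' @export
generatePangenome <- function(n = 50L, length = 20000L, mutationRate = 0.005,
                              indelRate = 5e-4, indelMeanLength = 5,
                              seed = 1L) {
    res <- .gen_pangenome_cpp(as.integer(n), as.numeric(length), mutationRate,
                              indelRate, indelMeanLength, as.numeric(seed))
    refs <- Biostrings::DNAStringSet(res$sequences)
    names(refs) <- sprintf("ref_%03d", seq_len(n))
    v <- res$variants
    S4Vectors::metadata(refs)$variants <- data.frame(
        pos = v$pos, type = v$type, length = v$length, freq = v$freq,
        stringsAsFactors = FALSE)
    refs
}

#' Simulate reads with ground truth
#'
#' Draws \code{round(nReads * positiveFraction)} positive reads from random
#' (reference, position, strand) with independent per-base substitution
#' errors, then fills up with negative reads: uniform random sequences
#' rejection-sampled until none of their canonical k-mers occurs in the
#' reference collection, so a negative read is guaranteed k-mer-disjoint
#' from any index over these references. Deterministic given \code{seed}.
#'
#' @param refs character vector or \code{DNAStringSet} of references.
#' @param k k-mer length used for the disjointness guarantee.
#' @param readLength read length (>= k).
#' @param nReads total number of reads.
#' @param positiveFraction fraction of positive reads in [0, 1].
#' @param errorRate per-base substitution probability on positive reads.
#' @param seed integer seed.
#' @return a list with \code{reads} (named \code{DNAStringSet}) and
#'   \code{truth} (data.frame: \code{name}, \code{origin} -- reference id or
#'   0 for negatives, \code{start} 0-based, \code{reverse}).
#' @examples
#' refs <- generatePangenome(n = 2, length = 400, seed = 3)
#' rs <- simulateReads(refs, k = 15, readLength = 60, nReads = 10, seed = 5)
#' rs$truth[1:3, ]
#' @export
simulateReads <- function(refs, k = 31L, readLength = 150L, nReads = 1000L,
                          positiveFraction = 0.5, errorRate = 0.01,
                          seed = 1L) {
    rr <- .as_ref_chars(refs)
    res <- .sim_reads_cpp(rr$seqs, as.integer(k), as.integer(readLength),
                          as.integer(nReads), positiveFraction, errorRate,
                          as.numeric(seed))
    reads <- Biostrings::DNAStringSet(res$sequence)
    names(reads) <- res$name
    list(reads = reads,
         truth = data.frame(name = res$name, origin = res$origin,
                            start = res$start, reverse = res$reverse,
                            stringsAsFactors = FALSE))
}

#' Read reference sequences from disk
#'
#' Accepts a FASTA file (optionally gzip-compressed) or a file-of-files: a
#' plain text file listing one FASTA path per line, whose sequences are
#' concatenated in order. The format is detected from the first byte
#' (\code{>} means FASTA).
#'
#' @param path a FASTA file or a file-of-files.
#' @return a named \code{DNAStringSet}.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGTACGT"), f)
#' readReferences(f)
#' @export
readReferences <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    first <- readBin(path, "raw", n = 2L)
    is_gz <- length(first) == 2L && first[1L] == as.raw(0x1f) && first[2L] == as.raw(0x8b)
    if (is_gz || (length(first) >= 1L && first[1L] == charToRaw(">")))
        return(Biostrings::readDNAStringSet(path))
    files <- trimws(readLines(path))
    files <- files[nzchar(files)]
    if (length(files) == 0L) stop("file-of-files is empty: ", path)
    missing <- files[!file.exists(files)]
    if (length(missing)) stop("listed FASTA not found: ", paste(missing, collapse = ", "))
    do.call(c, lapply(files, Biostrings::readDNAStringSet))
}
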