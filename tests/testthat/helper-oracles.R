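# Independent pure-R oracles. These re-derive expected results from first
# principles (character operations, linear scans, counting) and share no code
# with the package internals.

o_revcomp <- function(s) {
    vapply(s, function(x) {
        paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

o_canonical <- function(s) {
    rc <- o_revcomp(s)
    ifelse(s <= rc, s, rc)
}

# all k-mer substrings of a sequence, split at non-ACGT characters
o_kmers_of <- function(seq, k) {
    frags <- strsplit(gsub("[^ACGT]+", " ", toupper(seq)), " ")[[1]]
    out <- character(0)
    for (f in frags) {
        L <- nchar(f)
        if (L >= k) out <- c(out, substring(f, 1:(L - k + 1), k:L))
    }
    out
}

# canonical k-mer -> sorted vector of reference ids containing it
o_kmer_colors <- function(refs, k) {
    refs <- toupper(as.character(refs))
    acc <- list()
    for (i in seq_along(refs)) {
        for (km in unique(o_canonical(o_kmers_of(refs[i], k))))
            acc[[km]] <- c(acc[[km]], i)
    }
    acc <- lapply(acc, function(v) sort(unique(v)))
    acc[order(names(acc))]
}

# number of ones in bits[1..i-1] (half-open prefix), bits logical
o_rank1 <- function(bits, i) {
    vapply(i, function(p) sum(bits[seq_len(p - 1L)]), numeric(1))
}

# full-intersection pseudoalignment of one read: references containing every
# positive k-mer (empty when no k-mer is positive)
o_align_full <- function(kcolors, read, k) {
    kms <- unique(o_canonical(o_kmers_of(read, k)))
    hits <- kcolors[intersect(kms, names(kcolors))]
    if (length(hits) == 0L) return(integer(0))
    sort(Reduce(intersect, hits))
}

# threshold-union of one read by direct counting: each positive k-mer
# position votes for every reference in its color; references with at least
# ceiling(s * tau) votes pass, where s is the positive (or total) k-mer count
o_align_threshold <- function(kcolors, read, k, tau, s_positive, N) {
    kms <- o_canonical(o_kmers_of(read, k))   # one entry per position
    votes <- numeric(N)
    positives <- 0L
    for (km in kms) {
        C <- kcolors[[km]]
        if (!is.null(C)) {
            positives <- positives + 1L
            votes[C] <- votes[C] + 1
        }
    }
    if (positives == 0L) return(integer(0))
    s <- if (s_positive) positives else length(kms)
    t <- max(1, ceiling(s * tau))
    which(votes >= t)
}

# expected hybrid-codec representation by density routing
o_color_tag <- function(card, N) {
    if (4 * card < N) "sparse"
    else if (4 * card > 3 * N) "dense-complement"
    else "bitvector"
}

# Elias-delta code of one positive integer as a 0/1 string (MSB first):
# gamma(len(x)) followed by the len(x)-1 low bits of x
o_delta_bits <- function(x) {
    bits_of <- function(v) {          # arithmetic on doubles: safe past 2^31
        n <- floor(log2(v)) + 1
        out <- integer(n)
        for (i in n:1) { out[i] <- v %% 2; v <- v %/% 2 }
        paste(out, collapse = "")
    }
    nb <- nchar(bits_of(x))
    g <- bits_of(nb)
    gamma <- paste0(strrep("0", nchar(g) - 1L), g)
    low <- if (nb > 1) substring(bits_of(x), 2L) else ""
    paste0(gamma, low)
}

# raw bit stream -> 0/1 string, MSB first within each byte
o_raw_to_bits <- function(bits, nbits) {
    v <- as.integer(rawToBits(bits))          # little-endian within byte
    per_byte <- split(v, rep(seq_len(length(bits)), each = 8L))
    s <- unlist(lapply(per_byte, rev), use.names = FALSE)
    paste(s[seq_len(nbits)], collapse = "")
}

# deterministic local RNG so tests never disturb (or depend on) global state
with_local_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# random strictly increasing subset of 1..N with cardinality card
o_random_color <- function(N, card) sort(sample.int(N, card))
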