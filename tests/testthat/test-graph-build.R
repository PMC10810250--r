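# graph construction: canonicalization, k-mer color map, unitig properties

test_that("canonicalizeKmer matches the character-level oracle", {
    kms <- c("ACG", "CGT", "GTT", "AAA", "TTT", "ATA", "TAT")
    res <- canonicalizeKmer(kms)
    expect_identical(res$canonical, o_canonical(kms))
    expect_identical(res$forward, res$canonical == kms)
})

test_that("canonical form is invariant under reverse complement", {
    with_local_seed(101, {
        for (rep in 1:50) {
            km <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
                        collapse = "")
            expect_identical(canonicalizeKmer(km)$canonical,
                             canonicalizeKmer(o_revcomp(km))$canonical)
        }
    })
})

test_that("extractKmerColors equals the sliding-window oracle", {
    refs <- c("ACGTTGCAACGT", "ACGTTGCA", "TTTTACGT")
    got <- extractKmerColors(refs, k = 5)
    expect_identical(got, o_kmer_colors(refs, 5))
})

test_that("extractKmerColors splits at non-ACGT characters", {
    refs <- c("ACGTTGNNNGGGCATT")
    got <- extractKmerColors(refs, k = 5)
    expect_identical(got, o_kmer_colors(refs, 5))
    expect_false(any(grepl("N", names(got))))
})

test_that("a single reference without repeats or RC branching is one unitig", {
    # no repeated canonical 5-mer and no 5-mer adjacent (in the canonical
    # graph) to the reverse complement of another, so nothing forces a cut
    r <- "AAGCGTTAGAGGCATTCAAG"
    g <- buildCcdbg(r, k = 5)
    expect_identical(nUnitigs(g), 1L)
    expect_identical(as.character(unitigSequences(g)[[1]]), r)
    expect_identical(colorSet(g, 1), 1L)
    expect_identical(nKmers(g), nchar(r) - 5 + 1)
})

test_that("every unitig is monochromatic and covers the k-mer set exactly once", {
    fx <- fx_small()
    g <- fx$graph
    k <- fx$k
    u <- as.character(unitigSequences(g))
    seen <- character(0)
    for (i in seq_along(u)) {
        kms <- o_canonical(o_kmers_of(u[i], k))
        expect_false(any(kms %in% seen))
        seen <- c(seen, kms)
        cols <- unique(lapply(kms, function(x) fx$kcolors[[x]]))
        expect_length(cols, 1L)                     # monochromatic
        expect_identical(cols[[1]], colorSet(g, colorId(g, i)))
    }
    expect_setequal(seen, names(fx$kcolors))        # exact partition
    expect_identical(nKmers(g), as.numeric(length(fx$kcolors)))
})

test_that("unitig layout is color-sorted with deterministic ids", {
    fx <- fx_small()
    g <- fx$graph
    ids <- colorId(g, seq_len(nUnitigs(g)))
    expect_false(is.unsorted(ids))
    expect_identical(sort(unique(ids)), seq_len(nColors(g)))
    # colors ordered by (cardinality, content)
    sets <- lapply(seq_len(nColors(g)), function(j) colorSet(g, j))
    card <- lengths(sets)
    expect_false(is.unsorted(card))
    # unitigs within one color group sorted by spelling
    u <- as.character(unitigSequences(g))
    for (j in unique(ids)) expect_false(is.unsorted(u[ids == j]))
})

test_that("tilings re-spell every reference (round trip)", {
    fx <- fx_small()
    sp <- spellTilings(fx$graph)
    expect_identical(unname(vapply(sp, paste, "", collapse = "")),
                     unname(as.character(fx$refs)))
})

test_that("tilings re-spell fragmented references around non-ACGT runs", {
    refs <- c(x = "ACGTTGCAACGTNNNTTGCAACGTACGT", y = "ACGTTGCAACGT")
    g <- buildCcdbg(refs, k = 5)
    sp <- spellTilings(g)
    expect_identical(sp$x, strsplit(gsub("N+", " ", refs[["x"]]), " ")[[1]])
    expect_identical(sp$y, refs[["y"]])
})

test_that("boundary k-mers terminate unitigs (monochromatic sentinel cuts)", {
    # b is a strict prefix of a: the shared part and the a-only part must be
    # distinct unitigs with distinct colors even though the path continues
    refs <- c(a = "ACCCTCAGTAC", b = "ACCCTC")
    g <- buildCcdbg(refs, k = 3)
    sets <- lapply(seq_len(nColors(g)), function(j) colorSet(g, j))
    expect_true(any(vapply(sets, identical, TRUE, y = c(1L, 2L))))
    expect_true(any(vapply(sets, identical, TRUE, y = 1L)))
    # each reference still round-trips through its own tiling
    sp <- spellTilings(g)
    expect_identical(sp$a, unname(refs[["a"]]))
    expect_identical(sp$b, unname(refs[["b"]]))
})

test_that("graph construction is deterministic", {
    fx <- fx_small()
    g2 <- buildCcdbg(fx$refs, k = fx$k)
    expect_identical(as.character(unitigSequences(g2)),
                     as.character(unitigSequences(fx$graph)))
    expect_identical(colorId(g2, seq_len(nUnitigs(g2))),
                     colorId(fx$graph, seq_len(nUnitigs(fx$graph))))
    expect_identical(tilings(g2), tilings(fx$graph))
})

test_that("graph construction on random property instances matches the oracle", {
    with_local_seed(202, {
        for (rep in 1:20) {
            n <- sample(2:4, 1)
            refs <- vapply(seq_len(n), function(i) {
                paste(sample(c("A", "C", "G", "T"), sample(20:60, 1),
                             replace = TRUE), collapse = "")
            }, character(1))
            k <- sample(c(5L, 7L), 1)
            g <- buildCcdbg(refs, k = k)
            oc <- o_kmer_colors(refs, k)
            expect_identical(nKmers(g), as.numeric(length(oc)))
            # partition invariant: sum over unitigs of (|u| - k + 1) = n
            expect_identical(sum(Biostrings::width(unitigSequences(g)) - k + 1L),
                             length(oc))
            # per-k-mer colors agree
            u <- as.character(unitigSequences(g))
            for (i in seq_along(u)) {
                for (km in o_canonical(o_kmers_of(u[i], k)))
                    expect_identical(oc[[km]], colorSet(g, colorId(g, i)))
            }
            # tilings round-trip
            expect_identical(unname(vapply(spellTilings(g), paste, "",
                                           collapse = "")), toupper(refs))
        }
    })
})

test_that("invalid k is rejected", {
    expect_error(buildCcdbg("ACGTACGT", k = 4), "odd")
    expect_error(buildCcdbg("ACGTACGT", k = 33), "31")
    expect_error(buildCcdbg("ACGTACGT", k = 1), "k")
})

test_that("a collection with no valid k-mer warns and yields an empty graph", {
    expect_warning(g <- buildCcdbg("NNNNNNN", k = 5), "no valid k-mer")
    expect_identical(nUnitigs(g), 0L)
    expect_identical(nKmers(g), 0)
})

test_that("writeUnitigs emits one labelled FASTA record per unitig", {
    fx <- fx_small()
    f <- withr::local_tempfile(fileext = ".fa")
    writeUnitigs(fx$graph, f)
    lines <- readLines(f)
    expect_length(lines, 2L * nUnitigs(fx$graph))
    expect_identical(lines[seq(2, length(lines), by = 2)],
                     as.character(unitigSequences(fx$graph)))
    expect_match(lines[1], "^>unitig_1 color=1 refs=")
})
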