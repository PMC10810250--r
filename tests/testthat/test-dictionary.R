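# order-preserving k-mer dictionary: exact lookup, streaming, serialization

test_that("every indexed k-mer is found at its unitig position", {
    fx <- fx_small()
    idx <- fx$index
    u <- as.character(unitigSequences(idx))
    k <- fx$k
    for (i in seq_along(u)) {
        L <- nchar(u[i])
        kms <- substring(u[i], 1:(L - k + 1), k:L)
        hit <- lookupKmer(idx, kms)
        expect_identical(hit$unitig, rep(i, L - k + 1))
        expect_identical(hit$offset, 0:(L - k))
        expect_true(all(hit$forward))
    }
})

test_that("reverse complements are found with forward = FALSE", {
    fx <- fx_small()
    u1 <- as.character(unitigSequences(fx$index))[1]
    km <- substr(u1, 3, 3 + fx$k - 1)
    hit <- lookupKmer(fx$index, o_revcomp(km))
    expect_identical(hit$unitig, 1L)
    expect_identical(hit$offset, 2L)
    expect_false(hit$forward)
})

test_that("the dictionary has no false positives", {
    fx <- fx_small()
    indexed <- names(fx$kcolors)
    with_local_seed(303, {
        probes <- vapply(1:500, function(i) {
            paste(sample(c("A", "C", "G", "T"), fx$k, replace = TRUE),
                  collapse = "")
        }, character(1))
    })
    absent <- probes[!(o_canonical(probes) %in% indexed)]
    hit <- lookupKmer(fx$index, absent)
    expect_true(all(is.na(hit$unitig)))
    present <- probes[o_canonical(probes) %in% indexed]
    if (length(present)) expect_true(all(!is.na(lookupKmer(fx$index, present)$unitig)))
})

test_that("k-mers containing non-ACGT report absent; wrong length errors", {
    fx <- fx_small()
    bad <- paste0("N", strrep("A", fx$k - 1L))
    expect_true(is.na(lookupKmer(fx$index, bad)$unitig))
    expect_error(lookupKmer(fx$index, "ACG"), "length")
})

test_that("streaming lookup equals per-k-mer lookup on real reads", {
    fx <- fx_small()
    rs <- fx_small_reads()
    k <- fx$k
    for (q in as.character(rs$reads[1:50])) {
        sl <- streamingLookup(fx$index, q)
        P <- nchar(q) - k + 1
        kms <- substring(q, 1:P, k:nchar(q))
        one <- lookupKmer(fx$index, kms)
        expect_identical(sl$hits$unitig, one$unitig)
        expect_identical(sl$hits$offset, one$offset)
        expect_identical(sl$hits$forward, one$forward)
    }
})

test_that("streaming exploits locality: cache hits and bucket reuse occur", {
    fx <- fx_small()
    q <- as.character(fx$refs[[1]])
    sl <- streamingLookup(fx$index, q)
    P <- nchar(q) - fx$k + 1
    expect_gt(sl$cacheHits, 0)
    # every position is accounted for by exactly one path
    expect_identical(sl$cacheHits + sl$bucketReuse + sl$searches, as.numeric(P))
    # contiguous reference text: the vast majority of positions extend the cache
    expect_gt(sl$cacheHits / P, 0.8)
})

test_that("streaming on reverse-strand sequence also extends the cache", {
    fx <- fx_small()
    q <- o_revcomp(substr(as.character(fx$refs[[2]]), 1, 100))
    sl <- streamingLookup(fx$index, q)
    expect_gt(sl$cacheHits, 0)
})

test_that("a sequence shorter than k streams to an empty, flagged result", {
    fx <- fx_small()
    sl <- streamingLookup(fx$index, strrep("A", fx$k - 1L))
    expect_true(sl$tooShort)
    expect_identical(nrow(sl$hits), 0L)
})

test_that("minimizer length is validated at build time", {
    g <- fx_small()$graph
    expect_error(buildIndex(g, w = 15), "smaller than k")
    expect_error(buildIndex(g, w = 0), "positive")
})

test_that("an index round-trips through its binary file byte-for-byte", {
    fx <- fx_wide()
    f1 <- withr::local_tempfile(fileext = ".ccxi")
    f2 <- withr::local_tempfile(fileext = ".ccxi")
    saveIndex(fx$index, f1)
    idx2 <- loadIndex(f1)
    saveIndex(idx2, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    expect_identical(unitigSequences(idx2), unitigSequences(fx$index))
    expect_identical(nKmers(idx2), nKmers(fx$index))
    expect_identical(minimizerLength(idx2), minimizerLength(fx$index))
    expect_identical(referenceNames(idx2), referenceNames(fx$index))
})

test_that("a loaded index answers queries identically to the original", {
    fx <- fx_small()
    rs <- fx_small_reads()
    f <- withr::local_tempfile(fileext = ".ccxi")
    saveIndex(fx$index, f)
    idx2 <- loadIndex(f)
    r1 <- pseudoalign(fx$index, rs$reads[1:200])
    r2 <- pseudoalign(idx2, rs$reads[1:200])
    expect_identical(as.list(r1$refs), as.list(r2$refs))
})

test_that("corrupted index files are refused", {
    fx <- fx_small()
    f <- withr::local_tempfile(fileext = ".ccxi")
    saveIndex(fx$index, f)
    bytes <- readBin(f, "raw", file.size(f))
    # flip one payload byte: checksum must catch it
    bad <- bytes
    pos <- length(bytes) - 20L
    bad[pos] <- xor(bad[pos], as.raw(0xFF))
    writeBin(bad, f)
    expect_error(loadIndex(f), "refusing to load|checksum|corrupt")
    # wrong magic
    bad2 <- bytes
    bad2[1] <- as.raw(0x00)
    writeBin(bad2, f)
    expect_error(loadIndex(f), "refusing to load|magic|not a")
})
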