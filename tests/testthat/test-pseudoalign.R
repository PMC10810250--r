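# pseudoalignment query modes against naive per-k-mer oracles

test_that("full-intersection equals the naive oracle on simulated reads", {
    fx <- fx_small()
    rs <- fx_small_reads()
    res <- pseudoalign(fx$index, rs$reads)
    want <- lapply(unname(as.character(rs$reads)), o_align_full,
                   kcolors = fx$kcolors, k = fx$k)
    expect_identical(lapply(as.list(res$refs), as.integer),
                     lapply(want, as.integer))
})

test_that("positive error-free reads map to their origin; negatives map nowhere", {
    fx <- fx_small()
    rs <- simulateReads(fx$refs, k = fx$k, readLength = 80, nReads = 200,
                        positiveFraction = 0.5, errorRate = 0, seed = 77)
    res <- pseudoalign(fx$index, rs$reads)
    pos <- rs$truth$origin > 0
    expect_true(all(res$mapped[pos]))
    expect_true(all(mapply(function(refs, o) o %in% refs,
                           as.list(res$refs[pos]), rs$truth$origin[pos])))
    expect_false(any(res$mapped[!pos]))
    expect_true(all(res$positives[!pos] == 0))
})

test_that("threshold-union equals the counting oracle for both s modes", {
    fx <- fx_small()
    rs <- fx_small_reads()
    reads <- unname(as.character(rs$reads))
    N <- nReferences(fx$index)
    for (tau in c(0.5, 0.8, 1.0)) {
        for (sm in c("positive", "all")) {
            res <- pseudoalign(fx$index, rs$reads, mode = "threshold-union",
                               tau = tau, sMode = sm)
            want <- lapply(reads, o_align_threshold, kcolors = fx$kcolors,
                           k = fx$k, tau = tau, s_positive = sm == "positive",
                           N = N)
            expect_identical(lapply(as.list(res$refs), as.integer),
                             lapply(want, as.integer))
        }
    }
})

test_that("threshold-union at tau = 1 with positive s contains full-intersection", {
    fx <- fx_small()
    rs <- fx_small_reads()
    full <- pseudoalign(fx$index, rs$reads)
    thr <- pseudoalign(fx$index, rs$reads, mode = "threshold-union",
                       tau = 1.0, sMode = "positive")
    # a reference in every positive k-mer's color is covered s times
    for (i in seq_len(nrow(full)))
        expect_true(all(full$refs[[i]] %in% thr$refs[[i]]))
})

test_that("threshold-union is monotone in tau", {
    fx <- fx_small()
    rs <- fx_small_reads()
    r5 <- pseudoalign(fx$index, rs$reads[1:200], mode = "threshold-union", tau = 0.5)
    r9 <- pseudoalign(fx$index, rs$reads[1:200], mode = "threshold-union", tau = 0.9)
    for (i in 1:200) expect_true(all(r9$refs[[i]] %in% r5$refs[[i]]))
})

test_that("invalid thresholds are rejected", {
    fx <- fx_small()
    expect_error(pseudoalign(fx$index, "ACGT", mode = "threshold-union", tau = 0), "tau")
    expect_error(pseudoalign(fx$index, "ACGT", mode = "threshold-union", tau = 1.2), "tau")
})

test_that("skipping modes: every confirmed position is a real hit and queries are bounded", {
    fx <- fx_small()
    rs <- fx_small_reads()
    reads <- unname(as.character(rs$reads))
    for (mode in c("skip-kallisto-like", "skip-backoff-like")) {
        res <- pseudoalign(fx$index, rs$reads, mode = mode)
        expect_true(all(res$queries <= res$nKmers))
        for (i in seq_along(reads)) {
            conf <- res$confirmed[[i]]
            if (length(conf) == 0L) {
                expect_length(res$refs[[i]], 0L)
                next
            }
            k <- fx$k
            kms <- substring(reads[i], conf + 1L, conf + k)
            hit <- lookupKmer(fx$index, kms)
            expect_false(any(is.na(hit$unitig)))
            # reported refs = intersection of the confirmed k-mers' colors
            cids <- unique(colorId(fx$index, hit$unitig))
            want <- Reduce(intersect, lapply(cids, colorSet, x = fx$index))
            expect_identical(as.integer(res$refs[[i]]), as.integer(sort(want)))
        }
    }
})

test_that("skipping saves queries on long error-free reads", {
    fx <- fx_small()
    rs <- simulateReads(fx$refs, k = fx$k, readLength = 120, nReads = 100,
                        positiveFraction = 1, errorRate = 0, seed = 99)
    res <- pseudoalign(fx$index, rs$reads, mode = "skip-kallisto-like")
    expect_lt(sum(res$queries), sum(res$nKmers))
})

test_that("skipping equals full-intersection on error-free single-unitig reads", {
    fx <- fx_small()
    rs <- simulateReads(fx$refs, k = fx$k, readLength = 60, nReads = 300,
                        positiveFraction = 1, errorRate = 0, seed = 13)
    full <- pseudoalign(fx$index, rs$reads)
    for (mode in c("skip-kallisto-like", "skip-backoff-like")) {
        sk <- pseudoalign(fx$index, rs$reads, mode = mode)
        for (i in seq_len(nrow(full))) {
            # restrict to reads whose k-mers all fall in one unitig
            sl <- streamingLookup(fx$index, as.character(rs$reads[[i]]))
            if (length(unique(sl$hits$unitig)) == 1L && !anyNA(sl$hits$unitig))
                expect_identical(as.integer(sk$refs[[i]]),
                                 as.integer(full$refs[[i]]))
        }
    }
})

test_that("reads shorter than k yield zero k-mers and no mapping in every mode", {
    fx <- fx_small()
    short <- strrep("A", fx$k - 1L)
    for (mode in c("full-intersection", "threshold-union",
                   "skip-kallisto-like", "skip-backoff-like")) {
        res <- pseudoalign(fx$index, short, mode = mode)
        expect_identical(res$nKmers, 0)
        expect_false(res$mapped)
    }
})

test_that("result metadata records the query parameters", {
    fx <- fx_small()
    r <- pseudoalign(fx$index, "ACGTACGTACGTACGTACGT",
                     mode = "threshold-union", tau = 0.65, sMode = "all")
    md <- S4Vectors::metadata(r)
    expect_identical(md$mode, "threshold-union")
    expect_identical(md$tau, 0.65)
    expect_identical(md$sMode, "all")
    rk <- pseudoalign(fx$index, "ACGTACGTACGTACGTACGT", mode = "skip-kallisto-like")
    mk <- S4Vectors::metadata(rk)
    expect_identical(mk$onMiss, "query-next")
    expect_identical(mk$onUnexpected, "aggressive-jump")
    rb <- pseudoalign(fx$index, "ACGTACGTACGTACGTACGT", mode = "skip-backoff-like")
    mb <- S4Vectors::metadata(rb)
    expect_identical(mb$onMiss, "back-off")
    expect_identical(mb$backOffLimit, 4L)
})

test_that("writeMappings emits the self-describing TSV layout", {
    fx <- fx_small()
    reads <- c(r1 = as.character(fx$refs[[1]]), r2 = strrep("A", 40))
    res <- pseudoalign(fx$index, reads, mode = "threshold-union", tau = 0.8)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeMappings(res, f)
    lines <- readLines(f)
    expect_identical(lines[1:3], c("# mode: threshold-union", "# tau: 0.8",
                                   "# s_mode: positive"))
    row1 <- strsplit(lines[4], "\t")[[1]]
    expect_identical(row1[1], "r1")
    expect_identical(as.integer(row1[2]), length(res$refs[[1]]))
    expect_identical(as.integer(row1[-(1:2)]), res$refs[[1]] - 1L)  # 0-based
    expect_identical(strsplit(lines[5], "\t")[[1]], c("r2", "0"))
    # names instead of ids
    writeMappings(res, f, useNames = TRUE, index = fx$index)
    row1n <- strsplit(readLines(f)[4], "\t")[[1]]
    expect_identical(row1n[-(1:2)],
                     referenceNames(fx$index)[res$refs[[1]]])
})
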