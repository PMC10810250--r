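# fixtures, I/O, and the compression statistics report

test_that("the pangenome generator is deterministic and seed-sensitive", {
    a <- generatePangenome(n = 4, length = 400, seed = 5)
    b <- generatePangenome(n = 4, length = 400, seed = 5)
    c <- generatePangenome(n = 4, length = 400, seed = 6)
    expect_identical(as.character(a), as.character(b))
    expect_false(identical(as.character(a), as.character(c)))
    expect_identical(names(a), sprintf("ref_%03d", 1:4))
    v <- S4Vectors::metadata(a)$variants
    expect_true(all(v$freq > 0 & v$freq < 1))
    expect_true(all(v$type %in% c("snp", "ins", "del")))
})

test_that("zero variant rates produce identical references and one color", {
    refs <- generatePangenome(n = 6, length = 600, mutationRate = 0,
                              indelRate = 0, seed = 9)
    expect_identical(length(unique(as.character(refs))), 1L)
    g <- buildCcdbg(refs, k = 21)
    expect_identical(nColors(g), 1L)
    expect_identical(colorSet(g, 1), 1:6)
})

test_that("variant-frequency design yields colors across the density spectrum", {
    fx <- fx_wide()
    st <- colorStats(fx$index)
    expect_setequal(unique(st$tag),
                    c("sparse", "bitvector", "dense-complement"))
    expect_gt(max(st$density), 0.9)
    expect_lt(min(st$density), 0.25)
})

test_that("simulated reads honour their ground truth", {
    fx <- fx_small()
    rs <- fx_small_reads()
    tr <- rs$truth
    expect_identical(names(rs$reads), tr$name)
    pos <- tr$origin > 0
    expect_identical(sum(pos), 500L)
    # positives re-derive from (origin, start, strand) up to substitutions
    for (i in head(which(pos), 30)) {
        src <- substr(as.character(fx$refs[[tr$origin[i]]]),
                      tr$start[i] + 1L, tr$start[i] + 80L)
        if (tr$reverse[i]) src <- o_revcomp(src)
        got <- as.character(rs$reads[[i]])
        expect_identical(nchar(got), nchar(src))
        expect_lt(mean(strsplit(got, "")[[1]] != strsplit(src, "")[[1]]), 0.1)
    }
    # negatives are k-mer-disjoint from the reference collection
    for (i in which(!pos))
        expect_false(any(o_canonical(o_kmers_of(as.character(rs$reads[[i]]),
                                                fx$k)) %in% names(fx$kcolors)))
})

test_that("readReferences handles FASTA, gzip, and file-of-files", {
    fa1 <- withr::local_tempfile(fileext = ".fa")
    fa2 <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">s1", "ACGTACGTAA", ">s2", "TTGCAACGTT"), fa1)
    writeLines(c(">s3", "GGGCCCAATT"), fa2)
    refs <- readReferences(fa1)
    expect_identical(names(refs), c("s1", "s2"))
    expect_identical(as.character(refs[["s1"]]), "ACGTACGTAA")
    # gzip
    gz <- withr::local_tempfile(fileext = ".fa.gz")
    con <- gzfile(gz, "w")
    writeLines(c(">g1", "ACACACACAC"), con)
    close(con)
    expect_identical(as.character(readReferences(gz)[["g1"]]), "ACACACACAC")
    # file-of-files concatenates in order
    fofn <- withr::local_tempfile(fileext = ".txt")
    writeLines(c(fa1, fa2), fofn)
    all3 <- readReferences(fofn)
    expect_identical(names(all3), c("s1", "s2", "s3"))
    expect_error(readReferences(tempfile()), "no such file")
    bad <- withr::local_tempfile()
    writeLines("/nonexistent/path.fa", bad)
    expect_error(readReferences(bad), "not found")
})

test_that("an index built from files equals one built in memory", {
    fx <- fx_small()
    fa <- withr::local_tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(fx$refs, fa)
    idx2 <- buildIndex(readReferences(fa), k = fx$k, w = 7)
    expect_identical(unitigSequences(idx2), unitigSequences(fx$index))
    expect_identical(referenceNames(idx2), referenceNames(fx$index))
})

test_that("statsReport deciles are consistent with per-color bit accounting", {
    fx <- fx_wide()
    st <- colorStats(fx$index)
    rep_ <- statsReport(fx$index)
    total <- rep_[rep_$decile == "total", ]
    body <- rep_[rep_$decile != "total", ]
    expect_identical(total$colors, nrow(st))
    expect_identical(total$integers, sum(st$cardinality))
    # the total row is comprehensive: encoded lists plus offset directory
    expect_identical(total$bits,
                     attr(st, "sequencesBits") + attr(st, "offsetsBits"))
    expect_equal(total$bitsPerInt, total$bits / sum(st$cardinality))
    expect_identical(sum(body$colors), total$colors)
    expect_identical(sum(body$integers), total$integers)
    expect_identical(sum(body$bits), attr(st, "sequencesBits"))
    expect_identical(body$colors,
                     body$sparse + body$bitvector + body$denseComplement)
    # percentages conserve mass
    expect_equal(sum(body$pctColors), 100, tolerance = 1e-4)
    expect_equal(sum(body$pctIntegers), 100, tolerance = 1e-4)
    # per-decile bpi recomputed by a direct bit-accounting oracle
    dec <- pmin(10, pmax(1, ceiling(st$density * 10)))
    for (r in seq_len(nrow(body))) {
        d <- match(body$decile[r],
                   sprintf("(%.1f,%.1f]", (1:10 - 1) / 10, (1:10) / 10))
        sel <- st[dec == d, ]
        expect_identical(body$bits[r], sum(sel$bits))
        expect_equal(body$bitsPerInt[r], sum(sel$bits) / sum(sel$cardinality))
    }
    # dense colors must be cheaper per integer than sparse ones here
    if (any(body$decile == "(0.9,1.0]") && any(body$decile == "(0.0,0.1]"))
        expect_lt(body$bitsPerInt[body$decile == "(0.9,1.0]"],
                  body$bitsPerInt[body$decile == "(0.0,0.1]"])
})

test_that("a single full color puts all mass in the top decile", {
    refs <- generatePangenome(n = 5, length = 500, mutationRate = 0,
                              indelRate = 0, seed = 21)
    idx <- buildIndex(refs, k = 15, w = 7)
    rep_ <- statsReport(idx)
    body <- rep_[rep_$decile != "total", ]
    expect_identical(body$decile, "(0.9,1.0]")
    expect_equal(body$pctColors, 100)
    expect_equal(body$pctIntegers, 100)
})

test_that("mapping metrics against the truth table match the naive oracle", {
    fx <- fx_small()
    rs <- simulateReads(fx$refs, k = fx$k, readLength = 80, nReads = 10000,
                        positiveFraction = 0.25, errorRate = 0.01, seed = 29)
    full <- pseudoalign(fx$index, rs$reads)
    m <- mappingMetrics(full, rs$truth)
    expect_identical(m$nPositive, 2500L)
    expect_identical(m$nNegative, 7500L)
    # negatives are k-mer-disjoint by construction: no mode can map them
    expect_identical(m$fpr, 0)
    for (mode in c("threshold-union", "skip-kallisto-like", "skip-backoff-like"))
        expect_identical(mappingMetrics(pseudoalign(fx$index, rs$reads,
                                                    mode = mode),
                                        rs$truth)$fpr, 0)
    # exhaustive-mode TPR equals the TPR derived from the naive oracle
    pos <- rs$truth$origin > 0
    oracle_tp <- sum(mapply(function(q, o) {
        o %in% o_align_full(fx$kcolors, q, fx$k)
    }, unname(as.character(rs$reads[pos])), rs$truth$origin[pos]))
    expect_identical(m$tpr, oracle_tp / sum(pos))
})

test_that("show methods print a one-glance summary", {
    fx <- fx_small()
    expect_output(show(fx$graph), "CcdbgGraph: k=15")
    expect_output(show(fx$index), "color encodings:")
    expect_output(show(buildColorRank(c(1, 1, 2))), "ColorRank")
    expect_output(show(ColorStore(list(1:2), 4)), "ColorStore")
    expect_output(show(eliasFano(c(1, 5))), "EliasFano")
})
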