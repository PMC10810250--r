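# compressed color store: codecs, directory, iterators, combinators

test_that("Elias-delta round-trips and matches hand-computed codes", {
    expect_identical(eliasDeltaDecode(eliasDelta(1)), 1)
    expect_identical(o_raw_to_bits(eliasDelta(1)$bits, eliasDelta(1)$nbits), "1")
    expect_identical(o_raw_to_bits(eliasDelta(2)$bits, eliasDelta(2)$nbits), "0100")
    for (x in c(1, 2, 3, 7, 8, 100, 2^31, 2^50)) {
        enc <- eliasDelta(x)
        expect_identical(eliasDeltaDecode(enc), x)
        expect_identical(o_raw_to_bits(enc$bits, enc$nbits), o_delta_bits(x))
    }
})

test_that("Elias-delta round-trips vectors and rejects non-positive input", {
    with_local_seed(505, v <- sort(sample(1:1e6, 200)))
    expect_identical(eliasDeltaDecode(eliasDelta(v)), as.numeric(v))
    expect_error(eliasDelta(0), "positive")
    expect_error(eliasDelta(-3), "positive")
    expect_error(eliasDelta(1.5), "positive integers")
})

test_that("Elias-Fano reproduces the sequence and respects the size bound", {
    with_local_seed(606, {
        for (rep in 1:20) {
            n <- sample(1:200, 1)
            u <- sample(n:10000, 1) + 1
            S <- sort(sample(0:(u - 1), n, replace = TRUE))
            ef <- eliasFano(S, u)
            expect_identical(efAccess(ef, seq_len(n)), as.numeric(S))
            # n(2 + ceil(log2(u/n))) plus word-alignment slack
            expect_lte(efSizeBits(ef), n * (2 + max(0, ceiling(log2(u / n)))) + 192)
        }
    })
    expect_error(eliasFano(c(3, 1)), "non-decreasing")
    expect_error(eliasFano(c(1, 5), u = 5), "universe")
    ef <- eliasFano(c(0, 7))
    expect_error(efAccess(ef, 3), "range")
})

test_that("density routing picks the documented representation", {
    N <- 16L
    expect_identical(encodeColor(1, N)$tag, "sparse")            # 1/16 < 1/4
    expect_identical(encodeColor(1:3, N)$tag, "sparse")          # 3/16 < 1/4
    expect_identical(encodeColor(1:4, N)$tag, "bitvector")       # exactly 1/4
    expect_identical(encodeColor(1:12, N)$tag, "bitvector")      # exactly 3/4
    expect_identical(encodeColor(1:13, N)$tag, "dense-complement")
    expect_identical(encodeColor(1:16, N)$tag, "dense-complement")
    with_local_seed(707, {
        for (rep in 1:100) {
            n <- sample(2:64, 1)
            card <- sample(1:n, 1)
            C <- o_random_color(n, card)
            expect_identical(encodeColor(C, n)$tag, o_color_tag(card, n))
        }
    })
})

test_that("the hybrid codec round-trips across the density spectrum", {
    with_local_seed(808, {
        for (rep in 1:200) {
            N <- sample(1:100, 1)
            C <- o_random_color(N, sample(1:N, 1))
            expect_identical(decodeColor(encodeColor(C, N)), C)
        }
    })
    # full color: complement is empty, no payload beyond the header
    enc <- encodeColor(1:20, 20)
    expect_identical(enc$tag, "dense-complement")
    expect_identical(decodeColor(enc), 1:20)
})

test_that("invalid colors are rejected by the codec", {
    expect_error(encodeColor(integer(0), 4), "non-empty")
    expect_error(encodeColor(c(2, 2), 4), "strictly increasing")
    expect_error(encodeColor(c(0, 2), 4), "within")
    expect_error(encodeColor(5, 4), "within")
})

test_that("a store decodes every color and sizes its directory as M+1 offsets", {
    with_local_seed(909, {
        N <- 40L
        colors <- lapply(1:50, function(i) o_random_color(N, sample(1:N, 1)))
        cs <- ColorStore(colors, N)
        for (j in seq_along(colors))
            expect_identical(colorValues(cs, j), colors[[j]])
        st <- colorStats(cs)
        expect_identical(st$cardinality, lengths(colors))
        expect_identical(st$tag,
                         vapply(lengths(colors), o_color_tag, "", N = N))
        # each color's bits equal its standalone encoding
        for (j in seq_along(colors))
            expect_identical(st$bits[j], encodeColor(colors[[j]], N)$nbits)
        expect_identical(sum(st$bits), attr(st, "sequencesBits"))
    })
})

test_that("iterators expose the N+1 sentinel after exhaustion", {
    N <- 10L
    cs <- ColorStore(list(c(2L, 5L), 1:10, c(1L, 4L, 6L, 7L, 8L, 9L, 10L)), N)
    expect_identical(colorStream(cs, 1, 5), c(2L, 5L, 11L, 11L, 11L))
    expect_identical(colorStream(cs, 2, 12), c(1:10, 11L, 11L))
    expect_identical(colorStream(cs, 3, 9), c(1L, 4L, 6L, 7L, 8L, 9L, 10L, 11L, 11L))
})

test_that("NextGEQ matches a linear-scan oracle for every representation", {
    with_local_seed(111, {
        N <- 30L
        colors <- list(o_random_color(N, 3),    # sparse
                       o_random_color(N, 15),   # bitvector
                       o_random_color(N, 27))   # dense-complement
        cs <- ColorStore(colors, N)
        st <- colorStats(cs)
        expect_setequal(st$tag, c("sparse", "bitvector", "dense-complement"))
        for (j in seq_along(colors)) {
            C <- colors[[j]]
            probes <- 0:(N + 1)
            want <- vapply(probes, function(x) {
                geq <- C[C >= x]
                if (length(geq)) geq[1] else N + 1L
            }, integer(1))
            expect_identical(colorNextGEQ(cs, j, probes), want)
        }
    })
})

test_that("leapfrog intersection equals Reduce(intersect)", {
    with_local_seed(222, {
        N <- 25L
        colors <- lapply(1:12, function(i) o_random_color(N, sample(1:N, 1)))
        cs <- ColorStore(colors, N)
        for (rep in 1:30) {
            ids <- sample(seq_along(colors), sample(1:5, 1))
            want <- sort(Reduce(intersect, colors[ids]))
            expect_identical(intersectColors(cs, ids), as.integer(want))
        }
        # a disjoint pair intersects to empty
        cs2 <- ColorStore(list(c(1L, 3L), c(2L, 4L)), 4L)
        expect_identical(intersectColors(cs2, c(1, 2)), integer(0))
    })
})

test_that("store contents equal the graph colors inside a full index", {
    fx <- fx_wide()
    g <- fx$graph
    idx <- fx$index
    for (j in seq_len(nColors(g)))
        expect_identical(colorSet(idx, j), colorSet(g, j))
    st <- colorStats(idx)
    expect_identical(st$tag,
                     vapply(st$cardinality, o_color_tag, "", N = nReferences(idx)))
})
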