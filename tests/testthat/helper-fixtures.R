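# Shared fixtures, built once per test run. The generator defaults define
# the study conditions; fixtures here only scale them down where a smaller
# instance exercises the identical code paths.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
    if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
    get(name, .fixture_cache)
}

# small pangenome: 8 references, 500 bp, k = 15 -- used by most query tests
fx_small <- function() fixture("small", function() {
    refs <- generatePangenome(n = 8, length = 500, mutationRate = 0.02,
                              indelRate = 1e-3, seed = 11)
    graph <- buildCcdbg(refs, k = 15)
    index <- buildIndex(graph, w = 7)
    list(refs = refs, graph = graph, index = index, k = 15L,
         kcolors = o_kmer_colors(refs, 15))
})

fx_small_reads <- function() fixture("small_reads", function() {
    fx <- fx_small()
    simulateReads(fx$refs, k = fx$k, readLength = 80, nReads = 1000,
                  positiveFraction = 0.5, errorRate = 0.01, seed = 11)
})

# larger pangenome at generator defaults scaled to the test budget; spans
# all three color-encoding regimes
fx_wide <- function() fixture("wide", function() {
    refs <- generatePangenome(n = 50, length = 2000, mutationRate = 0.005,
                              indelRate = 5e-4, seed = 42)
    graph <- buildCcdbg(refs, k = 21)
    index <- buildIndex(graph, w = 11)
    list(refs = refs, graph = graph, index = index, k = 21L)
})
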