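# Modified-cosine scoring, consensus clustering, network topology,
# library matching and export.

test_that("cosine score satisfies self-similarity and disjoint limits", {
    s <- spec("a", 300, c(100, 150, 200), c(1, 2, 3))
    cs <- cosineScore(s, s)
    expect_equal(cs$score, 1)
    expect_equal(cs$matched, 3L)
    t <- spec("b", 300, c(101, 152, 203))
    p <- scoringParams(fragmentTol = 0.4)
    expect_equal(cosineScore(s, t, p)$score, 0)
    expect_error(cosineScore(s, Spectrum("e", 100, cbind(numeric(0),
                                                         numeric(0)))),
                 "empty")
})

test_that("two-peak toy spectra give the hand-computed score", {
    a <- spec("a", 300, c(100, 200), c(1, 1))
    b <- spec("b", 300, c(100, 200), c(1, 1))
    # each normalized weight 1/sqrt(2); two matches -> 2 * 1/2 = 1
    expect_equal(cosineScore(a, b)$score, 1)
    half <- spec("c", 300, c(100, 300), c(1, 1))
    expect_equal(cosineScore(a, half)$score, 0.5)
})

test_that("shifted matching links modification-offset spectra", {
    a <- spec("a", 400, c(100, 180), c(1, 1))
    b <- spec("b", 414, c(100, 194), c(1, 1))   # one fragment shifted by +14
    expect_equal(cosineScore(a, b, shifted = TRUE)$score, 1)
    expect_lt(cosineScore(a, b, shifted = FALSE)$score, 1)
})

test_that("cosine is symmetric, bounded, and bounded by the optimal matching", {
    set.seed(5)
    equalCount <- 0L
    for (i in 1:120) {
        a <- randomSpectrum("a", sample(2:6, 1), precursor = runif(1, 400, 500))
        b <- randomSpectrum("b", sample(2:6, 1), precursor = runif(1, 400, 500))
        p <- scoringParams(fragmentTol = sample(c(0.5, 2, 5), 1))
        ab <- cosineScore(a, b, p)
        ba <- cosineScore(b, a, p)
        expect_equal(ab$score, ba$score, tolerance = 1e-12)
        expect_gte(ab$score, 0); expect_lte(ab$score, 1)
        opt <- oracleCosine(a, b, p)
        expect_lte(ab$score, opt + 1e-12)
        if (abs(ab$score - opt) < 1e-12) equalCount <- equalCount + 1L
    }
    # greedy equals the optimum in the overwhelming majority of cases
    expect_gte(equalCount, 110L)
})

test_that("greedy equals the optimal matching when matches are unambiguous", {
    set.seed(9)
    for (i in 1:40) {
        # well-separated peaks, tolerance small: every peak has at most one
        # candidate partner, so matching is unambiguous
        mzA <- sort(sample(seq(100, 400, by = 10), sample(2:6, 1)))
        a <- spec("a", 450, mzA, runif(length(mzA), 0.1, 1))
        mzB <- sort(sample(seq(100, 400, by = 10), sample(2:6, 1)))
        b <- spec("b", 450, mzB, runif(length(mzB), 0.1, 1))
        p <- scoringParams(fragmentTol = 0.5)
        expect_equal(cosineScore(a, b, p)$score, oracleCosine(a, b, p),
                     tolerance = 1e-12)
    }
})

test_that("consensus clustering enforces the minimum cluster size", {
    mk <- function(n) lapply(seq_len(n), function(i)
        spec(paste0("s", i), 300.0, c(100, 150, 200), c(1, 2, 3),
             strain = "MM109"))
    expect_length(clusterSpectra(mk(4)), 1L)
    expect_message(out <- clusterSpectra(mk(3)), "minimum size")
    expect_length(out, 0L)
})

test_that("planted compounds are recovered as exactly k consensus nodes", {
    cfg <- simulationConfig(nStrains = 3, compoundsPerGroup = c(2, 2, 2),
                            specificity = 0, presenceProb = 1, seed = 31)
    lib <- makeLibrary(cfg)
    prod <- makeProduction(lib$library, cfg)
    sp <- simulateSpectra(lib$library, prod$production, cfg)
    nodes <- clusterSpectra(sp)
    expect_length(nodes, nrow(lib$library))
    # every node's members come from a single planted compound
    for (n in nodes) {
        cmpds <- unique(sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", memberIds(n)))
        expect_length(cmpds, 1L)
        expect_setequal(strainsObserved(n), cfg$strains)
    }
})

test_that("network construction thresholds and filters monotonically", {
    n1 <- spec("n1", 300, c(100, 150), c(1, 1))
    expect_equal(nrow(networkEdges(buildNetwork(list(n1)))), 0L)
    n2 <- spec("n2", 300, c(100, 150), c(1, 1))
    net <- buildNetwork(list(n1, n2))
    expect_equal(nrow(networkEdges(net)), 1L)
    expect_equal(networkEdges(net)$cosine, 1)
    # raising minCosine never increases the edge count
    set.seed(14)
    nodes <- lapply(1:8, function(i)
        randomSpectrum(paste0("n", i), 5, precursor = 300 + i * 0.001))
    counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
        nrow(networkEdges(buildNetwork(nodes, scoringParams(minCosine = th,
                                                            fragmentTol = 5)))),
        integer(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("planted families form disjoint constellations", {
    cfg <- simulationConfig(nStrains = 2, compoundsPerGroup = c(3, 3, 0),
                            specificity = 0, presenceProb = 1, seed = 17)
    lib <- makeLibrary(cfg)
    prod <- makeProduction(lib$library, cfg)
    sp <- simulateSpectra(lib$library, prod$production, cfg)
    net <- buildNetwork(clusterSpectra(sp))
    ed <- networkEdges(net)
    nodeGroup <- function(id) {
        n <- Filter(function(x) spectrumId(x) == id, networkNodes(net))[[1]]
        cmpd <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", memberIds(n)[1])
        lib$library$group[lib$library$name == cmpd]
    }
    if (nrow(ed))
        expect_true(all(mapply(function(f, t)
            nodeGroup(f) == nodeGroup(t), ed$from, ed$to)))
})

test_that("constellations agree with a union-find oracle", {
    e0 <- buildNetwork(lapply(1:5, function(i)
        spec(paste0("n", i), 100 + i, 100 + i * 7)),
        scoringParams(minCosine = 0.99))
    expect_length(constellations(e0), 5L)
    set.seed(23)
    for (rep in 1:100) {
        n <- sample(3:12, 1)
        ids <- paste0("n", seq_len(n))
        m <- sample(0:min(12, n * (n - 1) / 2), 1)
        pairs <- t(replicate(max(m, 1), sample(n, 2)))
        edges <- unique(data.frame(
            from = ids[pmin(pairs[, 1], pairs[, 2])],
            to = ids[pmax(pairs[, 1], pairs[, 2])],
            stringsAsFactors = FALSE))
        edges <- edges[seq_len(min(m, nrow(edges))), , drop = FALSE]
        edges$cosine <- rep(0.9, nrow(edges))
        edges$matchedPeaks <- rep(2L, nrow(edges))
        nodes <- lapply(ids, function(i) spec(i, 100, 100))
        g <- new("MolecularNetwork", nodes = nodes, edges = edges,
                 params = list(minCosine = 0.7), nodeGroups = character(0))
        expect_length(constellations(g), oracleComponents(ids, edges))
    }
})

test_that("library matching enforces score and matched-peak thresholds", {
    q <- spec("query", 300, c(100, 150, 200), c(1, 1, 1))
    libSpec <- spec("bagremycin A", 300, c(100, 150, 200), c(1, 1, 1))
    hit <- libraryMatch(q, list(libSpec))
    expect_equal(hit$annotation, "bagremycin A")
    expect_equal(hit$score, 1)
    # a single shared peak can never be a hit, whatever its score
    oneShared <- spec("one", 300, 100, 5)
    expect_equal(nrow(libraryMatch(oneShared, list(spec("x", 300, 100, 5),
                                                   libSpec))), 0L)
    expect_error(libraryMatch(q, list()), "non-empty")
    # agreement with brute-force scoring of every entry
    set.seed(2)
    lib <- lapply(1:10, function(i) randomSpectrum(paste0("L", i), 5))
    p <- scoringParams(libraryMinScore = 0.2, libraryMinMatched = 2,
                       fragmentTol = 3)
    hits <- libraryMatch(q, lib, p)
    manual <- vapply(lib, function(ref) {
        cs <- cosineScore(q, ref, p)
        cs$score >= 0.2 && cs$matched >= 2
    }, logical(1))
    expect_setequal(hits$annotation,
                    vapply(lib, spectrumId, character(1))[manual])
})

test_that("network export round-trips edges and loads as GraphML", {
    cfg <- simulationConfig(nStrains = 2, compoundsPerGroup = c(2, 0, 1),
                            specificity = 0, presenceProb = 1, seed = 41)
    lib <- makeLibrary(cfg)
    prod <- makeProduction(lib$library, cfg)
    sp <- simulateSpectra(lib$library, prod$production, cfg)
    net <- assignNodeGroups(buildNetwork(clusterSpectra(sp)), sp)
    prefix <- file.path(withr::local_tempdir(), "net")
    paths <- exportNetwork(net, prefix)
    back <- read.delim(paste0(prefix, "_edges.tsv"))
    expect_equal(nrow(back), nrow(networkEdges(net)))
    if (nrow(back))
        expect_setequal(paste(back$from, back$to),
                        paste(networkEdges(net)$from, networkEdges(net)$to))
    g <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
    expect_equal(igraph::vcount(g), length(networkNodes(net)))
    expect_equal(igraph::ecount(g), nrow(networkEdges(net)))
    # empty graph still exports valid files
    empty <- buildNetwork(list(spec("solo", 200, 100)))
    p2 <- file.path(withr::local_tempdir(), "empty")
    exportNetwork(empty, p2)
    expect_equal(igraph::vcount(igraph::read_graph(paste0(p2, ".graphml"),
                                                   format = "graphml")), 1)
})
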