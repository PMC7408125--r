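# Synthetic-data generators: determinism, construction contracts,
# distributional checks, truth-table coverage.

test_that("compound table fixture is transcribed and resolved", {
    tbl <- loadCompoundTable()
    expect_equal(nrow(tbl), 33L)
    expect_equal(tbl$group[tbl$name == "Bagremycin G"], "1")
    expect_equal(tbl$strains[tbl$name == "Bagrelactone E"][[1]], "MM37")
    expect_equal(tbl$best[tbl$name == "Bagremycin C"][[1]], "MM37")
    expect_equal(sum(tbl$new), 10L)
    # every resolved row reproduces its printed m/z within the printed ppm
    # plus double-rounding slack (m/z printed at 4 dp, ppm at 1 dp)
    ok <- tbl$reading != "inconsistent"
    expect_gte(sum(ok), 25L)
    dev <- abs(ppmError(tbl$mz_exp[ok], tbl$theoreticalMz[ok]))
    expect_true(all(dev <= tbl$dm_ppm[ok] + 0.5))
})

test_that("generators are pure functions of configuration and seed", {
    cfg <- simulationConfig(nStrains = 3, compoundsPerGroup = c(2, 1, 1),
                            seed = 99)
    a <- makeLibrary(cfg); b <- makeLibrary(cfg)
    expect_identical(a, b)
    pa <- makeProduction(a$library, cfg); pb <- makeProduction(b$library, cfg)
    expect_identical(abundances(pa$production), abundances(pb$production))
    sa <- simulateSpectra(a$library, pa$production, cfg)
    sb <- simulateSpectra(b$library, pb$production, cfg)
    expect_identical(lapply(sa, peaks), lapply(sb, peaks))
})

test_that("library construction honors group structure", {
    cfg <- simulationConfig(nStrains = 2, compoundsPerGroup = c(0, 5, 0),
                            seed = 4)
    lib <- makeLibrary(cfg)$library
    expect_true(all(lib$group == 2))
    tag2 <- defaultTagSet()$exactMz[2]
    expect_true(all(abs(lib$tagMz - tag2) < 1e-9))
    # precursors resolvable at the parent tolerance
    expect_gt(min(dist(lib$ionMz)), 0.05)
})

test_that("production respects specificity limits and expectation", {
    lib <- makeLibrary(simulationConfig(nStrains = 4,
                                        compoundsPerGroup = c(2, 2, 2),
                                        seed = 1))$library
    cfg1 <- simulationConfig(nStrains = 4, compoundsPerGroup = c(2, 2, 2),
                            specificity = 1, seed = 1)
    p1 <- makeProduction(lib, cfg1)
    expect_true(all(colSums(abundances(p1$production) > 0) == 1L))
    cfg0 <- simulationConfig(nStrains = 4, compoundsPerGroup = c(2, 2, 2),
                            specificity = 0, presenceProb = 1, seed = 1)
    p0 <- makeProduction(lib, cfg0)
    expect_true(all(abundances(p0$production) > 0))
    # Monte-Carlo: exclusive fraction ~ Binomial(n, p) expectation
    p <- 0.3; n <- 200
    cfgMC <- simulationConfig(nStrains = 6, compoundsPerGroup = c(70, 70, 60),
                              specificity = p, presenceProb = 0.6, seed = 12)
    libMC <- makeLibrary(cfgMC)$library
    excl <- makeProduction(libMC, cfgMC)$truth$exclusive
    # non-exclusive compounds can also end up single-strain by chance;
    # the planted-exclusive indicator itself is Bernoulli(p)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(excl) - p), 3 * se)
})

test_that("simulated spectra carry tags, jitter and replicates as configured", {
    cfg <- simulationConfig(nStrains = 2, compoundsPerGroup = c(1, 2, 1),
                            mzJitterSd = 0, noisePeaks = 0, seed = 8)
    lib <- makeLibrary(cfg)
    prod <- makeProduction(lib$library, cfg)
    sp <- simulateSpectra(lib$library, prod$production, cfg)
    tag2 <- defaultTagSet()$exactMz[2]
    for (s in sp) {
        cmpd <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", spectrumId(s))
        row <- lib$library[lib$library$name == cmpd, ]
        expect_equal(precursorMz(s), row$ionMz)   # jitter 0 -> exact
        if (row$group == 2)
            expect_true(any(abs(peaks(s)[, "mz"] - tag2) < 0.01))
    }
    produced <- sum(abundances(prod$production) > 0)
    expect_equal(length(sp), produced * cfg$replicates)
    expect_gte(cfg$replicates, 4L)
})

test_that("neutral-loss compounds plant the precursor-minus-tag fragment", {
    cfg <- simulationConfig(nStrains = 1, compoundsPerGroup = c(3, 0, 0),
                            nlRate = 1, mzJitterSd = 0, noisePeaks = 0,
                            specificity = 0, presenceProb = 1, seed = 2)
    lib <- makeLibrary(cfg)
    prod <- makeProduction(lib$library, cfg)
    sp <- simulateSpectra(lib$library, prod$production, cfg)
    proton <- particleMasses()[["proton"]]
    for (s in sp) {
        loss <- precursorMz(s) - peaks(s)[, "mz"]
        nl <- defaultTagSet()$tagMz[1] - proton
        expect_true(any(abs(loss - nl) < 0.011))
        # and the charged tag itself is absent
        expect_false(any(abs(peaks(s)[, "mz"] -
                             defaultTagSet()$exactMz[1]) < 0.01))
    }
})

test_that("EIC simulation is linear with flat traces for non-producers", {
    cfg <- simulationConfig(nStrains = 2, compoundsPerGroup = c(1, 1, 0),
                            specificity = 1, seed = 21)
    lib <- makeLibrary(cfg)
    prod <- makeProduction(lib$library, cfg)
    eic <- simulateEIC(lib$library, prod$production, cfg)
    ab <- abundances(prod$production)
    for (s in rownames(ab)) for (j in seq_len(ncol(ab))) {
        tr <- eic$traces[[s]][[colnames(ab)[j]]]
        if (ab[s, j] == 0) expect_true(all(tr@intensity == 0))
        else expect_gt(max(tr@intensity), 0)
    }
    # doubling abundance doubles the integrated area (noise off)
    v <- ab * 2
    prod2 <- StrainCompoundMatrix(v, referenceStrain = rownames(ab)[1])
    eic2 <- simulateEIC(lib$library, prod2, cfg)
    s <- rownames(ab)[which(rowSums(ab) > 0)[1]]
    j <- which(ab[s, ] > 0)[1]
    a1 <- integratePeak(eic$traces[[s]][[j]])
    a2 <- integratePeak(eic2$traces[[s]][[j]])
    expect_equal(a2 / a1, 2, tolerance = 1e-6)
})

test_that("BGC matrix generator plants recoverable core/accessory/unique", {
    allCore <- makeBGCMatrix(5, nCore = 10, nAccessory = 0, nUnique = 0,
                             seed = 1)
    st <- panBGCStats(allCore$matrix, "S1")
    expect_equal(st$nonCoreFraction, 0)
    allUnique <- makeBGCMatrix(5, nCore = 0, nAccessory = 0, nUnique = 7,
                               seed = 1)
    expect_equal(panBGCStats(allUnique$matrix, "S1")$nonCoreFraction, 100)
    for (seed in 1:100) {
        nCore <- sample(0:6, 1); nAcc <- sample(0:6, 1)
        nUniq <- sample(0:4, 1)
        if (nCore + nAcc + nUniq == 0) nCore <- 1
        sim <- makeBGCMatrix(6, nCore, nAcc, nUniq, seed = seed)
        st <- panBGCStats(sim$matrix, "S1")
        expect_equal(st$unionSize, nCore + nAcc + nUniq)
        expect_equal(st$coreCount, nCore)
        expect_equal(nrow(st$uniqueToOneStrain), nUniq)
        expect_equal(sort(st$uniqueToOneStrain$family),
                     sort(sim$truth$unique$family))
    }
})

test_that("CDS planting honors its contracts", {
    genes <- makeReferenceGenes(3, seed = 6)
    none <- makeCDSSet(genes, c("A", "B"), nSubstitutions = 0, seed = 6)
    expect_identical(as.character(none$sequences$A), as.character(genes))
    sil <- makeCDSSet(genes, "A", nSubstitutions = 5, pSilent = 1, seed = 6)
    gc11 <- Biostrings::getGeneticCode("11")
    for (g in names(genes)) {
        refAA <- Biostrings::translate(genes[[g]], genetic.code = gc11)
        mutAA <- Biostrings::translate(sil$sequences$A[[g]],
                                       genetic.code = gc11)
        expect_equal(as.character(refAA), as.character(mutAA))
    }
    expect_true(all(sil$truth$kind == "silent"))
})
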