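# Presence calls, exclusivity statistics, glog/Pareto and profile clustering.

test_that("presence matrix thresholds against the per-compound maximum", {
    v <- matrix(c(0, 1, 5, 5, 5, 5, 0, 0, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
    p0 <- presenceMatrix(v, 0)
    expect_equal(unname(p0[, "x"]), c(0, 1, 1))
    expect_equal(unname(p0[, "z"]), c(0, 0, 0))   # exact zeros never present
    pHalf <- presenceMatrix(v, 0.5)
    expect_equal(unname(pHalf[, "y"]), c(1, 1, 1))  # all-equal column
    expect_equal(unname(pHalf[, "x"]), c(0, 0, 1))
})

test_that("producing sets and exclusivity partition the compounds", {
    id <- diag(4); dimnames(id) <- list(paste0("s", 1:4), paste0("c", 1:4))
    expect_equal(producingStrains(id)$exclusiveCount, 4L)
    ones <- matrix(1, 3, 5, dimnames = list(paste0("s", 1:3),
                                            paste0("c", 1:5)))
    expect_equal(producingStrains(ones)$exclusiveCount, 0L)
    set.seed(6)
    for (i in 1:20) {
        m <- matrix(rbinom(24, 1, 0.4), 4, 6,
                    dimnames = list(paste0("s", 1:4), paste0("c", 1:6)))
        ps <- producingStrains(m)
        nMulti <- sum(colSums(m) >= 2)
        nZero <- sum(colSums(m) == 0)
        expect_equal(ps$exclusiveCount + nMulti + nZero, 6L)
    }
})

test_that("producing sets of the compound table match the transcription", {
    tbl <- loadCompoundTable()
    strains <- sort(unique(unlist(tbl$strains)))
    v <- matrix(0, length(strains), nrow(tbl),
                dimnames = list(strains, paste0("cmpd", tbl$id)))
    for (i in seq_len(nrow(tbl))) v[tbl$strains[[i]], i] <- 1
    ps <- producingStrains(presenceMatrix(v))
    for (i in seq_len(nrow(tbl)))
        expect_setequal(ps$producers[[i]], tbl$strains[[i]])
})

test_that("new-in-reference statistic counts reference detections", {
    tbl <- loadCompoundTable()
    res <- newInReference(tbl, "MM109")
    expect_equal(res$count, 3L)
    expect_equal(res$nNew, 10L)
    expect_equal(res$percent, 30)
    # limits
    all109 <- tbl
    all109$strains <- lapply(all109$strains, function(s) union(s, "MM109"))
    expect_equal(newInReference(all109, "MM109")$percent, 100)
    none <- tbl
    none$strains <- lapply(none$strains, function(s) setdiff(s, "MM109"))
    expect_equal(newInReference(none, "MM109")$count, 0L)
    expect_error(newInReference(tbl[tbl$known, ], "MM109"), "no records")
})

test_that("glog/Pareto matches a direct formula evaluation", {
    m <- matrix(c(1, 2, 4, 0, 3, 9, 5, 5, 5), 3, 3,
                dimnames = list(paste0("s", 1:3), paste0("c", 1:3)))
    lambda <- 2
    g <- log((m + sqrt(m^2 + lambda^2)) / 2)
    manual <- apply(g, 2, function(col) {
        s <- sd(col)
        if (s == 0) col - mean(col) else (col - mean(col)) / sqrt(s)
    })
    expect_warning(got <- glogPareto(m, lambda), "zero-variance")
    expect_equal(got, manual)
    # constant matrix transforms to all zeros
    const <- matrix(4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
    # one warning per zero-variance column
    expect_warning(expect_warning(z <- glogPareto(const, 1),
                                  "zero-variance"), "zero-variance")
    expect_true(all(z == 0))
    # monotone in x for fixed lambda
    xs <- seq(0, 100, by = 0.5)
    expect_true(!is.unsorted(log((xs + sqrt(xs^2 + 4)) / 2)))
})

test_that("profile clustering is complete-linkage Euclidean and deterministic", {
    m <- rbind(a = c(1, 0, 0, 5), b = c(1, 0, 0, 5), c = c(9, 9, 9, 0))
    colnames(m) <- paste0("c", 1:4)
    pc <- clusterProfiles(m, k = 2)
    # identical strains merge first at height 0
    expect_equal(pc$rowTree$height[1], 0)
    expect_equal(unname(pc$rowClusters["a"]), unname(pc$rowClusters["b"]))
    expect_true(pc$rowClusters["a"] != pc$rowClusters["c"])
    # heights non-decreasing along the merge order (complete linkage)
    expect_true(!is.unsorted(pc$rowTree$height))
    expect_error(clusterProfiles(m[1, , drop = FALSE]), "at least 2")
})

test_that("planted strain cohorts are recovered at the 2-cluster cut", {
    set.seed(19)
    cohortA <- matrix(rlnorm(4 * 6, 10, 0.2), 4, 6)
    cohortB <- matrix(0, 4, 6)
    m <- cbind(rbind(cohortA, cohortB), rbind(cohortB, cohortA))
    dimnames(m) <- list(paste0("s", 1:8), paste0("c", 1:12))
    pc <- clusterProfiles(glogPareto(m), k = 2)
    expect_length(unique(pc$rowClusters[1:4]), 1L)
    expect_length(unique(pc$rowClusters[5:8]), 1L)
    expect_true(pc$rowClusters[1] != pc$rowClusters[5])
})

test_that("clustering is invariant under row/column permutation", {
    set.seed(8)
    m <- matrix(rlnorm(30, 8, 1), 5, 6,
                dimnames = list(paste0("s", 1:5), paste0("c", 1:6)))
    tm <- glogPareto(m)
    pc1 <- clusterProfiles(tm, k = 3)
    perm <- tm[sample(5), sample(6)]
    pc2 <- clusterProfiles(perm, k = 3)
    # same partition up to relabeling
    lab1 <- pc1$rowClusters[sort(names(pc1$rowClusters))]
    lab2 <- pc2$rowClusters[sort(names(pc2$rowClusters))]
    expect_equal(length(unique(paste(lab1, lab2))), length(unique(lab1)))
    expect_equal(sort(pc1$rowTree$height), sort(pc2$rowTree$height))
})

test_that("identical genotypes can still separate by production profile", {
    # two strains with the same BGC repertoire but disjoint production
    bgc <- matrix(1, 2, 6, dimnames = list(c("MM22", "MM78"), paste0("b", 1:6)))
    expect_equal(panBGCStats(BGCMatrix(bgc), "MM22")$nonCoreCount, 0L)
    prodv <- rbind(MM22 = c(100, 80, 0, 0, 10, 0),
                   MM78 = c(0, 0, 90, 70, 0, 20),
                   MM109 = c(50, 50, 50, 50, 50, 50))
    colnames(prodv) <- paste0("c", 1:6)
    pc <- clusterProfiles(glogPareto(prodv), k = 2)
    expect_true(pc$rowClusters["MM22"] != pc$rowClusters["MM78"])
})

test_that("clustering exports Newick trees", {
    m <- matrix(rlnorm(20), 4, 5,
                dimnames = list(paste0("s", 1:4), paste0("c", 1:5)))
    pc <- clusterProfiles(m, k = 2)
    prefix <- file.path(withr::local_tempdir(), "prof")
    paths <- exportClustering(pc, prefix)
    tr <- ape::read.tree(paste0(prefix, "_rows.nwk"))
    expect_setequal(tr$tip.label, rownames(m))
})
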