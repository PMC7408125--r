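# Pan-BGC statistics, grape networks, CDS alignment and mutation profiling.

test_that("pan-BGC stats reproduce the 37-plus-5 worked example", {
    strains <- paste0("S", 1:18)
    fams <- paste0("BGC", 1:42)
    m <- matrix(0, 18, 42, dimnames = list(strains, fams))
    m["S1", 1:37] <- 1                     # type strain carries 37 families
    m[2:18, 1:18] <- 1                     # 18 conserved everywhere
    set.seed(1)
    for (j in 19:37) m[sample(2:18, 3), j] <- 1
    for (j in 38:42) m[sample(2:18, 2), j] <- 1   # 5 absent from type strain
    st <- panBGCStats(BGCMatrix(m), "S1")
    expect_equal(st$unionSize, 42L)
    expect_equal(st$typeStrainCount, 37L)
    expect_equal(st$absentFromTypeStrain, 5L)
    expect_equal(st$coreCount, 18L)
})

test_that("pan-BGC limits and identities hold", {
    ones <- matrix(1, 4, 6, dimnames = list(paste0("s", 1:4),
                                            paste0("b", 1:6)))
    expect_equal(panBGCStats(ones, "s1")$nonCoreFraction, 0)
    id <- diag(5); dimnames(id) <- list(paste0("s", 1:5), paste0("b", 1:5))
    st <- panBGCStats(id, "s1")
    expect_equal(nrow(st$uniqueToOneStrain), 5L)
    expect_error(panBGCStats(ones, "nope"), "not in matrix")
    set.seed(33)
    for (i in 1:100) {
        n <- sample(3:8, 1); f <- sample(2:10, 1)
        m <- matrix(rbinom(n * f, 1, 0.5), n, f,
                    dimnames = list(paste0("s", 1:n), paste0("b", 1:f)))
        m <- m[, colSums(m) > 0, drop = FALSE]
        if (ncol(m) == 0) next
        st <- panBGCStats(m, "s1")
        expect_equal(st$unionSize, st$coreCount + st$nonCoreCount)
        expect_equal(st$unionSize,
                     st$typeStrainCount + st$absentFromTypeStrain)
    }
})

test_that("grape network is one complete subgraph per family", {
    m <- rbind(s1 = c(1, 1, 0), s2 = c(1, 0, 1), s3 = c(1, 0, 0))
    colnames(m) <- c("famA", "famB", "famC")
    g <- bgcNetwork(m)
    expect_equal(igraph::vcount(g), sum(m))
    comp <- igraph::components(g)
    expect_equal(comp$no, 3L)   # two singleton grapes plus the triangle
    famA <- igraph::induced_subgraph(
        g, igraph::V(g)[startsWith(igraph::V(g)$name, "famA")])
    expect_equal(igraph::ecount(famA), 3L)   # complete on 3 nodes
    expect_error(bgcNetwork(m, orthology = c(famA = 1.5)), "\\[0, 1\\]")
})

test_that("global CDS alignment matches the affine-gap DP oracle", {
    aln <- alignCDS("ATGGCTGCTTAA", "ATGGCTGCTTAA")
    expect_equal(aln$refAligned, aln$queryAligned)
    sub <- alignCDS("ATGGCTGCTTAA", "ATGGATGCTTAA")
    diffs <- sum(strsplit(sub$refAligned, "")[[1]] !=
                 strsplit(sub$queryAligned, "")[[1]])
    expect_equal(diffs, 1L)
    expect_error(alignCDS("", "ATG"), "empty")
    expect_error(alignCDS("ATGN--", "ATG"), "A,C,G,T|divisible")
    set.seed(27)
    bases <- c("A", "C", "G", "T")
    for (i in 1:25) {
        n1 <- 3 * sample(2:6, 1)
        ref <- paste0(sample(bases, n1, TRUE), collapse = "")
        qry <- paste0(sample(bases, sample(4:20, 1), TRUE), collapse = "")
        got <- alignCDS(ref, qry)
        expect_equal(got$score, oracleAlignScore(ref, qry))
    }
})

test_that("codon-level classification follows the genetic code", {
    silent <- classifyMutations(alignCDS("ATGGCTTAA", "ATGGCCTAA"),
                                gene = "g", strain = "s")
    expect_equal(silent$kind, "silent")          # GCT -> GCC, Ala -> Ala
    expect_equal(silent$codon, 2L)
    nonsil <- classifyMutations(alignCDS("ATGGCTTAA", "ATGGATTAA"),
                                gene = "g", strain = "s")
    expect_equal(nonsil$kind, "non-silent")      # GCT -> GAT, Ala -> Asp
    expect_equal(nonsil$refAA, "A"); expect_equal(nonsil$altAA, "D")
    # identity alignments yield no events for arbitrary CDS
    set.seed(41)
    for (i in 1:10) {
        g <- as.character(makeReferenceGenes(1, 20, 40, seed = i)[[1]])
        expect_equal(nrow(classifyMutations(alignCDS(g, g))), 0L)
    }
})

test_that("in-frame deletions are reported once, frameshifts flagged", {
    ref <- "ATGGCTGATCGATAA"
    del <- "ATGGCTCGATAA"        # codon 3 (GAT) removed
    ev <- classifyMutations(alignCDS(ref, del), gene = "g", strain = "s")
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$kind, "in-frame deletion")
    expect_equal(ev$codon, 3L)
    expect_equal(ev$refCodon, "GAT")
    fs <- suppressWarnings(
        classifyMutations(alignCDS("ATGGCTGATTAA", "ATGGCGATTAA")))
    expect_true("frameshift" %in% fs$kind)
    expect_false(any(fs$kind %in% c("silent", "non-silent") &
                     is.na(fs$refAA)))
})

test_that("classification is silent for synonymous recodings", {
    set.seed(55)
    gc11 <- Biostrings::getGeneticCode("11")
    for (i in 1:10) {
        ref <- as.character(makeReferenceGenes(1, 30, 60, seed = i)[[1]])
        codons <- substring(ref, seq(1, nchar(ref) - 2, 3),
                            seq(3, nchar(ref), 3))
        recoded <- vapply(codons, function(cd) {
            syn <- names(gc11)[gc11 == gc11[[cd]]]
            sample(syn, 1)
        }, character(1))
        # keep start/stop fixed so the ORF stays sane
        recoded[1] <- codons[1]
        recoded[length(recoded)] <- codons[length(codons)]
        qry <- paste0(recoded, collapse = "")
        ev <- classifyMutations(alignCDS(ref, qry))
        expect_true(all(ev$kind == "silent"))
        aaRef <- as.character(Biostrings::translate(
            Biostrings::DNAString(ref), genetic.code = gc11))
        aaQry <- as.character(Biostrings::translate(
            Biostrings::DNAString(qry), genetic.code = gc11))
        expect_equal(aaRef, aaQry)
    }
})

test_that("mutation matrix distinguishes shared from distinct events", {
    empty <- mutationMatrix(classifyMutations(alignCDS("ATGTAA", "ATGTAA")),
                            strains = c("a", "b"), genes = "g")
    expect_true(all(empty$counts == 0))
    expect_equal(empty$distinctTotal, 0L)
    shared <- data.frame(
        strain = c("s1", "s2", "s3"), gene = "fevT", codon = 10L,
        kind = "non-silent", refCodon = "GCT", altCodon = "GAT",
        refAA = "A", altAA = "D", stringsAsFactors = FALSE)
    mm <- mutationMatrix(shared)
    expect_equal(mm$distinctTotal, 1L)
    expect_equal(unname(mm$perStrainTotals), c(1L, 1L, 1L))
})

test_that("a planted conserved-cluster profile shape is reported exactly", {
    # 67 distinct events: one gene carrying 11, one strain carrying 53
    genes <- sprintf("gene%02d", 1:16)
    perGene <- c(11L, rep(4L, 14), 0L)
    events <- list()
    k <- 0L
    for (gi in seq_along(genes)) for (e in seq_len(perGene[gi])) {
        k <- k + 1L
        events[[k]] <- data.frame(
            strain = "MM51", gene = genes[gi], codon = 10L + e,
            kind = "non-silent", refCodon = "GCT", altCodon = "GAT",
            refAA = "A", altAA = "D", stringsAsFactors = FALSE)
    }
    # 53 of the 67 carried by MM51; move the remaining 14 to another strain
    ev <- do.call(rbind, events)
    ev$strain[54:67] <- "MM103"
    mm <- mutationMatrix(ev, strains = c("MM51", "MM103"), genes = genes)
    expect_equal(mm$distinctTotal, 67L)
    expect_equal(max(mm$perStrainTotals), 53L)
    expect_equal(max(mm$perGeneDistinct), 11L)
})
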