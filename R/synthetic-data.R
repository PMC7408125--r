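# Seeded generators for every input the pipeline consumes: compound
# libraries, strain production matrices, MS/MS spectra, EIC traces, BGC
# presence/absence matrices and mutated CDS sets. Each generator is a pure
# function of (inputs, seed) and returns a ground-truth table alongside the
# simulated data so downstream stages can be tested by recovery.

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators. The defaults emulate
#' a seven-strain study of three diagnostic compound groups: a reference
#' strain plus six others, three groups of eight compounds each sharing a
#' group tag fragment, partly strain-exclusive production with log-normal
#' abundance spread, four replicate MS/MS scans per produced compound, and
#' high-resolution m/z jitter.
#'
#' @param nStrains number of strains (first strain is the reference).
#' @param strains strain labels; default `MM109` (reference) plus
#'   `MM25,MM31,MM37,MM40,MM83,MM113`-style labels, extended/truncated to
#'   `nStrains`.
#' @param compoundsPerGroup integer vector of length 3: compounds in tag
#'   groups 1, 2, 3.
#' @param specificity probability that a compound is produced by exactly
#'   one strain (strain-exclusive production).
#' @param presenceProb per-strain production probability for non-exclusive
#'   compounds.
#' @param abundanceMeanlog,abundanceSdlog log-normal abundance parameters
#'   (peak-area units).
#' @param replicates MS/MS scans per produced (strain, compound) pair.
#' @param nFragments family-shared fragments per group backbone (3--10).
#' @param noisePeaks random noise peaks per scan.
#' @param noiseFrac noise-peak intensity ceiling, as a fraction of the base
#'   peak.
#' @param mzJitterSd m/z jitter standard deviation (Da), applied to every
#'   peak and precursor.
#' @param nlRate probability that a compound presents its tag as a neutral
#'   loss (precursor-minus-tag fragment) instead of the charged tag.
#' @param rtMax,rtStep retention-time grid extent and spacing (s).
#' @param peakSigma chromatographic peak width sigma (s).
#' @param eicNoise EIC baseline-noise ceiling (intensity units; 0 = none).
#' @param seed integer seed fixing all randomness.
#' @return a classed list (`SimulationConfig`).
#' @export
simulationConfig <- function(nStrains = 7L,
                             strains = NULL,
                             compoundsPerGroup = c(8L, 8L, 8L),
                             specificity = 0.1,
                             presenceProb = 0.55,
                             abundanceMeanlog = log(1e5),
                             abundanceSdlog = 1,
                             replicates = 4L,
                             nFragments = 6L,
                             noisePeaks = 5L,
                             noiseFrac = 0.05,
                             mzJitterSd = 0.002,
                             nlRate = 0,
                             rtMax = 600,
                             rtStep = 0.5,
                             peakSigma = 4,
                             eicNoise = 0,
                             seed = 1L) {
    if (is.null(strains)) {
        pool <- c("MM109", "MM25", "MM31", "MM37", "MM40", "MM83", "MM113",
                  "MM15", "MM22", "MM28", "MM29", "MM51", "MM78", "MM91",
                  "MM103", "MM115", "MM126", "MMun143")
        strains <- if (nStrains <= length(pool)) pool[seq_len(nStrains)]
            else c(pool, paste0("MMx", seq_len(nStrains - length(pool))))
    }
    stopifnot(length(strains) == nStrains,
              length(compoundsPerGroup) == 3L, all(compoundsPerGroup >= 0L),
              specificity >= 0, specificity <= 1,
              presenceProb >= 0, presenceProb <= 1,
              replicates >= 0L, nFragments >= 0L, noisePeaks >= 0L,
              noiseFrac >= 0, mzJitterSd >= 0, nlRate >= 0, nlRate <= 1,
              length(seed) == 1L, is.finite(seed))
    cfg <- list(nStrains = as.integer(nStrains), strains = strains,
                compoundsPerGroup = as.integer(compoundsPerGroup),
                specificity = specificity, presenceProb = presenceProb,
                abundanceMeanlog = abundanceMeanlog,
                abundanceSdlog = abundanceSdlog,
                replicates = as.integer(replicates),
                nFragments = as.integer(nFragments),
                noisePeaks = as.integer(noisePeaks), noiseFrac = noiseFrac,
                mzJitterSd = mzJitterSd, nlRate = nlRate,
                rtMax = rtMax, rtStep = rtStep, peakSigma = peakSigma,
                eicNoise = eicNoise, seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig:", x$nStrains, "strains,",
        paste(x$compoundsPerGroup, collapse = "/"),
        "compounds per group, seed", x$seed, "\n")
    invisible(x)
}

#' Load the packaged compound table
#'
#' Returns the packaged 33-row table of bagremycin- and bagrelactone-related
#' compounds (name, printed formula with charge, experimental m/z, printed
#' ppm deviation, producing strains with the best producer, tag group, and
#' whether the compound was previously known).
#'
#' Printed formulas in such tables mix two conventions: some rows print the
#' cation formula whose electron-corrected mass is the m/z, others print the
#' neutral formula whose `[M+H]+` is the m/z. At load time each row is
#' resolved to the convention (`"cation"` or `"protonated"`) that reproduces
#' the printed m/z within 1 ppm; rows where neither does are flagged
#' `"inconsistent"` and should be excluded from mass arithmetic.
#'
#' @param path path to the TSV; defaults to the packaged fixture.
#' @return data.frame with one row per compound; `strains` and `best` are
#'   list columns of strain labels, `reading` the resolved ion convention,
#'   `theoreticalMz` the m/z under that convention (NA when inconsistent).
#' @export
loadCompoundTable <- function(path = system.file("extdata",
                                                 "compound_table.tsv",
                                                 package = "strainmet")) {
    df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    df$id <- as.integer(df$id)
    df$mz_exp <- as.numeric(df$mz_exp)
    df$dm_ppm <- as.numeric(df$dm_ppm)
    df$known <- as.logical(df$known)
    df$strains <- strsplit(df$strains, ",", fixed = TRUE)
    df$best <- strsplit(df$best, ",", fixed = TRUE)
    reading <- character(nrow(df))
    theo <- numeric(nrow(df))
    for (i in seq_len(nrow(df))) {
        f <- parseFormula(df$formula[i])
        mzCat <- ionMz(f, "cation", z = 1L)
        mzProt <- ionMz(f, "protonated", z = 1L)
        pCat <- abs(ppmError(df$mz_exp[i], mzCat))
        pProt <- abs(ppmError(df$mz_exp[i], mzProt))
        if (pCat <= 1 && pCat <= pProt) {
            reading[i] <- "cation"; theo[i] <- mzCat
        } else if (pProt <= 1) {
            reading[i] <- "protonated"; theo[i] <- mzProt
        } else {
            reading[i] <- "inconsistent"; theo[i] <- NA_real_
        }
    }
    df$reading <- reading
    df$theoreticalMz <- theo
    df$new <- !df$known & nzchar(df$name)
    df
}

# draw masses pairwise separated by >= minGap Da; the gap shrinks when the
# range gets crowded (large libraries) rather than failing
.drawSeparated <- function(n, lo, hi, existing = numeric(0), minGap = 1.2) {
    out <- numeric(0)
    tries <- 0L
    while (length(out) < n) {
        x <- runif(1L, lo, hi)
        if (all(abs(x - c(out, existing)) >= minGap)) out <- c(out, x)
        tries <- tries + 1L
        if (tries %% 2000L == 0L) {
            minGap <- minGap / 2
            if (minGap < 1e-3) stop("cannot place separated masses")
        }
    }
    out
}

#' Generate a synthetic compound library
#'
#' Random CHNOS formulas within the default decomposition bounds, assigned
#' to the three diagnostic tag groups. Each group carries a fragment
#' "backbone" shared by all its compounds (this is what makes family members
#' network together) plus the group's tag fragment; each compound adds two
#' private fragments. Precursor ions are kept at least 0.1 Da apart so
#' planted compounds are resolvable at the 0.01 Da parent tolerance.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `library` (data.frame: name, formula, group, ionMz,
#'   tagMz, nl, fragments list column, rt) and `truth` (the same, the
#'   generator's ground truth).
#' @export
makeLibrary <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(cfg$seed)
    tags <- defaultTagSet()
    nTot <- sum(cfg$compoundsPerGroup)
    if (nTot == 0L)
        return(list(library = data.frame(), truth = data.frame()))
    # group fragment backbones, all fragments well separated in mass
    taken <- tags$exactMz
    backbones <- list()
    for (g in 1:3) {
        bb <- .drawSeparated(cfg$nFragments, 130, 240, existing = taken)
        taken <- c(taken, bb)
        backbones[[g]] <- sort(bb)
    }
    rows <- list()
    usedMz <- numeric(0)
    for (g in 1:3) {
        for (k in seq_len(cfg$compoundsPerGroup[g])) {
            repeat {
                nC <- sample(12:30, 1L)
                nH <- sample(seq(nC %/% 2, 2L * nC), 1L)
                nN <- sample(0:4, 1L)
                nS <- if (g == 2L) sample(1:2, 1L) else 0L
                nO <- sample(2:10, 1L)
                cts <- as.integer(c(nC, nH, nN, nO, nS))
                names(cts) <- c("C", "H", "N", "O", "S")
                f <- new("Formula", counts = cts[cts > 0L], charge = 0L)
                if (rdbe(f) < 1) next
                mz <- ionMz(f, "protonated")
                if (length(usedMz) && any(abs(mz - usedMz) < 0.1)) next
                break
            }
            usedMz <- c(usedMz, mz)
            priv <- .drawSeparated(2L, 250, max(260, mz - 30), existing = taken)
            taken <- c(taken, priv)
            rows[[length(rows) + 1L]] <- data.frame(
                name = sprintf("SYN-G%d-%02d", g, k),
                formula = formulaString(f), group = g, ionMz = mz,
                tagMz = tags$exactMz[g],
                nl = runif(1L) < cfg$nlRate,
                stringsAsFactors = FALSE)
            rows[[length(rows)]]$fragments <-
                list(sort(c(backbones[[g]], priv)))
        }
    }
    lib <- do.call(rbind, rows)
    lib$rt <- seq(60, cfg$rtMax - 60, length.out = nrow(lib))
    rownames(lib) <- NULL
    list(library = lib, truth = lib)
}

#' Simulate per-strain production of a compound library
#'
#' Each compound is strain-exclusive with probability `cfg$specificity`
#' (produced by exactly one random strain); otherwise each strain produces
#' it independently with probability `cfg$presenceProb` (at least one
#' producer is enforced). Abundances are log-normal where produced and
#' exactly 0 where not; the first configured strain is the reference.
#'
#' @param library the `library` element of [makeLibrary()].
#' @param cfg a [simulationConfig()].
#' @param strains strain labels (default `cfg$strains`).
#' @return list with `production` (a [StrainCompoundMatrix-class]) and
#'   `truth` (list: abundance matrix, logical `exclusive` per compound).
#' @export
makeProduction <- function(library, cfg, strains = cfg$strains) {
    stopifnot(inherits(cfg, "SimulationConfig"), length(strains) >= 1L)
    set.seed(cfg$seed + 1L)
    n <- length(strains)
    m <- matrix(0, n, nrow(library),
                dimnames = list(strains, library$name))
    exclusive <- logical(nrow(library))
    for (j in seq_len(nrow(library))) {
        if (runif(1L) < cfg$specificity) {
            producers <- sample(n, 1L)
            exclusive[j] <- TRUE
        } else {
            producers <- which(runif(n) < cfg$presenceProb)
            if (length(producers) == 0L) producers <- sample(n, 1L)
        }
        m[producers, j] <- rlnorm(length(producers),
                                  cfg$abundanceMeanlog, cfg$abundanceSdlog)
    }
    list(production = StrainCompoundMatrix(m, referenceStrain = strains[1L]),
         truth = list(abundance = m, exclusive = exclusive))
}

#' Simulate MS/MS spectra for produced compounds
#'
#' For every produced (strain, compound) pair, `cfg$replicates` scans are
#' generated: precursor at the compound's ion m/z plus jitter; fragments
#' from the compound's family backbone and private set with
#' replicate-jittered intensities; the group tag fragment (or, for
#' neutral-loss compounds, a precursor-minus-tag-mass fragment); and random
#' noise peaks capped at `cfg$noiseFrac` of the base peak. The base-peak
#' intensity is proportional to the true abundance.
#'
#' @param library the `library` element of [makeLibrary()].
#' @param production a [StrainCompoundMatrix-class] from [makeProduction()].
#' @param cfg a [simulationConfig()].
#' @return list of [Spectrum-class].
#' @export
simulateSpectra <- function(library, production, cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(cfg$seed + 2L)
    ab <- abundances(production)
    proton <- particleMasses()[["proton"]]
    spectra <- list()
    for (j in seq_len(nrow(library))) {
        frags <- library$fragments[[j]]
        fragFrac <- runif(length(frags), 0.3, 1)   # compound-level profile
        for (s in rownames(ab)) {
            a <- ab[s, library$name[j]]
            if (a <= 0) next
            for (r in seq_len(cfg$replicates)) {
                base <- a
                mzs <- frags
                ints <- base * fragFrac * runif(length(frags), 0.85, 1.15)
                if (library$nl[j]) {
                    nlMass <- library$tagMz[j] - proton
                    mzs <- c(mzs, library$ionMz[j] - nlMass)
                } else {
                    mzs <- c(mzs, library$tagMz[j])
                }
                ints <- c(ints, 0.6 * base * runif(1L, 0.85, 1.15))
                if (cfg$noisePeaks > 0L) {
                    mzs <- c(mzs, runif(cfg$noisePeaks, 50,
                                        library$ionMz[j] - 1))
                    ints <- c(ints, runif(cfg$noisePeaks, 0,
                                          cfg$noiseFrac * base))
                }
                mzs <- mzs + rnorm(length(mzs), 0, cfg$mzJitterSd)
                spectra[[length(spectra) + 1L]] <- Spectrum(
                    id = sprintf("%s|%s|r%d", s, library$name[j], r),
                    precursorMz = library$ionMz[j] +
                        rnorm(1L, 0, cfg$mzJitterSd),
                    peaks = cbind(mzs, ints), charge = 1L,
                    rt = library$rt[j], strain = s)
            }
        }
    }
    spectra
}

#' Simulate extracted-ion-chromatogram traces
#'
#' One Gaussian chromatographic peak per produced compound on a shared
#' retention-time grid, with peak area equal to the true abundance, plus an
#' optional additive uniform baseline noise.
#'
#' @param library the `library` element of [makeLibrary()].
#' @param production a [StrainCompoundMatrix-class].
#' @param cfg a [simulationConfig()].
#' @return list with `traces` (named list per strain; each a list of
#'   [EICTrace-class], one channel per compound ion) and `truth` (data.frame
#'   compound, rt, sigma, targetMz).
#' @export
simulateEIC <- function(library, production, cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(cfg$seed + 3L)
    grid <- seq(0, cfg$rtMax, by = cfg$rtStep)
    ab <- abundances(production)
    traces <- list()
    for (s in rownames(ab)) {
        ts <- vector("list", nrow(library))
        for (j in seq_len(nrow(library))) {
            a <- ab[s, library$name[j]]
            y <- if (a > 0)
                a * exp(-(grid - library$rt[j])^2 / (2 * cfg$peakSigma^2)) /
                    (cfg$peakSigma * sqrt(2 * pi))
            else rep(0, length(grid))
            if (cfg$eicNoise > 0)
                y <- y + runif(length(grid), 0, cfg$eicNoise)
            ts[[j]] <- EICTrace(grid, y, targetMz = library$ionMz[j],
                                tolDa = 0.005)
        }
        names(ts) <- library$name
        traces[[s]] <- ts
    }
    list(traces = traces,
         truth = data.frame(compound = library$name, rt = library$rt,
                            sigma = cfg$peakSigma, targetMz = library$ionMz,
                            stringsAsFactors = FALSE))
}

#' Generate a BGC presence/absence matrix with known structure
#'
#' Builds a binary strains x families matrix with `nCore` families present
#' in every strain, `nAccessory` families present in a random subset of 2 to
#' `nStrains - 1` strains, and `nUnique` families present in exactly one
#' strain. Defaults emulate an 18-strain species pan-BGC of 42 families with
#' 18 conserved.
#'
#' @param nStrains number of strains.
#' @param nCore,nAccessory,nUnique family counts per category.
#' @param strains optional strain labels (default `S1..Sn`).
#' @param seed integer seed.
#' @return list with `matrix` (a [BGCMatrix-class]) and `truth` (list of
#'   family names per category plus the unique family-strain pairs).
#' @export
makeBGCMatrix <- function(nStrains = 18L, nCore = 18L, nAccessory = 19L,
                          nUnique = 5L, strains = NULL, seed = 1L) {
    stopifnot(nStrains >= 2L, nCore >= 0L, nAccessory >= 0L, nUnique >= 0L)
    set.seed(seed)
    if (is.null(strains)) strains <- paste0("S", seq_len(nStrains))
    nFam <- nCore + nAccessory + nUnique
    fams <- sprintf("BGC%02d", seq_len(nFam))
    m <- matrix(0, nStrains, nFam, dimnames = list(strains, fams))
    idx <- 0L
    for (i in seq_len(nCore)) m[, idx <- idx + 1L] <- 1
    accFams <- character(0)
    for (i in seq_len(nAccessory)) {
        idx <- idx + 1L
        k <- sample(2:(nStrains - 1L), 1L)
        m[sample(nStrains, k), idx] <- 1
        accFams <- c(accFams, fams[idx])
    }
    uniq <- data.frame(family = character(0), strain = character(0),
                       stringsAsFactors = FALSE)
    for (i in seq_len(nUnique)) {
        idx <- idx + 1L
        s <- sample(nStrains, 1L)
        m[s, idx] <- 1
        uniq <- rbind(uniq, data.frame(family = fams[idx],
                                       strain = strains[s],
                                       stringsAsFactors = FALSE))
    }
    list(matrix = BGCMatrix(m),
         truth = list(core = fams[seq_len(nCore)], accessory = accFams,
                      unique = uniq))
}

#' Generate random reference coding sequences
#'
#' Random bacterial-style ORFs: ATG start, internal codons drawn from the 61
#' sense codons, TAA stop. Used as the reference gene set for mutation
#' planting. Defaults emulate a 16-gene biosynthetic cluster.
#'
#' @param nGenes number of genes.
#' @param minCodons,maxCodons internal codon count range.
#' @param seed integer seed.
#' @return a [Biostrings::DNAStringSet] named `gene01`, `gene02`, ...
#' @export
makeReferenceGenes <- function(nGenes = 16L, minCodons = 80L,
                               maxCodons = 200L, seed = 1L) {
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    allCodons <- apply(expand.grid(bases, bases, bases), 1L, paste0,
                       collapse = "")
    sense <- setdiff(allCodons, c("TAA", "TAG", "TGA"))
    seqs <- vapply(seq_len(nGenes), function(i) {
        n <- sample(minCodons:maxCodons, 1L)
        paste0("ATG", paste0(sample(sense, n, replace = TRUE),
                             collapse = ""), "TAA")
    }, character(1L))
    names(seqs) <- sprintf("gene%02d", seq_len(nGenes))
    Biostrings::DNAStringSet(seqs)
}

# all single-nucleotide variants of a codon
.codonVariants <- function(codon) {
    bases <- c("A", "C", "G", "T")
    out <- character(0)
    for (p in 1:3) for (b in setdiff(bases, substr(codon, p, p))) {
        v <- codon
        substr(v, p, p) <- b
        out <- c(out, v)
    }
    out
}

.gcCache <- new.env(parent = emptyenv())
.translateCodon <- function(codon) {
    if (is.null(.gcCache$gc11))
        .gcCache$gc11 <- Biostrings::getGeneticCode("11")
    unname(.gcCache$gc11[codon])
}

#' Plant classified mutations into reference coding sequences
#'
#' Draws a set of distinct mutation events (single-codon substitutions,
#' classified silent/non-silent by bacterial codon table 11 at planting
#' time, plus optional single-codon in-frame deletions) and assigns each
#' event to a random non-empty subset of strains, so that events can be
#' shared across strains exactly as shared mutations are in real
#' conserved-cluster comparisons. Planting sites are chosen so the mutated
#' sequence has a unique optimal alignment against the reference (deletion
#' contexts that would allow the gap to slide are re-drawn), which makes the
#' truth table exactly recoverable by [classifyMutations()].
#'
#' @param refGenes reference ORFs, a [Biostrings::DNAStringSet]; lengths
#'   must be divisible by 3.
#' @param strains strain labels.
#' @param nSubstitutions number of distinct substitution events.
#' @param pSilent probability a substitution event is silent.
#' @param nDeletions number of distinct single-codon in-frame deletions.
#' @param shareProb per-strain probability of carrying each event.
#' @param seed integer seed.
#' @return list with `sequences` (named list per strain of
#'   `DNAStringSet`) and `truth` (data.frame: strain, gene, codon, kind,
#'   refCodon, altCodon, refAA, altAA).
#' @export
makeCDSSet <- function(refGenes, strains, nSubstitutions = 10L,
                       pSilent = 0.1, nDeletions = 0L, shareProb = 0.3,
                       seed = 1L) {
    stopifnot(all(Biostrings::width(refGenes) %% 3L == 0L),
              length(strains) >= 1L)
    set.seed(seed)
    refChar <- as.character(refGenes)
    genes <- names(refGenes)
    nCodons <- Biostrings::width(refGenes) %/% 3L
    usedCodons <- lapply(genes, function(g) integer(0))
    names(usedCodons) <- genes
    getCodon <- function(seqStr, i) substr(seqStr, 3L * i - 2L, 3L * i)
    events <- list()
    drawSite <- function(minGapToUsed = 1L) {
        for (try in seq_len(500L)) {
            g <- sample(genes, 1L)
            # avoid start and stop codons
            cd <- sample(2:(nCodons[[match(g, genes)]] - 1L), 1L)
            if (all(abs(cd - usedCodons[[g]]) > minGapToUsed))
                return(list(gene = g, codon = cd))
        }
        stop("could not place mutation event; too many events for sequence size")
    }
    for (e in seq_len(nSubstitutions)) {
        wantSilent <- runif(1L) < pSilent
        placed <- FALSE
        for (try in seq_len(500L)) {
            site <- drawSite()
            ref <- getCodon(refChar[[site$gene]], site$codon)
            vars <- .codonVariants(ref)
            aaRef <- .translateCodon(ref)
            aaVar <- vapply(vars, .translateCodon, character(1L))
            ok <- if (wantSilent) aaVar == aaRef else
                aaVar != aaRef & aaVar != "*"
            if (!any(ok)) next
            alt <- sample(vars[ok], 1L)
            usedCodons[[site$gene]] <- c(usedCodons[[site$gene]], site$codon)
            events[[length(events) + 1L]] <- list(
                gene = site$gene, codon = site$codon,
                kind = if (wantSilent) "silent" else "non-silent",
                refCodon = ref, altCodon = alt,
                refAA = aaRef, altAA = unname(aaVar[match(alt, vars)]))
            placed <- TRUE
            break
        }
        if (!placed)
            stop("requested ", if (wantSilent) "silent" else "non-silent",
                 " substitution impossible after bounded retries")
    }
    for (e in seq_len(nDeletions)) {
        placed <- FALSE
        for (try in seq_len(500L)) {
            site <- drawSite(minGapToUsed = 2L)
            seqStr <- refChar[[site$gene]]
            i <- site$codon
            del <- getCodon(seqStr, i)
            # unique gap placement: no equal-base slide at either edge
            beforeB <- substr(seqStr, 3L * i - 3L, 3L * i - 3L)
            afterB <- substr(seqStr, 3L * i + 1L, 3L * i + 1L)
            if (beforeB == substr(del, 3L, 3L) ||
                afterB == substr(del, 1L, 1L)) next
            prevCodon <- getCodon(seqStr, i - 1L)
            nextCodon <- getCodon(seqStr, i + 1L)
            if (del == prevCodon || del == nextCodon) next
            usedCodons[[site$gene]] <- c(usedCodons[[site$gene]],
                                         i - 1L, i, i + 1L)
            events[[length(events) + 1L]] <- list(
                gene = site$gene, codon = i, kind = "in-frame deletion",
                refCodon = del, altCodon = "---",
                refAA = .translateCodon(del), altAA = "-")
            placed <- TRUE
            break
        }
        if (!placed) stop("could not place in-frame deletion")
    }
    # assign each distinct event to a non-empty strain subset
    carriers <- lapply(events, function(ev) {
        w <- which(runif(length(strains)) < shareProb)
        if (length(w) == 0L) w <- sample(length(strains), 1L)
        strains[w]
    })
    truth <- do.call(rbind, lapply(seq_along(events), function(k) {
        ev <- events[[k]]
        data.frame(strain = carriers[[k]], gene = ev$gene, codon = ev$codon,
                   kind = ev$kind, refCodon = ev$refCodon,
                   altCodon = ev$altCodon, refAA = ev$refAA,
                   altAA = ev$altAA, stringsAsFactors = FALSE)
    }))
    if (is.null(truth))
        truth <- data.frame(strain = character(), gene = character(),
                            codon = integer(), kind = character(),
                            refCodon = character(), altCodon = character(),
                            refAA = character(), altAA = character(),
                            stringsAsFactors = FALSE)
    sequences <- lapply(strains, function(s) {
        seqs <- refChar
        myEvents <- which(vapply(carriers, function(cs) s %in% cs, logical(1L)))
        # apply deletions last within each gene so codon indices stay valid
        ord <- myEvents[order(vapply(events[myEvents], function(e)
            e$kind == "in-frame deletion", logical(1L)))]
        for (k in ord) {
            ev <- events[[k]]
            seqStr <- seqs[[ev$gene]]
            pos <- 3L * ev$codon - 2L
            if (ev$kind == "in-frame deletion") {
                seqs[[ev$gene]] <- paste0(substr(seqStr, 1L, pos - 1L),
                                          substring(seqStr, pos + 3L))
            } else {
                substr(seqStr, pos, pos + 2L) <- ev$altCodon
                seqs[[ev$gene]] <- seqStr
            }
        }
        Biostrings::DNAStringSet(seqs)
    })
    names(sequences) <- strains
    truth <- truth[order(truth$strain, truth$gene, truth$codon), ,
                   drop = FALSE]
    rownames(truth) <- NULL
    list(sequences = sequences, truth = truth)
}
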