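# Independent oracles and small fixture builders used across the suite.

# quick Spectrum builder
spec <- function(id, pre, mz, int = rep(1, length(mz)), strain = NA) {
    Spectrum(id, pre, cbind(mz, int), strain = strain)
}

# brute-force CHNOS enumeration: the quintuple-loop oracle for decomposeMass
bruteDecompose <- function(targetMz, mode, tolPpm, bounds, minRdbe = -0.5) {
    pm <- particleMasses()
    masses <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                O = 15.9949146196, S = 31.97207100)
    hits <- character(0)
    for (nC in 0:bounds[["C"]]) for (nH in 0:bounds[["H"]])
    for (nN in 0:bounds[["N"]]) for (nO in 0:bounds[["O"]])
    for (nS in 0:bounds[["S"]]) {
        if (nC + nH + nN + nO + nS == 0) next
        m <- nC * masses[["C"]] + nH * masses[["H"]] + nN * masses[["N"]] +
            nO * masses[["O"]] + nS * masses[["S"]]
        mz <- if (mode == "protonated") m + pm[["proton"]]
              else m - pm[["electron"]]
        if (abs(1e6 * (targetMz - mz) / mz) > tolPpm) next
        if (nC - nH / 2 + nN / 2 + 1 < minRdbe) next
        cts <- c(C = nC, H = nH, N = nN, O = nO, S = nS)
        cts <- cts[cts > 0]
        hits <- c(hits, paste0(names(cts), ifelse(cts > 1, cts, ""),
                               collapse = ""))
    }
    sort(hits)
}

# exhaustive optimal one-to-one peak assignment for the modified cosine:
# maximizes the sum of weight products over all matchings of candidate pairs
oracleCosine <- function(a, b, p = scoringParams(), shifted = TRUE) {
    pa <- peaks(a); pb <- peaks(b)
    wa <- pa[, 2]^p$intensityPower; wa <- wa / sqrt(sum(wa^2))
    wb <- pb[, 2]^p$intensityPower; wb <- wb / sqrt(sum(wb^2))
    shift <- precursorMz(a) - precursorMz(b)
    dmz <- outer(pa[, 1], pb[, 1], "-")
    cand <- abs(dmz) <= p$fragmentTol
    if (shifted && abs(shift) > p$fragmentTol)
        cand <- cand | (abs(dmz - shift) <= p$fragmentTol)
    idx <- which(cand, arr.ind = TRUE)
    if (nrow(idx) == 0) return(0)
    best <- 0
    recurse <- function(k, usedA, usedB, acc) {
        if (acc > best) best <<- acc
        if (k > nrow(idx)) return()
        recurse(k + 1, usedA, usedB, acc)  # skip pair k
        i <- idx[k, 1]; j <- idx[k, 2]
        if (!(i %in% usedA) && !(j %in% usedB))
            recurse(k + 1, c(usedA, i), c(usedB, j),
                    acc + wa[i] * wb[j])
    }
    recurse(1, integer(0), integer(0), 0)
    min(best, 1)
}

# Gotoh global alignment score with affine gaps: oracle for alignCDS scores
oracleAlignScore <- function(s1, s2, match = 2, mismatch = -3,
                             gapOpen = 10, gapExt = 0.5) {
    a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
    n <- length(a); m <- length(b)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
    M[1, 1] <- 0
    for (i in 2:(n + 1)) X[i, 1] <- -gapOpen - gapExt * (i - 1)
    for (j in 2:(m + 1)) Y[1, j] <- -gapOpen - gapExt * (j - 1)
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
        s <- if (a[i - 1] == b[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
        X[i, j] <- max(M[i - 1, j] - gapOpen - gapExt,
                       X[i - 1, j] - gapExt)
        Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExt,
                       Y[i, j - 1] - gapExt)
    }
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# union-find connected-component count: oracle for constellations()
oracleComponents <- function(ids, edges) {
    parent <- stats::setNames(ids, ids)
    find <- function(x) {
        while (parent[[x]] != x) {
            parent[[x]] <<- parent[[parent[[x]]]]
            x <- parent[[x]]
        }
        x
    }
    for (k in seq_len(nrow(edges)))
        parent[[find(edges$from[k])]] <- find(edges$to[k])
    length(unique(vapply(ids, find, character(1))))
}

# random spectrum generator for property tests
randomSpectrum <- function(id, nPeaks, mzRange = c(60, 480),
                           precursor = 500) {
    spec(id, precursor,
         sort(runif(nPeaks, mzRange[1], mzRange[2])),
         runif(nPeaks, 0.1, 1))
}
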