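# Molecular networking: modified-cosine scoring, greedy consensus
# clustering, thresholded network construction, constellation extraction,
# spectral-library matching and GraphML/TSV export.

#' Scoring and networking parameters
#'
#' Defaults follow common molecular-networking practice for high-resolution
#' data: 0.01 Da parent tolerance, 0.5 Da fragment tolerance, cosine
#' threshold 0.7 for both clustering and networking, minimum consensus
#' cluster size 4, library matching at score 0.5 with at least 2 matched
#' peaks, and square-root intensity weighting.
#'
#' @param parentTol precursor mass tolerance (Da).
#' @param fragmentTol fragment mass tolerance (Da).
#' @param minCosine cosine threshold for network edges and for joining a
#'   consensus cluster.
#' @param minClusterSize minimum spectra per consensus cluster; smaller
#'   clusters are discarded.
#' @param libraryMinScore minimum cosine for a spectral-library hit.
#' @param libraryMinMatched minimum matched peaks for a library hit.
#' @param intensityPower intensity weighting exponent (0.5 = square root).
#' @param topK optional neighbor pruning: keep an edge only if it ranks in
#'   the top `topK` of both endpoints (0 = no pruning).
#' @return classed parameter list.
#' @export
scoringParams <- function(parentTol = 0.01, fragmentTol = 0.5,
                          minCosine = 0.7, minClusterSize = 4L,
                          libraryMinScore = 0.5, libraryMinMatched = 2L,
                          intensityPower = 0.5, topK = 0L) {
    stopifnot(parentTol > 0, fragmentTol > 0,
              minCosine >= 0, minCosine <= 1,
              libraryMinScore >= 0, libraryMinScore <= 1,
              minClusterSize >= 1L, libraryMinMatched >= 0L,
              intensityPower >= 0, topK >= 0L)
    p <- list(parentTol = parentTol, fragmentTol = fragmentTol,
              minCosine = minCosine, minClusterSize = as.integer(minClusterSize),
              libraryMinScore = libraryMinScore,
              libraryMinMatched = as.integer(libraryMinMatched),
              intensityPower = intensityPower, topK = as.integer(topK))
    class(p) <- "ScoringParams"
    p
}

#' @export
print.ScoringParams <- function(x, ...) {
    cat("ScoringParams: parentTol", x$parentTol, "Da, fragmentTol",
        x$fragmentTol, "Da, minCosine", x$minCosine, ", minClusterSize",
        x$minClusterSize, "\n")
    invisible(x)
}

# normalized weight vector: intensity^power then L2 normalization
.peakWeights <- function(p, power) {
    w <- p[, 2L]^power
    n <- sqrt(sum(w^2))
    if (n > 0) w / n else w
}

#' Modified cosine similarity between two spectra
#'
#' Fragment peaks are matched one-to-one within `fragmentTol`, either
#' directly or (when `shifted = TRUE`) offset by the precursor mass
#' difference, which lets structurally related compounds differing by one
#' modification still match. Intensities are raised to
#' `p$intensityPower` and L2-normalized per spectrum; matching is greedy by
#' descending weight product with one-to-one peak use, and the score is the
#' sum of matched weight products, symmetric in its arguments and in
#' `[0, 1]`.
#'
#' @param a,b [Spectrum-class] objects with at least one peak each.
#' @param p a [scoringParams()] list.
#' @param shifted allow precursor-difference-shifted matches (modified
#'   cosine); `FALSE` gives the plain cosine.
#' @return list with `score` and `matched` (matched peak count).
#' @export
cosineScore <- function(a, b, p = scoringParams(), shifted = TRUE) {
    pa <- peaks(a); pb <- peaks(b)
    if (nrow(pa) == 0L || nrow(pb) == 0L)
        stop("cannot score an empty peak list")
    wa <- .peakWeights(pa, p$intensityPower)
    wb <- .peakWeights(pb, p$intensityPower)
    shift <- precursorMz(a) - precursorMz(b)
    # candidate pairs within tolerance, direct or precursor-shifted
    dmz <- outer(pa[, 1L], pb[, 1L], "-")
    cand <- abs(dmz) <= p$fragmentTol
    if (shifted && abs(shift) > p$fragmentTol)
        cand <- cand | (abs(dmz - shift) <= p$fragmentTol)
    idx <- which(cand, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(list(score = 0, matched = 0L))
    prod <- wa[idx[, 1L]] * wb[idx[, 2L]]
    ord <- order(-prod, idx[, 1L], idx[, 2L])   # deterministic greedy
    usedA <- logical(nrow(pa)); usedB <- logical(nrow(pb))
    score <- 0; matched <- 0L
    for (k in ord) {
        i <- idx[k, 1L]; j <- idx[k, 2L]
        if (usedA[i] || usedB[j]) next
        usedA[i] <- TRUE; usedB[j] <- TRUE
        score <- score + prod[k]
        matched <- matched + 1L
    }
    list(score = min(score, 1), matched = matched)
}

# merge pooled peaks within tol: greedy ascending grouping,
# intensity-weighted mean m/z, summed intensity
.mergePeaks <- function(pk, tol) {
    if (nrow(pk) == 0L) return(pk)
    pk <- pk[order(pk[, 1L]), , drop = FALSE]
    groups <- cumsum(c(TRUE, diff(pk[, 1L]) > tol))
    mz <- tapply(seq_len(nrow(pk)), groups, function(i)
        sum(pk[i, 1L] * pk[i, 2L]) / max(sum(pk[i, 2L]), .Machine$double.eps))
    int <- tapply(pk[, 2L], groups, sum)
    cbind(mz = as.numeric(mz), intensity = as.numeric(int))
}

#' Cluster replicate spectra into consensus spectra
#'
#' Greedy single-pass clustering after sorting by precursor m/z: a spectrum
#' joins the current cluster when its precursor is within `p$parentTol` of
#' the cluster's median precursor and its cosine against the running
#' consensus is at least `p$minCosine`; otherwise a new cluster starts.
#' Clusters with fewer than `p$minClusterSize` members are discarded.
#' Consensus peaks are the tolerance-merged, intensity-summed union of the
#' members' peaks. Deterministic given the input set.
#'
#' @param spectra non-empty list of [Spectrum-class].
#' @param p a [scoringParams()] list.
#' @return list of [ConsensusSpectrum-class] (possibly empty).
#' @export
clusterSpectra <- function(spectra, p = scoringParams()) {
    if (length(spectra) == 0L) stop("no spectra to cluster")
    ord <- order(vapply(spectra, precursorMz, numeric(1L)),
                 vapply(spectra, spectrumId, character(1L)))
    spectra <- spectra[ord]
    clusters <- list()
    cur <- NULL
    flush <- function(cl, clusters) {
        if (!is.null(cl)) clusters[[length(clusters) + 1L]] <- cl
        clusters
    }
    makeConsensus <- function(members, tol) {
        pooled <- do.call(rbind, lapply(members, peaks))
        .mergePeaks(pooled, tol)
    }
    for (s in spectra) {
        if (!is.null(cur)) {
            med <- median(vapply(cur$members, precursorMz, numeric(1L)))
            joins <- abs(precursorMz(s) - med) <= p$parentTol
            if (joins) {
                cons <- Spectrum("consensus", med,
                                 makeConsensus(cur$members, p$fragmentTol))
                joins <- cosineScore(s, cons, p, shifted = FALSE)$score >=
                    p$minCosine
            }
            if (joins) {
                cur$members <- c(cur$members, s)
                next
            }
            clusters <- flush(cur, clusters)
        }
        cur <- list(members = list(s))
    }
    clusters <- flush(cur, clusters)
    keep <- Filter(function(cl) length(cl$members) >= p$minClusterSize,
                   clusters)
    if (length(keep) == 0L) {
        message("no cluster reached the minimum size of ", p$minClusterSize)
        return(list())
    }
    out <- vector("list", length(keep))
    for (i in seq_along(keep)) {
        members <- keep[[i]]$members
        pk <- makeConsensus(members, p$fragmentTol)
        strainsSeen <- sort(unique(stats::na.omit(
            vapply(members, spectrumStrain, character(1L)))))
        out[[i]] <- new("ConsensusSpectrum",
            id = sprintf("CS%03d", i), strain = NA_character_,
            precursorMz = median(vapply(members, precursorMz, numeric(1L))),
            charge = members[[1L]]@charge,
            rt = median(vapply(members, rtime, numeric(1L))),
            peaks = pk,
            memberIds = vapply(members, spectrumId, character(1L)),
            strainsObserved = as.character(strainsSeen))
    }
    out
}

#' Build a molecular network over consensus spectra
#'
#' All-pairs modified cosine; undirected edges are kept when the score
#' reaches `p$minCosine`. Optional top-K neighbor pruning keeps an edge
#' only when it ranks among the `p$topK` best edges of both endpoints.
#'
#' @param nodes list of [ConsensusSpectrum-class] (or [Spectrum-class]).
#' @param p a [scoringParams()] list.
#' @return a [MolecularNetwork-class].
#' @export
buildNetwork <- function(nodes, p = scoringParams()) {
    if (length(nodes) < 1L) stop("need at least one node")
    ids <- vapply(nodes, spectrumId, character(1L))
    if (anyDuplicated(ids)) stop("node ids must be unique")
    n <- length(nodes)
    from <- character(0); to <- character(0)
    cosv <- numeric(0); mp <- integer(0)
    if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        cs <- cosineScore(nodes[[i]], nodes[[j]], p, shifted = TRUE)
        if (cs$score >= p$minCosine) {
            from <- c(from, ids[i]); to <- c(to, ids[j])
            cosv <- c(cosv, cs$score); mp <- c(mp, cs$matched)
        }
    }
    edges <- data.frame(from = from, to = to, cosine = cosv,
                        matchedPeaks = mp, stringsAsFactors = FALSE)
    if (p$topK > 0L && nrow(edges) > 0L) {
        rankOf <- function(id) {
            inc <- which(edges$from == id | edges$to == id)
            inc[order(-edges$cosine[inc])]
        }
        keep <- rep(FALSE, nrow(edges))
        for (id in ids) {
            top <- head(rankOf(id), p$topK)
            keep[top] <- keep[top] | TRUE
        }
        both <- vapply(seq_len(nrow(edges)), function(k) {
            kf <- head(rankOf(edges$from[k]), p$topK)
            kt <- head(rankOf(edges$to[k]), p$topK)
            (k %in% kf) && (k %in% kt)
        }, logical(1L))
        edges <- edges[both, , drop = FALSE]
    }
    new("MolecularNetwork", nodes = nodes, edges = edges,
        params = unclass(p), nodeGroups = character(0))
}

#' Constellations (connected components) of a molecular network
#'
#' @param g a [MolecularNetwork-class].
#' @return list of character vectors of node ids, sorted by component size
#'   descending (ties by first node id); singleton nodes included.
#' @export
constellations <- function(g) {
    ids <- vapply(networkNodes(g), spectrumId, character(1L))
    if (length(ids) == 0L) return(list())
    gr <- igraph::graph_from_data_frame(
        networkEdges(g)[, c("from", "to")], directed = FALSE,
        vertices = data.frame(name = ids))
    comp <- igraph::components(gr)
    comps <- split(ids, comp$membership[ids])
    comps <- lapply(comps, sort)
    comps[order(-vapply(comps, length, integer(1L)),
                vapply(comps, `[`, character(1L), 1L))]
}

#' Match a spectrum against an annotated spectral library
#'
#' Scores the query against every library spectrum with the modified cosine
#' and keeps hits with score at least `p$libraryMinScore` and at least
#' `p$libraryMinMatched` matched fragment peaks, best first.
#'
#' @param node query [Spectrum-class] or [ConsensusSpectrum-class].
#' @param library non-empty list of annotated [Spectrum-class]; the
#'   annotation is the spectrum id.
#' @param p a [scoringParams()] list.
#' @return data.frame with columns `annotation`, `score`, `matched`.
#' @export
libraryMatch <- function(node, library, p = scoringParams()) {
    if (length(library) == 0L) stop("library must be non-empty")
    res <- lapply(library, function(ref) cosineScore(node, ref, p, TRUE))
    out <- data.frame(
        annotation = vapply(library, spectrumId, character(1L)),
        score = vapply(res, `[[`, numeric(1L), "score"),
        matched = vapply(res, `[[`, integer(1L), "matched"),
        stringsAsFactors = FALSE)
    out <- out[out$score >= p$libraryMinScore &
               out$matched >= p$libraryMinMatched, , drop = FALSE]
    out <- out[order(-out$score), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.nodeTable <- function(g) {
    nodes <- networkNodes(g)
    grp <- g@nodeGroups
    data.frame(
        id = vapply(nodes, spectrumId, character(1L)),
        precursorMz = vapply(nodes, precursorMz, numeric(1L)),
        size = vapply(nodes, function(n)
            if (is(n, "ConsensusSpectrum")) length(memberIds(n)) else 1L,
            integer(1L)),
        strains = vapply(nodes, function(n)
            if (is(n, "ConsensusSpectrum"))
                paste(strainsObserved(n), collapse = ",")
            else spectrumStrain(n), character(1L)),
        group = vapply(nodes, function(n) {
            id <- spectrumId(n)
            if (id %in% names(grp)) grp[[id]] else NA_character_
        }, character(1L)),
        stringsAsFactors = FALSE)
}

#' Export a molecular network as GraphML plus node/edge TSV
#'
#' Writes `<prefix>.graphml` (via igraph, loadable by Cytoscape and other
#' graph tools), `<prefix>_nodes.tsv` and `<prefix>_edges.tsv`. Node
#' attributes carry precursor m/z, cluster size, strain set and the tag
#' group when assigned; edge attributes carry the cosine score (the usual
#' edge-thickness channel) and matched peak count.
#'
#' @param g a [MolecularNetwork-class].
#' @param prefix output path prefix.
#' @return character vector of the three paths written, invisibly.
#' @export
exportNetwork <- function(g, prefix) {
    nt <- .nodeTable(g)
    nt$group[is.na(nt$group)] <- ""
    nt$strains[is.na(nt$strains)] <- ""
    et <- networkEdges(g)
    gr <- igraph::graph_from_data_frame(et, directed = FALSE, vertices = nt)
    paths <- paste0(prefix, c(".graphml", "_nodes.tsv", "_edges.tsv"))
    igraph::write_graph(gr, paths[1L], format = "graphml")
    write.table(nt, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(et, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(paths)
}
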